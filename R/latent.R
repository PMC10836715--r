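# Latent-space analysis: encode the channel space, binarize the latent
# coordinates, turn windowed pairwise entropy production into features, and
# classify behavioral stages with a balanced random forest across latent
# dimensions.

#' Latent trace container
#'
#' @param values d x frames matrix of latent coordinates.
#' @param fs sampling rate in Hz.
#' @return object of class `latent_trace` with `values`, `binary`
#'   (`values > 0`, the zero-cutoff binarization) and `fs`.
#' @export
latent_trace <- function(values, fs) {
  values <- as.matrix(values)
  structure(list(values = values,
                 binary = (values > 0) * 1L,
                 fs = fs),
            class = "latent_trace")
}

#' @export
print.latent_trace <- function(x, ...) {
  cat(sprintf("<latent_trace> d = %d x %d frames @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  invisible(x)
}

#' Encode a recording into latent space
#'
#' Runs the trained encoder half of the network (inference mode, running
#' batch-norm statistics) and binarizes the latent coordinates at zero.
#'
#' @param rec a [recording] with the channel count the encoder was
#'   trained on.
#' @param ae a trained [train_autoencoder()] object.
#' @return a [latent_trace] at the recording's sampling rate.
#' @export
encode_recording <- function(rec, ae) {
  stopifnot(inherits(rec, "recording"), inherits(ae, "autoencoder"))
  if (n_channels(rec) != ae$spec$widths[1]) {
    stop("recording has ", n_channels(rec), " channels; encoder expects ",
         ae$spec$widths[1])
  }
  X <- ae_preprocess(ae, rec)
  H <- X
  for (l in 1:3) {
    p <- ae$params[[l]]
    Z <- sweep(H %*% p$W, 2, p$b, "+")
    if (ae$spec$batchnorm[l]) {
      Zh <- sweep(sweep(Z, 2, p$rmean), 2, sqrt(p$rvar + BN_EPS), "/")
      Y <- sweep(sweep(Zh, 2, p$gamma, "*"), 2, p$beta, "+")
      H <- pmax(Y, 0)
    } else {
      H <- Z
    }
  }
  latent_trace(t(H), fs = rec$fs)
}

#' Held-out reconstruction error of a trained autoencoder
#'
#' @param ae a trained autoencoder.
#' @param rec a [recording].
#' @param frames optional integer index of frames to evaluate (e.g. the
#'   autoencoder's stored `val_idx`); default all frames.
#' @return mean squared reconstruction error on the (z-scored) frames.
#' @export
reconstruction_mse <- function(ae, rec, frames = NULL) {
  X <- ae_preprocess(ae, rec)
  if (!is.null(frames)) X <- X[frames, , drop = FALSE]
  mean((ae_reconstruct(ae, X) - X)^2)
}

#' Windowed pairwise entropy-production features
#'
#' Splits the binarized latent trace into non-overlapping windows of
#' `window_s` seconds and computes, per window, the entropy production of
#' every unordered pair of latent coordinates (d(d-1)/2 features per
#' window).
#'
#' @param trace a [latent_trace].
#' @param window_s window length in seconds (default 5).
#' @param pseudocount,units passed to [pairwise_entropy_production()].
#' @return list with `features` (windows x pairs matrix),
#'   `window_start_s` and `window_s`.
#' @export
entropy_feature_windows <- function(trace, window_s = 5,
                                    pseudocount = "auto", units = "nats") {
  stopifnot(inherits(trace, "latent_trace"))
  wframes <- round(window_s * trace$fs)
  if (wframes < 2) stop("window contains fewer than 2 frames")
  feats <- pairwise_entropy_production(trace$binary, wframes,
                                       pseudocount = pseudocount,
                                       units = units)
  const <- which(apply(trace$binary, 1, function(b) length(unique(b)) == 1))
  if (length(const)) {
    message("constant binary coordinate(s): ",
            paste(const, collapse = ", "),
            " (their pair entropies are ~0)")
  }
  list(features = feats,
       window_start_s = (seq_len(nrow(feats)) - 1) * window_s,
       window_s = window_s)
}

#' Balanced random-forest classification of behavioral stages
#'
#' Class-balances the windows by under-sampling without replacement
#' (`n_undersample` repetitions), then for each balanced set draws
#' `n_splits` stratified 80/20 train/test splits and fits a random-forest
#' classifier on the training features, recording the test accuracy.
#'
#' @param features windows x features numeric matrix.
#' @param stage_labels integer/character label per window (`NA` windows
#'   dropped).
#' @param seed integer RNG seed (drives under-sampling, splits and the
#'   forests).
#' @param n_undersample balanced resamplings (default 50).
#' @param n_splits train/test splits per resampling (default 50).
#' @param num_trees trees per forest (default 500).
#' @param train_frac training fraction (default 0.8).
#' @param min_per_class minimum windows required per class (default 10).
#' @return list with `accuracies` (length `n_undersample * n_splits`),
#'   `mean_accuracy` and `n_classes`.
#' @export
balanced_stage_classification <- function(features, stage_labels, seed = 1,
                                          n_undersample = 50, n_splits = 50,
                                          num_trees = 500, train_frac = 0.8,
                                          min_per_class = 10) {
  features <- as.matrix(features)
  keep <- !is.na(stage_labels)
  features <- features[keep, , drop = FALSE]
  y <- factor(stage_labels[keep])
  counts <- table(y)
  if (length(counts) < 2) stop("need at least 2 stages present")
  if (any(counts < min_per_class)) {
    stop("class counts too small: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         " (need >= ", min_per_class, " windows per class)")
  }
  m <- min(counts)
  classes <- levels(y)
  set.seed(seed)
  accs <- numeric(0)
  for (u in seq_len(n_undersample)) {
    bal_idx <- unlist(lapply(classes, function(cl) {
      sample(which(y == cl), m)
    }))
    Xb <- features[bal_idx, , drop = FALSE]
    yb <- y[bal_idx]
    for (sp in seq_len(n_splits)) {
      tr <- unlist(lapply(classes, function(cl) {
        ix <- which(yb == cl)
        sample(ix, round(train_frac * length(ix)))
      }))
      df_tr <- data.frame(y = yb[tr], Xb[tr, , drop = FALSE])
      df_te <- data.frame(Xb[-tr, , drop = FALSE])
      rf <- ranger::ranger(y ~ ., data = df_tr, num.trees = num_trees,
                           seed = child_seed(seed, u * 1000L + sp),
                           num.threads = 1)
      pred <- predict(rf, data = df_te, num.threads = 1)$predictions
      accs <- c(accs, mean(pred == yb[-tr]))
    }
  }
  list(accuracies = accs, mean_accuracy = mean(accs),
       n_classes = length(classes))
}

# Frame-decimated copy of a recording for autoencoder training (the
# network treats frames independently; encoding always uses all frames).
decimate_for_training <- function(rec, max_frames) {
  stride <- max(1L, ceiling(n_samples(rec) / max_frames))
  if (stride == 1L) return(rec)
  recording(rec$data[, seq(1, n_samples(rec), by = stride), drop = FALSE],
            fs = rec$fs / stride, channel_ids = rec$channel_ids,
            system_of = rec$system_of)
}

#' Stage label of each feature window
#'
#' Majority frame-level stage label within each window.
#'
#' @param stages frame-level [state_sequence].
#' @param window_start_s,window_s window geometry (as returned by
#'   [entropy_feature_windows()]).
#' @return integer vector of per-window labels.
#' @export
window_labels <- function(stages, window_start_s, window_s) {
  window_stage_labels(stages, window_start_s, window_s)
}

#' Classification accuracy across latent dimensions
#'
#' Trains one autoencoder per candidate latent dimension, computes the
#' windowed pairwise entropy-production features and the balanced
#' random-forest accuracy for each, and reports the smallest dimension
#' whose mean accuracy lies within one standard error of the maximum (the
#' accuracy plateau).
#'
#' @param rec a [recording].
#' @param stages frame-level behavioral-stage [state_sequence].
#' @param d_values candidate latent dimensions.
#' @param seed integer RNG seed.
#' @param window_s feature window length in seconds (default 5).
#' @param ae_args list of overrides for [autoencoder_spec()].
#' @param class_args list of overrides for
#'   [balanced_stage_classification()].
#' @param max_train_frames frame budget for autoencoder training; longer
#'   recordings are decimated (every k-th frame) for training only, while
#'   encoding and the entropy features always use the full recording
#'   (default 30000). The network treats frames independently, so training
#'   on a frame subsample is unbiased.
#' @return list with `curve` (data.frame of `d`, `mean_accuracy`,
#'   `sd_accuracy`, `n`), `plateau_d` and `fits` (the per-d accuracy
#'   distributions).
#' @export
dimension_sweep <- function(rec, stages, d_values, seed = 1, window_s = 5,
                            ae_args = list(), class_args = list(),
                            max_train_frames = 30000) {
  stopifnot(length(d_values) >= 1)
  train_rec <- decimate_for_training(rec, max_train_frames)
  res <- lapply(seq_along(d_values), function(i) {
    d <- d_values[i]
    spec <- do.call(autoencoder_spec,
                    c(list(d = d, n_channels = n_channels(rec)), ae_args))
    ae <- train_autoencoder(train_rec, spec = spec,
                            seed = child_seed(seed, i))
    trace <- encode_recording(rec, ae)
    fw <- entropy_feature_windows(trace, window_s = window_s)
    labels <- window_labels(stages, fw$window_start_s, fw$window_s)
    cls <- do.call(balanced_stage_classification,
                   c(list(features = fw$features, stage_labels = labels,
                          seed = child_seed(seed, 100L + i)), class_args))
    cls
  })
  curve <- data.frame(
    d = d_values,
    mean_accuracy = vapply(res, `[[`, numeric(1), "mean_accuracy"),
    sd_accuracy = vapply(res, function(r) sd(r$accuracies), numeric(1)),
    n = vapply(res, function(r) length(r$accuracies), numeric(1))
  )
  imax <- which.max(curve$mean_accuracy)
  se_max <- curve$sd_accuracy[imax] / sqrt(curve$n[imax])
  plateau_d <- min(curve$d[curve$mean_accuracy >=
                             curve$mean_accuracy[imax] - se_max])
  list(curve = curve, plateau_d = plateau_d, fits = res)
}
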