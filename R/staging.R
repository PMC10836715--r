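# Data-driven behavioral staging from the recording's spectral signature:
# a channel-averaged z-scored spectrogram at 14 log-spaced frequencies,
# artifact rejection, PCA + k-means clustering, and a physiological naming
# heuristic for the three clusters.

#' Spectrogram features for stage classification
#'
#' Computes a per-channel spectrogram in sliding windows of `win_s` seconds
#' (Hann taper, step `step_s`), evaluated at `n_freqs` logarithmically
#' spaced center frequencies between `f_min` and `f_max` Hz (power averaged
#' over the periodogram bins of each log-spaced band). Each channel's
#' log-power is z-scored per frequency across epochs, the channels are
#' averaged into one global spectrogram, and the result is re-standardized
#' per frequency so every frequency carries equal weight.
#'
#' @param rec a [recording] of at least `win_s` seconds.
#' @param win_s epoch window length in seconds (default 60).
#' @param step_s epoch step in seconds (default 5).
#' @param n_freqs number of log-spaced center frequencies (default 14).
#' @param f_min,f_max frequency range in Hz (defaults 0.5-128; the lower
#'   edge must be positive for log spacing). Frequencies above Nyquist are
#'   dropped with a warning.
#' @return an object of class `spectro_features` with `times_s` (epoch
#'   centers), `freqs_hz`, `z_power` (epochs x frequencies) and
#'   `artifact_mask` (all `FALSE`; see [reject_artifacts()]).
#' @export
compute_stage_features <- function(rec, win_s = 60, step_s = 5,
                                   n_freqs = 14, f_min = 0.5, f_max = 128) {
  stopifnot(inherits(rec, "recording"))
  if (duration_s(rec) < win_s) stop("recording shorter than one epoch window")
  freqs <- logspace(f_min, f_max, n_freqs)
  nyq <- rec$fs / 2
  keep <- freqs <= nyq
  if (!all(keep)) {
    warning(sum(!keep), " center frequencies above Nyquist (", nyq,
            " Hz) dropped")
    freqs <- freqs[keep]
  }
  wlen <- round(win_s * rec$fs)
  step <- round(step_s * rec$fs)
  n <- n_samples(rec)
  n_epochs <- (n - wlen) %/% step + 1
  starts <- (seq_len(n_epochs) - 1) * step + 1

  # log-spaced band edges: geometric midpoints between neighbouring centers
  ratio <- if (length(freqs) > 1) sqrt(freqs[2] / freqs[1]) else 1.25
  f_lo <- freqs / ratio
  f_hi <- freqs * ratio
  fft_freqs <- (seq_len(wlen %/% 2)) * rec$fs / wlen  # skip DC
  bin_sets <- lapply(seq_along(freqs), function(i) {
    sel <- which(fft_freqs >= f_lo[i] & fft_freqs < f_hi[i])
    if (!length(sel)) sel <- which.min(abs(fft_freqs - freqs[i]))
    sel + 1L  # offset for the DC bin in the FFT output
  })
  taper <- hann_window(wlen)

  p <- n_channels(rec)
  P <- array(NA_real_, c(n_epochs, length(freqs), p))
  for (e in seq_len(n_epochs)) {
    seg <- t(rec$data[, starts[e]:(starts[e] + wlen - 1), drop = FALSE])
    seg <- sweep(seg, 2, colMeans(seg)) * taper
    sp <- Mod(mvfft(seg))^2                       # wlen x channels
    for (i in seq_along(bin_sets)) {
      P[e, i, ] <- colMeans(sp[bin_sets[[i]], , drop = FALSE])
    }
  }
  acc <- matrix(0, n_epochs, length(freqs))
  for (ch in seq_len(p)) {
    lp <- log10(pmax(P[, , ch], 1e-300))
    acc <- acc + z_cols(lp)  # z-score per frequency, then average channels
  }
  z <- z_cols(acc / p)       # re-standardize the global spectrogram
  structure(
    list(times_s = (starts - 1) / rec$fs + win_s / 2,
         freqs_hz = freqs,
         z_power = z,
         artifact_mask = rep(FALSE, n_epochs),
         step_s = step_s, win_s = win_s),
    class = "spectro_features"
  )
}

# Column z-scoring with a zero-variance guard (constant columns map to 0).
z_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv <= 0] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' @export
print.spectro_features <- function(x, ...) {
  cat(sprintf("<spectro_features> %d epochs x %d frequencies (%g-%g Hz), %d artifact\n",
              nrow(x$z_power), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), sum(x$artifact_mask)))
  invisible(x)
}

#' Mark artifact epochs by extreme mean z-score
#'
#' Epochs whose mean z-scored power exceeds `z_thresh` are flagged as noise,
#' together with every epoch whose center lies within `pad_s` seconds of a
#' flagged one.
#'
#' @param feat a `spectro_features` object.
#' @param z_thresh mean-z threshold (default 10).
#' @param pad_s rejection padding in seconds (default 10).
#' @return `feat` with an updated `artifact_mask`.
#' @export
reject_artifacts <- function(feat, z_thresh = 10, pad_s = 10) {
  stopifnot(inherits(feat, "spectro_features"))
  mz <- rowMeans(feat$z_power)
  bad <- which(mz > z_thresh)
  mask <- rep(FALSE, length(mz))
  for (b in bad) {
    mask[abs(feat$times_s - feat$times_s[b]) <= pad_s] <- TRUE
  }
  if (all(mask)) {
    stop("all epochs flagged as artifacts; review 'z_thresh' (", z_thresh, ")")
  }
  feat$artifact_mask <- mask
  feat
}

#' Cluster epochs into behavioral stages
#'
#' PCA on the non-artifact feature epochs, retaining the `n_pcs` strongest
#' components, followed by k-means with `k` clusters and multiple restarts.
#' Artifact epochs receive `NA` labels.
#'
#' @param feat a `spectro_features` object.
#' @param n_pcs number of principal components (default 8, capped at the
#'   number of features).
#' @param k number of clusters (default 3).
#' @param seed integer RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return a [state_sequence] on the epoch time base (frame rate
#'   `1/step_s`), with the feature object attached as attribute
#'   `"features"`.
#' @export
cluster_stages <- function(feat, n_pcs = 8, k = 3, seed = 1, nstart = 10) {
  stopifnot(inherits(feat, "spectro_features"))
  ok <- !feat$artifact_mask
  X <- feat$z_power[ok, , drop = FALSE]
  if (nrow(X) < k) stop("fewer non-artifact epochs than clusters")
  if (any(apply(X, 2, sd) == 0) && all(apply(X, 2, sd) == 0)) {
    stop("degenerate features: zero variance in every frequency")
  }
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1)
  set.seed(seed)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  km <- kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
  labels <- rep(NA_integer_, nrow(feat$z_power))
  labels[ok] <- km$cluster
  out <- state_sequence(labels, frame_rate = 1 / feat$step_s, K = k)
  attr(out, "features") <- feat
  out
}

#' Name stage clusters from their spectral content
#'
#' Heuristic mapping of the three clusters to behavioral-stage names: the
#' cluster with the highest mean low-frequency (delta, <= 4 Hz) z-power
#' becomes `"SWS"`; of the remaining two, the one with higher
#' high-frequency (>= 30 Hz) z-power becomes `"AA/REM"`, the other `"QA"`.
#' Ties are broken by cluster size (largest cluster to SWS, matching slow-
#' wave sleep being the most occupied stage). The assignment depends only
#' on cluster content, never on the arbitrary k-means label order.
#'
#' @param seq a [state_sequence] from [cluster_stages()] with `K = 3`.
#' @param feat the `spectro_features` used for clustering; defaults to the
#'   attribute attached by [cluster_stages()].
#' @return the sequence with `state_names` set.
#' @export
assign_stage_names <- function(seq, feat = attr(seq, "features")) {
  stopifnot(inherits(seq, "state_sequence"), seq$K == 3)
  if (is.null(feat)) stop("spectrogram features required to name stages")
  lo <- feat$freqs_hz <= 4
  hi <- feat$freqs_hz >= 30
  prof <- function(sel) {
    colMeans(feat$z_power[which(seq$labels == sel), , drop = FALSE])
  }
  sizes <- tabulate(seq$labels, nbins = 3)
  low_power <- vapply(1:3, function(k) mean(prof(k)[lo]), numeric(1))
  # tie-break by size: nudge larger clusters up by an epsilon ranking
  ord <- order(low_power, sizes, decreasing = TRUE)
  sws <- ord[1]
  rest <- setdiff(1:3, sws)
  hi_power <- vapply(rest, function(k) mean(prof(k)[hi]), numeric(1))
  aa <- rest[which.max(hi_power)]
  qa <- setdiff(rest, aa)
  nm <- character(3)
  nm[sws] <- "SWS"; nm[aa] <- "AA/REM"; nm[qa] <- "QA"
  seq$state_names <- nm
  seq
}

#' Epoch-level stage table
#'
#' Convenience export of a staged sequence as a data.frame
#' (`epoch_start_s`, `cluster`, `stage_name`, `is_artifact`).
#'
#' @param seq a named [state_sequence] from the staging pipeline.
#' @param feat the corresponding `spectro_features`.
#' @return a data.frame with one row per epoch.
#' @export
stage_table <- function(seq, feat = attr(seq, "features")) {
  stopifnot(inherits(seq, "state_sequence"))
  nm <- seq$state_names %||% as.character(seq_len(seq$K))
  data.frame(
    epoch_start_s = feat$times_s - feat$win_s / 2,
    cluster = seq$labels,
    stage_name = ifelse(is.na(seq$labels), NA_character_, nm[seq$labels]),
    is_artifact = feat$artifact_mask
  )
}
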