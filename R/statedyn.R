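# Region reduction, leakage correction and per-stage summaries of the
# network-state dynamics.

#' First principal component per cortical system
#'
#' Reduces each system's channels to the first principal-component score of
#' that system, with the sign convention that the score correlates
#' positively with the system's mean signal. Systems with a single channel
#' pass through unchanged with a warning.
#'
#' @param rec a [recording] with system labels.
#' @return a [recording] with one channel per system (labeled by system
#'   name); per-system PC1 explained variance is attached as attribute
#'   `"explained_variance"`.
#' @export
region_pca_signals <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  systems <- unique(unname(rec$system_of))
  out <- matrix(0, length(systems), n_samples(rec))
  expl <- setNames(numeric(length(systems)), systems)
  for (i in seq_along(systems)) {
    ch <- which(rec$system_of == systems[i])
    if (length(ch) == 1) {
      warning("system '", systems[i], "' has a single channel: passthrough")
      out[i, ] <- rec$data[ch, ]
      expl[i] <- 1
      next
    }
    X <- t(rec$data[ch, , drop = FALSE])
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    score <- pc$x[, 1]
    if (cor(score, rowMeans(X)) < 0) score <- -score
    out[i, ] <- score
    expl[i] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  res <- recording(out, fs = rec$fs, channel_ids = systems,
                   system_of = setNames(systems, systems))
  attr(res, "explained_variance") <- expl
  res
}

#' Symmetric (Loewdin) leakage correction
#'
#' Orthogonalizes the channels against zero-lag correlations by the
#' symmetric (closest-in-least-squares) transform `Y = C^{-1/2} X`, where
#' `C` is the zero-lag correlation matrix of the standardized channels.
#' The instantaneous correlation matrix of the output is the identity.
#'
#' @param rec a [recording] with `n_channels <= n_samples`.
#' @param tol eigenvalue threshold below which the input is declared
#'   rank-deficient.
#' @return a [recording] of mutually zero-lag-uncorrelated channels.
#' @export
leakage_correct <- function(rec, tol = 1e-10) {
  stopifnot(inherits(rec, "recording"))
  p <- n_channels(rec); n <- n_samples(rec)
  if (p > n) stop("more channels than samples: cannot orthogonalize")
  X <- rec$data - rowMeans(rec$data)
  sds <- sqrt(rowMeans(X^2))
  if (any(sds <= 0)) {
    stop("constant channel(s): ",
         paste(rec$channel_ids[sds <= 0], collapse = ", "))
  }
  X <- X / sds
  C <- tcrossprod(X) / n
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values < tol)) {
    bad <- which.max(abs(eg$vectors[, p]))
    stop("rank-deficient input: channel '", rec$channel_ids[bad],
         "' is (near) linearly dependent on the others")
  }
  Cinv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  with_data(rec, Cinv_sqrt %*% X)
}

# Transition counts of an integer label vector (NA-safe), optionally
# restricted to consecutive pairs allowed by 'pair_ok'.
transition_counts <- function(labels, K, pair_ok = NULL) {
  a <- labels[-length(labels)]
  b <- labels[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!is.null(pair_ok)) ok <- ok & pair_ok
  counts <- matrix(0, K, K)
  if (any(ok)) {
    tab <- tabulate((a[ok] - 1L) * K + b[ok], nbins = K * K)
    counts <- matrix(tab, K, K, byrow = TRUE)
  }
  counts
}

#' Per-stage summary of network-state dynamics
#'
#' Computes the state-sequence and information-theoretic metrics on the
#' network-state subsequence within each behavioral stage. Stage labels are
#' aligned to the network time base by nearest-frame lookup; transitions
#' that span a stage boundary belong to neither stage and are excluded
#' from the per-stage transition counts and switching rates. Lifetimes are
#' truncated at stage boundaries.
#'
#' @param seq network-state [state_sequence] (e.g. `fit$states`).
#' @param stages behavioral-stage [state_sequence]; any frame rate.
#' @param pseudocount passed to the per-stage transition estimate
#'   (default `"auto"` so entropy production stays finite).
#' @param units entropy-production units (default nats).
#' @return data.frame with one row per stage: `stage`, `n_frames`,
#'   `switching_rate`, `max_fo`, `mean_lifetime_s`, `entropy_production`,
#'   `determinism`, `degeneracy`, `mutual_information`. Stages with fewer
#'   than 2 usable frames yield `NA` metrics.
#' @export
per_stage_metrics <- function(seq, stages, pseudocount = "auto",
                              units = "nats") {
  stopifnot(inherits(seq, "state_sequence"),
            inherits(stages, "state_sequence"))
  K <- seq$K
  st <- align_labels(stages, length(seq$labels), seq$frame_rate)
  levels <- sort(unique(st[!is.na(st)]))
  rows <- lapply(levels, function(s) {
    in_stage <- !is.na(st) & st == s
    lab <- seq$labels
    n_frames <- sum(in_stage & !is.na(lab))
    base <- data.frame(stage = stage_name(stages, s), n_frames = n_frames)
    if (n_frames < 2) {
      return(cbind(base, switching_rate = NA_real_, max_fo = NA_real_,
                   mean_lifetime_s = NA_real_, entropy_production = NA_real_,
                   determinism = NA_real_, degeneracy = NA_real_,
                   mutual_information = NA_real_))
    }
    # consecutive pairs fully inside this stage
    pair_ok <- in_stage[-length(in_stage)] & in_stage[-1]
    counts <- transition_counts(lab, K, pair_ok)
    n_trans <- sum(counts)
    sr <- if (n_trans > 0) 1 - sum(diag(counts)) / n_trans else NA_real_
    fo <- tabulate(lab[in_stage], nbins = K) / n_frames
    # lifetimes from runs within contiguous stage blocks
    blocks <- split(which(in_stage), cumsum(c(1, diff(which(in_stage)) != 1)))
    runs <- do.call(rbind, lapply(blocks, function(ix) {
      run_lengths(lab[ix][!is.na(lab[ix])])
    }))
    mean_lt <- if (nrow(runs)) mean(runs$length) / seq$frame_rate else NA_real_
    if (n_trans > 0) {
      pc <- if (identical(pseudocount, "auto")) 1 / (n_trans * K^2) else
        pseudocount
      tm <- transition_model((counts + pc) / sum(counts + pc))
      ep <- entropy_production(tm, units = units)
      det <- determinism(tm); deg <- degeneracy(tm)
      mi <- mutual_information(tm)
    } else {
      ep <- det <- deg <- mi <- NA_real_
    }
    cbind(base, switching_rate = sr, max_fo = max(fo),
          mean_lifetime_s = mean_lt, entropy_production = ep,
          determinism = det, degeneracy = deg, mutual_information = mi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
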