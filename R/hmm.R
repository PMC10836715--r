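# Gaussian-emission hidden Markov model trained by Baum-Welch EM, used to
# infer recurring network states from the region-reduced signals. The
# forward-backward recursions run in compiled code; the M-step is standard
# closed-form Gaussian updates.

#' Fit hidden Markov network states to a region-reduced recording
#'
#' Trains a K-state hidden Markov model with full-covariance Gaussian
#' emissions by expectation-maximization on the (optionally time-embedded)
#' standardized channel signals. Several restarts are run from different
#' k-means initializations and the best log-likelihood is kept. States are
#' decoded by per-frame posterior argmax.
#'
#' @param rec a [recording], typically the 3-channel output of
#'   [region_pca_signals()].
#' @param K number of states (default 5).
#' @param seed integer RNG seed.
#' @param n_restarts EM restarts (default 5).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood gain below which EM stops
#'   (default 1e-6).
#' @param embed_lags non-negative integer; when positive, the observation
#'   vector is augmented with that many lagged copies so the emissions see
#'   short-range spectral structure (default 0).
#' @return an object of class `network_state_fit` with `K`,
#'   `state_posteriors` (frames x K), `states` (posterior-argmax
#'   [state_sequence]), `means`, `covariances`, `transition`, `initial`,
#'   `log_lik` (trace of the winning restart) and `frame_rate`.
#' @export
fit_network_states <- function(rec, K = 5, seed = 1, n_restarts = 5,
                               max_iter = 500, tol = 1e-6, embed_lags = 0) {
  stopifnot(inherits(rec, "recording"), K >= 1)
  X <- t(rec$data)
  X <- scale(X)
  if (embed_lags > 0) {
    n <- nrow(X)
    emb <- lapply(seq_len(embed_lags), function(l) {
      rbind(matrix(0, l, ncol(X)), X[seq_len(n - l), , drop = FALSE])
    })
    X <- do.call(cbind, c(list(X), emb))
  }
  Tn <- nrow(X)
  if (Tn < 50 * K) stop("need at least 50 frames per state (have ", Tn, ")")

  best <- NULL
  attempt <- 0L
  for (r in seq_len(n_restarts)) {
    repeat {
      attempt <- attempt + 1L
      fit <- try(em_gauss_hmm(X, K, seed = child_seed(seed, attempt),
                              max_iter = max_iter, tol = tol),
                 silent = TRUE)
      if (!inherits(fit, "try-error")) break
      if (attempt > n_restarts + 5L) {
        if (K > 1) {
          warning("persistent empty state: reducing K to ", K - 1)
          return(fit_network_states(rec, K = K - 1, seed = seed,
                                    n_restarts = n_restarts,
                                    max_iter = max_iter, tol = tol,
                                    embed_lags = embed_lags))
        }
        stop("EM failed for K = 1")
      }
    }
    if (is.null(best) || tail(fit$log_lik, 1) > tail(best$log_lik, 1)) {
      best <- fit
    }
  }

  labels <- max.col(best$gamma, ties.method = "first")
  structure(
    list(K = K,
         state_posteriors = best$gamma,
         states = state_sequence(labels, frame_rate = rec$fs, K = K),
         means = best$means,
         covariances = best$covs,
         transition = best$P,
         initial = best$pi,
         log_lik = best$log_lik,
         frame_rate = rec$fs),
    class = "network_state_fit"
  )
}

#' @export
print.network_state_fit <- function(x, ...) {
  cat(sprintf("<network_state_fit> K = %d, %d frames, log-lik %.2f (%d EM iterations)\n",
              x$K, nrow(x$state_posteriors), tail(x$log_lik, 1),
              length(x$log_lik)))
  cat("  fractional occupancy:",
      paste(sprintf("%.3f", fractional_occupancy(x$states)), collapse = " "),
      "\n")
  invisible(x)
}

# One EM run. Errors (caught by the caller) if a state's posterior mass
# drops below one frame.
em_gauss_hmm <- function(X, K, seed, max_iter, tol) {
  Tn <- nrow(X); d <- ncol(X)
  set.seed(seed)
  if (K == 1) {
    km_centers <- matrix(colMeans(X), 1)
  } else {
    sub <- X[sample.int(Tn, min(Tn, 5000L)), , drop = FALSE]
    km_centers <- kmeans(sub, centers = K, nstart = 3, iter.max = 50)$centers
  }
  means <- km_centers
  gcov <- cov(X) + diag(1e-4, d)
  covs <- replicate(K, gcov, simplify = FALSE)
  pi0 <- rep(1 / K, K)
  P <- matrix((1 - 0.7) / max(K - 1, 1), K, K)
  diag(P) <- if (K > 1) 0.7 else 1

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      logB[, k] <- gauss_logdens(X, means[k, ], covs[[k]])
    }
    m <- apply(logB, 1, max)
    B <- exp(logB - m)
    fb <- .hmm_forward_backward(B, pi0, P)
    ll <- fb$log_lik + sum(m)
    ll_trace <- c(ll_trace, ll)
    gamma <- fb$gamma
    nk <- colSums(gamma)
    if (any(nk < 1)) stop("empty state during EM")
    # M-step
    pi0 <- gamma[1, ] / sum(gamma[1, ])
    P <- fb$xi / rowSums(fb$xi)
    means <- (t(gamma) %*% X) / nk
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2, means[k, ])
      covs[[k]] <- crossprod(Xc * gamma[, k], Xc) / nk[k] + diag(1e-6, d)
    }
    if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- ll
  }
  list(gamma = gamma, means = means, covs = covs, P = P, pi = pi0,
       log_lik = ll_trace)
}

# Multivariate Gaussian log density for all rows of X.
gauss_logdens <- function(X, mu, Sigma) {
  d <- ncol(X)
  ch <- chol(Sigma)
  Xc <- sweep(X, 2, mu)
  z <- backsolve(ch, t(Xc), transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' Select the number of network states by occupancy balance
#'
#' Fits the model over a range of `K` and picks the value whose decoded
#' occupancy is most heterogeneous-but-balanced: the smallest excess of the
#' maximal fractional occupancy over the uniform share `1/K`, i.e. no
#' single state predominates.
#'
#' @param rec region-reduced [recording].
#' @param K_range candidate state counts (default `4:7`).
#' @param ... passed to [fit_network_states()].
#' @return list with `K_best`, `imbalance` per candidate and `fits`.
#' @export
choose_n_states <- function(rec, K_range = 4:7, ...) {
  fits <- lapply(K_range, function(K) fit_network_states(rec, K = K, ...))
  imb <- vapply(seq_along(K_range), function(i) {
    max_fractional_occupancy(fits[[i]]$states) - 1 / K_range[i]
  }, numeric(1))
  list(K_best = K_range[which.min(imb)],
       imbalance = setNames(imb, K_range),
       fits = setNames(fits, K_range))
}
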