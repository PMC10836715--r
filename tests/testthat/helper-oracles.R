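# Independent oracles, deliberately naive: explicit time flips, explicit
# Pearson correlations, explicit transition-cell enumeration. These never
# share code with the package internals they check.

# Brute-force irreversibility of one pair in one window: flip both series,
# correlate both directions, take the absolute difference.
brute_irrev <- function(x, y, shift = 1) {
  n <- length(x)
  cf <- stats::cor(x[1:(n - shift)], y[(1 + shift):n])
  xr <- rev(x)
  yr <- rev(y)
  cr <- stats::cor(xr[1:(n - shift)], yr[(1 + shift):n])
  abs(cf - cr)
}

# Brute-force entropy production of an integer sequence: enumerate every
# transition cell, normalize, sum P log(P/Prev) over observed cells.
brute_entropy_production <- function(labels, K, pseudocount = 0,
                                     base = exp(1)) {
  J <- matrix(pseudocount, K, K)
  for (t in seq_len(length(labels) - 1)) {
    J[labels[t], labels[t + 1]] <- J[labels[t], labels[t + 1]] + 1
  }
  J <- J / sum(J)
  s <- 0
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (J[i, j] > 0) {
        if (J[j, i] == 0) return(Inf)
        s <- s + J[i, j] * log(J[i, j] / J[j, i], base = base)
      }
    }
  }
  s
}

# Best-permutation label agreement between predicted and true labelings.
perm_accuracy <- function(pred, truth, k) {
  perms <- all_perms(seq_len(k))
  ok <- !is.na(pred) & !is.na(truth)
  max(vapply(perms, function(p) mean(p[pred[ok]] == truth[ok]), numeric(1)))
}

all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Small helper: a three-state cycle conditional matrix with forward
# probability p and backward probability 1 - p.
cycle3 <- function(p) {
  P <- matrix(0, 3, 3)
  P[cbind(1:3, c(2, 3, 1))] <- p
  P[cbind(1:3, c(3, 1, 2))] <- 1 - p
  P
}
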