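# Small shared numerical helpers.

#' Logarithmically spaced sequence
#'
#' @param from,to positive endpoints.
#' @param length.out number of points.
#' @return numeric vector, geometric progression from `from` to `to`.
#' @keywords internal
logspace <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0, length.out >= 1)
  exp(seq(log(from), log(to), length.out = length.out))
}

# Hann taper of length n (periodic-symmetric form used for spectral windows).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1) * (n + 1) / n)
}

# Shannon entropy of a probability vector, in the given log base.
# Zero cells contribute 0 by the usual 0 log 0 = 0 convention.
shannon_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# Spectral radius of a square matrix.
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

# Run-length encoding of an integer vector as a data.frame (value, length).
run_lengths <- function(x) {
  r <- rle(as.integer(x))
  data.frame(value = r$values, length = r$lengths)
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range so it is always a valid `set.seed()` argument.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
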