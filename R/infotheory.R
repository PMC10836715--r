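# State-sequence summaries (switching rate, fractional occupancy, lifetime)
# and information-theoretic nonequilibrium metrics on discrete transition
# models: entropy production, determinism, degeneracy, mutual information.

#' Transition model of a discrete state sequence
#'
#' Holds the joint transition probabilities `P(i -> j) = P(x_t = i,
#' x_{t+1} = j)`, the conditional matrix `P(j | i)` and the occupancy
#' distribution `pi(i) = sum_j P(i -> j)`.
#'
#' @param joint K x K non-negative matrix summing to 1.
#' @return an object of class `transition_model` with fields `K`, `joint`,
#'   `conditional`, `occupancy`.
#' @export
transition_model <- function(joint) {
  joint <- as.matrix(joint)
  K <- nrow(joint)
  stopifnot(ncol(joint) == K)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-8) {
    stop("'joint' must be non-negative and sum to 1")
  }
  occ <- rowSums(joint)
  cond <- joint / ifelse(occ > 0, occ, 1)
  cond[occ == 0, ] <- 1 / K   # unvisited states: uninformative rows
  structure(list(K = K, joint = joint, conditional = cond, occupancy = occ),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> K = %d states\n", x$K))
  cat("  occupancy:", paste(sprintf("%.3f", x$occupancy), collapse = " "),
      "\n")
  invisible(x)
}

#' Estimate a transition model from a state sequence
#'
#' Counts consecutive label pairs (`NA` frames break the chain) and
#' normalizes, with an optional Laplace pseudocount applied to every cell.
#' A pseudocount of `1/(T*K^2)` (`pseudocount = "auto"`) regularizes the
#' entropy-production estimator against structurally absent reverse
#' transitions; the default 0 keeps closed-form values exact.
#'
#' @param seq a [state_sequence] (or integer vector) of length >= 2.
#' @param K number of states; defaults to the sequence's `K`.
#' @param pseudocount non-negative number, or `"auto"`.
#' @return a [transition_model].
#' @examples
#' estimate_transitions(c(1, 2, 1, 2, 1), K = 2)$joint
#' @export
estimate_transitions <- function(seq, K = NULL, pseudocount = 0) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else
    as.integer(seq)
  if (is.null(K)) {
    K <- if (inherits(seq, "state_sequence")) seq$K else
      max(labels, na.rm = TRUE)
  }
  if (length(labels) < 2) stop("need at least 2 frames to count transitions")
  a <- labels[-length(labels)]
  b <- labels[-1]
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(0, K, K)
  if (any(ok)) {
    tab <- tabulate((a[ok] - 1L) * K + b[ok], nbins = K * K)
    counts <- matrix(tab, K, K, byrow = TRUE)
  }
  n <- sum(counts)
  if (identical(pseudocount, "auto")) pseudocount <- 1 / (max(n, 1) * K^2)
  counts <- counts + pseudocount
  if (sum(counts) == 0) stop("no valid transitions in the sequence")
  transition_model(counts / sum(counts))
}

#' Entropy production of a transition model
#'
#' Kullback-Leibler divergence between the forward joint transition
#' probabilities and their time reversal:
#' `S = sum_{ij} P(i->j) log( P(i->j) / P(j->i) )`, taken over cells with
#' `P(i->j) > 0`. `S = 0` iff the joint matrix is symmetric (detailed
#' balance); a forward transition with zero reverse probability makes `S`
#' infinite (flagged with a warning) — estimate with a pseudocount to
#' regularize.
#'
#' @param tm a [transition_model].
#' @param units `"nats"` (natural log, thermodynamic convention; default)
#'   or `"bits"`.
#' @return a single non-negative number (possibly `Inf`).
#' @export
entropy_production <- function(tm, units = c("nats", "bits")) {
  stopifnot(inherits(tm, "transition_model"))
  units <- match.arg(units)
  J <- tm$joint
  Jt <- t(J)
  sel <- J > 0
  if (any(sel & Jt == 0)) {
    warning("forward transition with zero reverse probability: ",
            "entropy production is infinite; consider a pseudocount")
    return(Inf)
  }
  S <- sum(J[sel] * log(J[sel] / Jt[sel]))
  if (units == "bits") S <- S / log(2)
  max(S, 0)
}

#' Determinism of a transition graph
#'
#' `Det = (log2 K - <H(row_i)>) / log2 K`, the normalized complement of
#' the mean out-going row entropy (bits): 1 for a permutation matrix, 0 for
#' uniform rows.
#'
#' @param tm a [transition_model] with `K >= 2`.
#' @return a number in \[0, 1\].
#' @export
determinism <- function(tm) {
  stopifnot(inherits(tm, "transition_model"), tm$K >= 2)
  hrows <- apply(tm$conditional, 1, shannon_entropy, base = 2)
  (log2(tm$K) - mean(hrows)) / log2(tm$K)
}

#' Degeneracy of a transition graph
#'
#' `Deg = (log2 K - H(column means of the conditional matrix)) / log2 K`:
#' 1 when every state feeds the same successor, 0 for a doubly stochastic
#' graph (uniform mean out-distribution).
#'
#' @param tm a [transition_model] with `K >= 2`.
#' @return a number in \[0, 1\].
#' @export
degeneracy <- function(tm) {
  stopifnot(inherits(tm, "transition_model"), tm$K >= 2)
  wbar <- colMeans(tm$conditional)
  (log2(tm$K) - shannon_entropy(wbar, base = 2)) / log2(tm$K)
}

#' Mutual information between past and future states
#'
#' `MI = H(pi_past) + H(pi_future) - H(joint)` in bits, where the
#' marginals are the row and column sums of the joint transition matrix.
#'
#' @param tm a [transition_model].
#' @return a non-negative number (bits).
#' @export
mutual_information <- function(tm) {
  stopifnot(inherits(tm, "transition_model"))
  h_past <- shannon_entropy(rowSums(tm$joint), base = 2)
  h_future <- shannon_entropy(colSums(tm$joint), base = 2)
  h_joint <- shannon_entropy(as.vector(tm$joint), base = 2)
  max(h_past + h_future - h_joint, 0)
}

#' Switching rate of a state sequence
#'
#' Fraction of consecutive frame pairs whose label changes; `NA` frames
#' and the pairs touching them are excluded.
#'
#' @param seq a [state_sequence] or integer vector of length >= 2.
#' @return a number in \[0, 1\].
#' @examples
#' switching_rate(c(1, 1, 2, 2, 2, 3))  # 2 changes over 5 steps = 0.4
#' @export
switching_rate <- function(seq) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else
    as.integer(seq)
  if (length(labels) < 2) stop("switching rate undefined for length < 2")
  a <- labels[-length(labels)]; b <- labels[-1]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no valid consecutive pairs")
  mean(a[ok] != b[ok])
}

#' Fractional occupancy
#'
#' Fraction of (non-`NA`) frames spent in each state; sums to 1.
#'
#' @param seq a [state_sequence] or integer vector.
#' @param K number of states; defaults to the sequence's `K`.
#' @return numeric vector of length `K`.
#' @seealso [max_fractional_occupancy()]
#' @export
fractional_occupancy <- function(seq, K = NULL) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else
    as.integer(seq)
  if (is.null(K)) {
    K <- if (inherits(seq, "state_sequence")) seq$K else
      max(labels, na.rm = TRUE)
  }
  labels <- labels[!is.na(labels)]
  tabulate(labels, nbins = K) / length(labels)
}

#' @rdname fractional_occupancy
#' @export
max_fractional_occupancy <- function(seq, K = NULL) {
  max(fractional_occupancy(seq, K))
}

#' Average lifetime of state visits
#'
#' Run-length encodes the sequence and reports the mean visit duration per
#' state and overall, in seconds.
#'
#' @param seq a [state_sequence] or integer vector.
#' @param frame_rate frames per second; defaults to the sequence's.
#' @param K number of states.
#' @return list with `per_state` (mean lifetime in seconds per state,
#'   `NA` for unvisited states), `overall` (mean over all visits) and
#'   `n_visits` per state.
#' @export
average_lifetime <- function(seq, frame_rate = NULL, K = NULL) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else
    as.integer(seq)
  if (is.null(frame_rate)) {
    frame_rate <- if (inherits(seq, "state_sequence")) seq$frame_rate else 1
  }
  if (is.null(K)) {
    K <- if (inherits(seq, "state_sequence")) seq$K else
      max(labels, na.rm = TRUE)
  }
  labels <- labels[!is.na(labels)]
  runs <- run_lengths(labels)
  per_state <- vapply(seq_len(K), function(k) {
    d <- runs$length[runs$value == k]
    if (!length(d)) NA_real_ else mean(d) / frame_rate
  }, numeric(1))
  list(per_state = per_state,
       overall = mean(runs$length) / frame_rate,
       n_visits = vapply(seq_len(K), function(k) sum(runs$value == k),
                         integer(1)))
}

#' Pairwise entropy production of binarized multichannel traces
#'
#' For every unordered pair of binary channels, forms the joint 4-state
#' sequence (00, 01, 10, 11), estimates its transition model per
#' non-overlapping window and applies the entropy-production formula. The
#' subsystem of a pair is the same regardless of channel order, so one
#' value is stored per unordered pair.
#'
#' @param binary_traces 0/1 matrix, channels x frames.
#' @param window frames per window; the trailing partial window is
#'   discarded.
#' @param pseudocount passed to [estimate_transitions()]; default
#'   `"auto"` to keep estimates finite.
#' @param units passed to [entropy_production()].
#' @return matrix of windows x pairs; column names `"i|j"`. Constant
#'   channels yield 0 for their pairs when regularized.
#' @export
pairwise_entropy_production <- function(binary_traces, window,
                                        pseudocount = "auto",
                                        units = "nats") {
  binary_traces <- as.matrix(binary_traces)
  if (!all(binary_traces %in% c(0, 1))) {
    stop("'binary_traces' must contain only 0/1")
  }
  d <- nrow(binary_traces)
  n <- ncol(binary_traces)
  stopifnot(window >= 2, d >= 2)
  nw <- n %/% window
  if (nw < 1) stop("fewer frames than one window")
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  out <- matrix(NA_real_, nw, nrow(pairs))
  colnames(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  for (pi in seq_len(nrow(pairs))) {
    a <- binary_traces[pairs[pi, 1], ]
    b <- binary_traces[pairs[pi, 2], ]
    s4 <- 1L + a + 2L * b                   # joint micro-state in 1..4
    for (w in seq_len(nw)) {
      idx <- ((w - 1) * window + 1):(w * window)
      tm <- estimate_transitions(s4[idx], K = 4, pseudocount = pseudocount)
      out[w, pi] <- entropy_production(tm, units = units)
    }
  }
  out
}
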