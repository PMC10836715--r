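#' Discrete state sequence
#'
#' Integer state labels on a stated time base, used both for behavioral
#' stages (from the spectral classifier or the generator's ground truth) and
#' for hidden-Markov network states. `NA` labels mark frames without a valid
#' label (e.g. artifact epochs).
#'
#' @param labels integer vector with values in `1..K` (or `NA`).
#' @param frame_rate frames per second of the label time base.
#' @param K number of distinct states; defaults to `max(labels)`.
#' @param state_names optional character vector of length `K` naming the
#'   states (e.g. `"AA/REM"`, `"QA"`, `"SWS"`).
#' @return an object of class `state_sequence`.
#' @examples
#' state_sequence(c(1, 1, 2, 3), frame_rate = 1, K = 3)
#' @export
state_sequence <- function(labels, frame_rate, K = NULL,
                           state_names = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1) stop("state sequence must have length >= 1")
  if (is.null(K)) K <- max(labels, na.rm = TRUE)
  ok <- is.na(labels) | (labels >= 1L & labels <= K)
  if (!all(ok)) stop("labels must lie in 1..K (or NA)")
  if (!is.null(state_names) && length(state_names) != K) {
    stop("'state_names' must have length K")
  }
  structure(
    list(labels = labels, frame_rate = frame_rate, K = as.integer(K),
         state_names = state_names),
    class = "state_sequence"
  )
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("<state_sequence> %d frames @ %g Hz, K = %d\n",
              length(x$labels), x$frame_rate, x$K))
  if (!is.null(x$state_names)) {
    cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.state_sequence <- function(x) length(x$labels)

#' @export
as.data.frame.state_sequence <- function(x, ...) {
  data.frame(frame_index = seq_along(x$labels),
             time_s = (seq_along(x$labels) - 1) / x$frame_rate,
             label = x$labels)
}

# Resample labels to a new frame rate by nearest-frame lookup.
align_labels <- function(seq, n_frames, frame_rate) {
  t_new <- (seq_len(n_frames) - 0.5) / frame_rate
  idx <- pmin(pmax(round(t_new * seq$frame_rate + 0.5), 1L),
              length(seq$labels))
  seq$labels[idx]
}
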