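# Windowed pairwise signal irreversibility: the absolute difference between
# the forward time-shifted Pearson correlation and its time-reversed
# counterpart, evaluated in non-overlapping windows, plus system-level and
# frequency-resolved decompositions.

#' Resample a recording to a lower analysis rate
#'
#' Anti-aliased polyphase resampling of every channel; metadata preserved.
#' Upsampling is refused (the estimator is defined at or below the
#' acquisition rate).
#'
#' @param rec a [recording].
#' @param target_fs target sampling rate in Hz, `<= rec$fs`.
#' @return a [recording] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs) {
    stop("upsampling refused: target_fs (", target_fs,
         ") exceeds the recording rate (", rec$fs, ")")
  }
  if (target_fs == rec$fs) return(rec)
  # smallest integer ratio p/q = target_fs/fs
  scale <- 1e6
  a <- round(target_fs * scale); b <- round(rec$fs * scale)
  g <- gcd_int(a, b)
  p <- a / g; q <- b / g
  out <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
  recording(out, fs = target_fs, channel_ids = rec$channel_ids,
            system_of = rec$system_of)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Forward and time-reversed shifted correlations of a signal pair
#'
#' The forward value is the Pearson correlation of `(x[t], y[t + shift])`;
#' the reversal value is the same statistic after flipping the time order of
#' both series, which is algebraically the forward correlation of the
#' swapped pair `(y, x)` at the same shift.
#'
#' @param x,y numeric vectors of equal length `> shift_frames`.
#' @param shift_frames positive integer lag in frames.
#' @return named numeric vector `c(c_forward, c_reversal)`, both in
#'   \[-1, 1\]; `NA` with a warning if a segment has zero variance.
#' @export
shifted_correlation_pair <- function(x, y, shift_frames = 1) {
  n <- length(x)
  stopifnot(length(y) == n, shift_frames >= 1, n > shift_frames)
  s <- shift_frames
  lead <- seq_len(n - s)
  lag <- lead + s
  xr <- rev(x); yr <- rev(y)
  cf <- safe_cor(x[lead], y[lag])
  cr <- safe_cor(xr[lead], yr[lag])
  c(c_forward = cf, c_reversal = cr)
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance segment: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Windowed pairwise irreversibility of a recording
#'
#' For each non-overlapping window of `window_s` seconds and each channel
#' pair, computes the absolute difference between the forward and
#' time-reversed shifted correlations at a lag of `shift_frames` frames.
#' Because the reversal correlation of `(x, y)` equals the forward
#' correlation of `(y, x)`, the pair value is identical for both orderings
#' and is stored once in a symmetric per-window matrix with a zero diagonal.
#'
#' The per-window scalar aggregates the upper-triangle pair values
#' (`mean` by default). The signed differences are also retained: averaging
#' them across windows before taking the absolute value gives the
#' consistent long-run estimator used by [aggregate_irreversibility()].
#'
#' @param rec a [recording] with at least one full window.
#' @param window_s window length in seconds (default 1).
#' @param shift_frames correlation lag in frames (default 1).
#' @param aggregate per-window scalar aggregation: `"mean"`, `"median"` or
#'   `"sum"` of the upper-triangle pair values.
#' @return an object of class `irrev_series` with fields `window_start_s`,
#'   `pair_matrix` (channels x channels x windows, absolute differences),
#'   `signed` (same shape, antisymmetric signed differences), `scalar`
#'   (one value per window), `window_len_s`, `shift_frames`,
#'   `channel_ids`, `system_of`, `fs`.
#' @export
irreversibility_windows <- function(rec, window_s = 1, shift_frames = 1,
                                    aggregate = c("mean", "median", "sum")) {
  stopifnot(inherits(rec, "recording"))
  aggregate <- match.arg(aggregate)
  wlen <- round(window_s * rec$fs)
  if (wlen <= shift_frames + 2) {
    stop("window too short for the requested shift at fs = ", rec$fs)
  }
  n <- n_samples(rec)
  nw <- n %/% wlen
  if (nw < 1) stop("recording shorter than one window")
  dropped <- n - nw * wlen
  if (dropped > 0) {
    message("discarding trailing partial window of ", dropped, " frames")
  }
  p <- n_channels(rec)
  s <- shift_frames
  signed <- array(NA_real_, c(p, p, nw))
  scalar <- numeric(nw)
  ut <- upper.tri(matrix(0, p, p))
  agg_fun <- switch(aggregate, mean = mean, median = median, sum = sum)
  for (w in seq_len(nw)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    X1 <- t(rec$data[, idx[1:(wlen - s)], drop = FALSE])
    X2 <- t(rec$data[, idx[(1 + s):wlen], drop = FALSE])
    C <- cross_cor(X1, X2)        # C[i, j] = cor(x_i[t], x_j[t + s])
    D <- C - t(C)                 # forward minus reversal, antisymmetric
    signed[, , w] <- D
    scalar[w] <- agg_fun(abs(D[ut]), na.rm = TRUE)
  }
  structure(
    list(window_start_s = (seq_len(nw) - 1) * window_s,
         pair_matrix = abs(signed),
         signed = signed,
         scalar = scalar,
         window_len_s = window_s,
         shift_frames = shift_frames,
         aggregate = aggregate,
         channel_ids = rec$channel_ids,
         system_of = rec$system_of,
         fs = rec$fs),
    class = "irrev_series"
  )
}

# Column-pairwise Pearson correlation between two frame x channel slices,
# each column standardized within its own slice. Channels with zero
# variance in either slice yield NA rows/columns (excluded pairwise
# downstream) rather than failing the whole window.
cross_cor <- function(X1, X2) {
  z <- function(X) {
    mu <- colMeans(X)
    sdv <- sqrt(colMeans(X^2) - mu^2)
    bad <- sdv <= 0
    sdv[bad] <- 1
    Xc <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    Xc[, bad] <- NA_real_
    Xc
  }
  m <- nrow(X1)
  crossprod(z(X1), z(X2)) / m
}

#' @export
print.irrev_series <- function(x, ...) {
  cat(sprintf(
    "<irrev_series> %d windows of %g s (shift %d frame(s)), %d channels\n",
    length(x$scalar), x$window_len_s, x$shift_frames, length(x$channel_ids)))
  cat(sprintf("  per-window scalar: mean %.4g, time-averaged signed %.4g\n",
              mean(x$scalar, na.rm = TRUE), aggregate_irreversibility(x)))
  invisible(x)
}

#' @export
as.data.frame.irrev_series <- function(x, ...) {
  data.frame(window_start_s = x$window_start_s, scalar = x$scalar)
}

#' Time-averaged irreversibility of a window series
#'
#' The consistent long-run estimator: per pair, average the *signed*
#' forward-minus-reversed correlation differences across windows, take the
#' absolute value, then average over pairs. For a time-reversible process
#' this converges to 0 as the window count grows; the per-window absolute
#' values (`method = "abs"`) instead converge to the positive sampling
#' noise floor of windowed correlations and are kept for per-window time
#' courses.
#'
#' @param series an `irrev_series` from [irreversibility_windows()].
#' @param method `"signed"` (default, consistent) or `"abs"` (mean of the
#'   per-window scalars).
#' @param windows optional integer/logical index of windows to include.
#' @param pairs optional logical channels x channels mask restricting which
#'   pairs enter the average (upper triangle is used).
#' @return a single non-negative number.
#' @export
aggregate_irreversibility <- function(series, method = c("signed", "abs"),
                                      windows = NULL, pairs = NULL) {
  stopifnot(inherits(series, "irrev_series"))
  method <- match.arg(method)
  p <- length(series$channel_ids)
  ut <- upper.tri(matrix(0, p, p))
  if (!is.null(pairs)) ut <- ut & pairs
  sub <- if (is.null(windows)) series$signed else
    series$signed[, , windows, drop = FALSE]
  if (method == "abs") {
    sc <- if (is.null(windows)) series$scalar else series$scalar[windows]
    return(mean(sc, na.rm = TRUE))
  }
  pm <- apply(sub, c(1, 2), mean, na.rm = TRUE)
  mean(abs(pm[ut]), na.rm = TRUE)
}

# Logical pair masks for within/between-system decompositions.
system_pair_masks <- function(system_of) {
  systems <- unique(system_of)
  p <- length(system_of)
  same <- outer(system_of, system_of, "==")
  masks <- list(all = matrix(TRUE, p, p), within = same, between = !same)
  for (s in systems) {
    both <- outer(system_of == s, system_of == s, "&")
    masks[[s]] <- both
  }
  masks
}

#' Within/between-system decomposition of irreversibility
#'
#' Averages pair values with both channels inside each system (the
#' "within-system" relations), across all same-system pairs pooled, and
#' across cross-system pairs, per window and as time-averaged summaries.
#' With a behavioral-stage sequence supplied, windows are grouped by their
#' majority stage label and summarized per stage.
#'
#' @param series an `irrev_series`.
#' @param system_of channel -> system map; defaults to the one carried by
#'   the series.
#' @param stages optional [state_sequence] of behavioral stages on the
#'   recording time base used for the series.
#' @return list with `per_window` (data.frame of per-window means),
#'   `summary` (time-averaged signed estimates per system plus within and
#'   between) and, when `stages` is given, `per_stage`. Systems with fewer
#'   than two channels have `NA` within values.
#' @export
group_by_system <- function(series, system_of = NULL, stages = NULL) {
  stopifnot(inherits(series, "irrev_series"))
  system_of <- system_of %||% series$system_of
  if (!setequal(names(system_of), series$channel_ids)) {
    stop("'system_of' must map every channel of the series")
  }
  sys <- unname(system_of[series$channel_ids])
  masks <- system_pair_masks(sys)
  p <- length(sys)
  ut <- upper.tri(matrix(0, p, p))
  nw <- length(series$scalar)

  per_window <- data.frame(window_start_s = series$window_start_s)
  for (m in names(masks)) {
    sel <- masks[[m]] & ut
    per_window[[m]] <- if (!any(sel)) NA_real_ else
      apply(series$pair_matrix, 3, function(M) mean(M[sel], na.rm = TRUE))
  }

  summarize <- function(windows) {
    vals <- vapply(names(masks), function(m) {
      sel <- masks[[m]] & ut
      if (!any(sel)) return(NA_real_)
      aggregate_irreversibility(series, windows = windows, pairs = masks[[m]])
    }, numeric(1))
    as.list(vals)
  }
  out <- list(per_window = per_window,
              summary = as.data.frame(summarize(NULL)))

  if (!is.null(stages)) {
    wl <- window_stage_labels(stages, series$window_start_s,
                              series$window_len_s)
    st_levels <- sort(unique(wl[!is.na(wl)]))
    per_stage <- do.call(rbind, lapply(st_levels, function(s) {
      cbind(data.frame(stage = stage_name(stages, s),
                       n_windows = sum(wl == s, na.rm = TRUE)),
            as.data.frame(summarize(which(wl == s))))
    }))
    out$per_stage <- per_stage
  }
  out
}

# Majority stage label of each analysis window.
window_stage_labels <- function(stages, window_start_s, window_len_s) {
  vapply(window_start_s, function(t0) {
    i0 <- floor(t0 * stages$frame_rate) + 1
    i1 <- min(ceiling((t0 + window_len_s) * stages$frame_rate),
              length(stages$labels))
    if (i0 > length(stages$labels)) return(NA_integer_)
    lab <- stages$labels[i0:i1]
    lab <- lab[!is.na(lab)]
    if (!length(lab)) return(NA_integer_)
    as.integer(names(which.max(table(lab))))
  }, integer(1))
}

stage_name <- function(stages, k) {
  if (!is.null(stages$state_names)) stages$state_names[k] else as.character(k)
}

# Band assignment of 1-Hz bins: a bin [lo, lo+1) belongs to a band when its
# lower edge falls in the band's bin range. Bins at lo = 0, 7 and 16 Hz are
# deliberately left unassigned (the canonical band table has gaps there).
band_bin_table <- function() {
  list(delta = 1:3, theta = 4:6, alpha = 8:15, beta = 17:29, gamma = 30:49)
}

#' Frequency-resolved irreversibility profile
#'
#' Bandpass-filters the recording into contiguous 1-Hz bins (zero-phase
#' 4th-order Butterworth; the DC bin is narrowed to 0.5-1 Hz), runs the
#' windowed irreversibility estimator on each filtered signal, and stores
#' the time-averaged value per bin together with canonical band means
#' (delta 1-3, theta 4-6, alpha 8-16, beta 17-30, gamma 30-50 Hz).
#'
#' @param rec a [recording].
#' @param lo,hi sweep range in Hz (default 0-50); `hi` must not exceed the
#'   Nyquist frequency.
#' @param bin_width bin width in Hz (default 1).
#' @param window_s,shift_frames passed to [irreversibility_windows()].
#' @return an object of class `band_profile` with `bin_lo_hz`, `bin_hi_hz`,
#'   `irreversibility_per_bin` and `band_means`.
#' @export
band_sweep <- function(rec, lo = 0, hi = 50, bin_width = 1, window_s = 1,
                       shift_frames = 1) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$fs / 2
  if (hi > nyq) stop("'hi' exceeds the Nyquist frequency (", nyq, " Hz)")
  bin_lo <- seq(lo, hi - bin_width, by = bin_width)
  bin_hi <- bin_lo + bin_width
  vals <- rep(NA_real_, length(bin_lo))
  for (i in seq_along(bin_lo)) {
    f1 <- if (bin_lo[i] <= 0) 0.5 else bin_lo[i]
    f2 <- bin_hi[i]
    if (f1 >= nyq * 0.98) {
      warning("bin ", bin_lo[i], "-", bin_hi[i], " Hz at/above Nyquist: skipped")
      next
    }
    f2 <- min(f2, nyq * 0.98)
    bf <- signal::butter(2, c(f1, f2) / nyq, type = "pass")
    filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
    frec <- recording(filt, fs = rec$fs, channel_ids = rec$channel_ids,
                      system_of = rec$system_of)
    ser <- irreversibility_windows(frec, window_s = window_s,
                                   shift_frames = shift_frames)
    vals[i] <- aggregate_irreversibility(ser)
  }
  bins <- band_bin_table()
  band_means <- vapply(bins, function(bb) {
    sel <- bin_lo %in% bb
    if (!any(sel)) NA_real_ else mean(vals[sel], na.rm = TRUE)
  }, numeric(1))
  structure(
    list(bin_lo_hz = bin_lo, bin_hi_hz = bin_hi,
         irreversibility_per_bin = vals, band_means = band_means),
    class = "band_profile"
  )
}

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf("<band_profile> %d bins, %g-%g Hz\n", length(x$bin_lo_hz),
              min(x$bin_lo_hz), max(x$bin_hi_hz)))
  print(round(x$band_means, 6))
  invisible(x)
}

#' @export
as.data.frame.band_profile <- function(x, ...) {
  data.frame(bin_lo_hz = x$bin_lo_hz, bin_hi_hz = x$bin_hi_hz,
             irreversibility = x$irreversibility_per_bin)
}
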