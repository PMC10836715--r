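# Synthetic recordings with planted, known structure. Every downstream
# estimator in the package is validated against data produced here, since
# real multichannel cortical recordings carry no ground truth.

# Frequency bands used both for band-shaped noise synthesis and for the
# band-profile summaries (Hz).
band_definitions <- function() {
  list(delta = c(1, 3), theta = c(4, 6), alpha = c(8, 16),
       beta = c(17, 30), gamma = c(30, 50))
}

#' Behavioral-stage specification for the synthetic generator
#'
#' Describes one behavioral stage: its spectral signature (relative power in
#' the canonical delta/theta/alpha/beta/gamma bands plus a `broadband` white
#' floor), the asymmetry of its cross-channel coupling (0 = symmetric, hence
#' time-reversible in expectation; 1 = fully unidirectional), and the mean
#' dwell time of its exponentially distributed visits.
#'
#' @param name stage name.
#' @param band_powers named non-negative vector; names from
#'   `delta, theta, alpha, beta, gamma, broadband`.
#' @param coupling_asymmetry real in \[0, 1\].
#' @param mean_dwell_s mean dwell time in seconds (> 0).
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(name, band_powers, coupling_asymmetry, mean_dwell_s) {
  stopifnot(is.character(name), length(name) == 1)
  if (any(band_powers < 0)) stop("band powers must be >= 0")
  known <- c(names(band_definitions()), "broadband")
  if (!all(names(band_powers) %in% known)) {
    stop("unknown band name(s): ",
         paste(setdiff(names(band_powers), known), collapse = ", "))
  }
  if (coupling_asymmetry < 0 || coupling_asymmetry > 1) {
    stop("'coupling_asymmetry' must lie in [0, 1]")
  }
  if (mean_dwell_s <= 0) stop("'mean_dwell_s' must be > 0")
  structure(list(name = name, band_powers = band_powers,
                 coupling_asymmetry = coupling_asymmetry,
                 mean_dwell_s = mean_dwell_s),
            class = "stage_spec")
}

#' Default three-stage synthetic conditions
#'
#' Stage analogs of active-awake/REM (high gamma and theta, strongly
#' asymmetric coupling), quiet-awake (alpha-dominant, intermediate
#' asymmetry) and slow-wave sleep (delta-dominant, near-symmetric coupling,
#' longest dwell, so it occupies the largest share of the recording).
#'
#' @return list of three [stage_spec] objects.
#' @export
default_stage_specs <- function() {
  list(
    stage_spec("AA/REM",
               c(delta = 0.1, theta = 0.7, alpha = 0.2, beta = 0.3,
                 gamma = 0.9, broadband = 0.15),
               coupling_asymmetry = 0.9, mean_dwell_s = 120),
    stage_spec("QA",
               c(delta = 0.3, theta = 0.25, alpha = 0.9, beta = 0.2,
                 gamma = 0.15, broadband = 0.15),
               coupling_asymmetry = 0.5, mean_dwell_s = 120),
    stage_spec("SWS",
               c(delta = 1.0, theta = 0.15, alpha = 0.1, beta = 0.05,
                 gamma = 0.05, broadband = 0.15),
               coupling_asymmetry = 0.1, mean_dwell_s = 240)
  )
}

#' Default 64-channel system layout
#'
#' Thirty visual, twenty-one auditory and thirteen parietal channels.
#' @return named integer vector summing to 64.
#' @export
default_system_sizes <- function() {
  c(visual = 30L, auditory = 21L, parietal = 13L)
}

systems_from_sizes <- function(system_sizes, channel_ids) {
  setNames(rep(names(system_sizes), system_sizes), channel_ids)
}

# Band-shaped stage signal: white noise filtered into each requested band
# (zero-phase 4th-order Butterworth), coupled across channels by the VAR
# matrix A *after* filtering (so the planted arrow of time is localized to
# the bands that carry power), mixed with the stated relative powers. The
# "broadband" component is an uncoupled white floor. Each channel is
# standardized to unit SD. Returns channels x n matrix.
band_signal <- function(n_channels, n, fs, band_powers, A = NULL) {
  bands <- band_definitions()
  out <- matrix(0, n_channels, n)
  for (bn in names(band_powers)) {
    p <- band_powers[[bn]]
    if (p <= 0) next
    w <- matrix(rnorm(n_channels * n), n_channels, n)
    if (bn != "broadband") {
      rng <- bands[[bn]]
      lo <- rng[1]; hi <- min(rng[2], 0.45 * fs)
      if (lo >= hi) next
      bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
      for (i in seq_len(n_channels)) {
        w[i, ] <- signal::filtfilt(bf, w[i, ])
      }
      if (!is.null(A)) w <- .var_filter(A, w)
      w <- w / pmax(apply(w, 1, sd), 1e-12)
    }
    out <- out + sqrt(p) * w
  }
  sds <- apply(out, 1, sd)
  out / pmax(sds, 1e-12)
}

#' Ring coupling matrix with a prescribed asymmetry
#'
#' Diagonal autoregressive term plus a mixture of a symmetric
#' nearest-neighbour ring (time-reversible) and a unidirectional ring
#' (maximally directed), rescaled if necessary to keep the spectral radius
#' below `radius_max` so the implied VAR(1) process is stationary.
#'
#' @param n_channels matrix dimension.
#' @param asymmetry mixture weight of the unidirectional ring, in
#'   \[0, 1\].
#' @param strength off-diagonal coupling magnitude.
#' @param ar diagonal autoregressive coefficient.
#' @param radius_max spectral radius cap.
#' @return an `n_channels x n_channels` coupling matrix for
#'   [gen_var_recording()].
#' @export
build_coupling <- function(n_channels, asymmetry, strength = 0.35,
                           ar = 0.3, radius_max = 0.95) {
  idx <- seq_len(n_channels)
  nxt <- c(idx[-1], idx[1])
  Dir <- matrix(0, n_channels, n_channels)
  Dir[cbind(nxt, idx)] <- 1                 # channel i drives channel i+1
  Sym <- (Dir + t(Dir)) / 2
  A <- ar * diag(n_channels) +
    strength * (asymmetry * Dir + (1 - asymmetry) * Sym)
  r <- spectral_radius(A)
  if (r >= radius_max) A <- A * (radius_max / r)
  A
}

#' Generate a first-order vector-autoregressive recording
#'
#' Simulates `x[t] = coupling %*% x[t-1] + e[t]` with iid Gaussian
#' innovations. Asymmetric `coupling` plants a known arrow of time;
#' symmetric coupling (or none) yields a time-reversible process, the null
#' case for the irreversibility estimator.
#'
#' @param n_channels number of channels.
#' @param coupling `n_channels x n_channels` matrix with spectral radius
#'   < 1 (stationarity); a scalar is taken as `scalar * identity`.
#' @param noise_sd innovation standard deviation.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param seed integer RNG seed; output is bit-identical for a fixed seed.
#' @param system_of optional channel -> system map (see [recording]).
#' @return a [recording].
#' @examples
#' A <- matrix(0, 2, 2); A[2, 1] <- 0.8   # channel 1 drives channel 2
#' rec <- gen_var_recording(2, A, duration_s = 10, seed = 1)
#' @export
gen_var_recording <- function(n_channels, coupling, noise_sd = 1, fs = 100,
                              duration_s, seed, system_of = NULL) {
  if (length(coupling) == 1) coupling <- diag(n_channels) * as.numeric(coupling)
  coupling <- as.matrix(coupling)
  stopifnot(nrow(coupling) == n_channels, ncol(coupling) == n_channels)
  if (spectral_radius(coupling) >= 1) {
    stop("unstable coupling: spectral radius >= 1, process is non-stationary")
  }
  n <- round(duration_s * fs)
  set.seed(seed)
  e <- matrix(rnorm(n_channels * n, sd = noise_sd), n_channels, n)
  x <- .var_filter(coupling, e)
  recording(x, fs = fs, system_of = system_of)
}

#' Sample a Markov state sequence from a conditional transition matrix
#'
#' The chain starts from its stationary distribution, so empirical
#' transition frequencies are unbiased estimates of `P_cond` from the first
#' frame on.
#'
#' @param P_cond row-stochastic K x K conditional transition matrix.
#' @param n_steps sequence length.
#' @param seed integer RNG seed.
#' @param frame_rate frames per second recorded on the result (default 1).
#' @return a [state_sequence].
#' @examples
#' P <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE)
#' gen_markov_sequence(P, 10, seed = 1)
#' @export
gen_markov_sequence <- function(P_cond, n_steps, seed, frame_rate = 1) {
  P_cond <- as.matrix(P_cond)
  K <- nrow(P_cond)
  stopifnot(ncol(P_cond) == K, n_steps >= 1)
  if (any(P_cond < 0) || any(abs(rowSums(P_cond) - 1) > 1e-12)) {
    stop("'P_cond' rows must be non-negative and sum to 1 (tol 1e-12)")
  }
  set.seed(seed)
  labels <- sample_chain(P_cond, n_steps, init = stationary_dist(P_cond))
  state_sequence(labels, frame_rate = frame_rate, K = K)
}

# Stationary distribution of a row-stochastic matrix (leading left
# eigenvector, made real and normalized).
stationary_dist <- function(P) {
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- abs(v)
  v / sum(v)
}

# Sample n steps of a Markov chain given row-stochastic P and an initial
# distribution. Uses a single pre-drawn uniform stream for determinism.
sample_chain <- function(P, n, init) {
  K <- nrow(P)
  cp <- t(apply(P, 1, cumsum))
  u <- runif(n)
  labels <- integer(n)
  labels[1] <- findInterval(u[1], cumsum(init)) + 1L
  for (t in seq_len(n - 1L)) {
    labels[t + 1L] <- findInterval(u[t + 1L], cp[labels[t], ]) + 1L
  }
  pmin(labels, K)
}

# Alternating stage segments with exponential dwell times (uniform choice
# among the other stages at each switch). Segments are floored at ~50 ms /
# 15 frames so per-segment filtering and standardization stay well posed.
draw_segments <- function(n_total, fs, mean_dwells) {
  n_stages <- length(mean_dwells)
  min_len <- max(15L, round(0.05 * fs))
  seg_stage <- integer(0); seg_len <- integer(0)
  cur <- sample.int(n_stages, 1)
  filled <- 0L
  while (filled < n_total) {
    len <- max(min_len, round(rexp(1, rate = 1 / mean_dwells[cur]) * fs))
    len <- min(len, n_total - filled)
    if (n_total - filled - len < min_len) len <- n_total - filled
    seg_stage <- c(seg_stage, cur); seg_len <- c(seg_len, len)
    filled <- filled + len
    cur <- if (n_stages > 1) sample(setdiff(seq_len(n_stages), cur), 1) else cur
  }
  list(stage = seg_stage, len = seg_len)
}

# Per-stage network-state transition matrix. Persistence follows the
# stage's dwell scale; the off-diagonal kernel mixes a unidirectional cycle
# (weight = coupling asymmetry; breaks detailed balance) with a reversible
# preference kernel concentrated on a stage-favored state (weight grows
# with dwell, skewing occupancy for slow stages).
stage_network_P <- function(stage, stage_index, K, fs, dwell_frac = 0.1) {
  nd <- max(dwell_frac * stage$mean_dwell_s, 0.03)
  q <- exp(-1 / (fs * nd))
  a <- stage$coupling_asymmetry
  h <- min(0.8, stage$mean_dwell_s / 3)
  fav <- ((stage_index - 1L) %% K) + 1L
  w <- (1 - h) * rep(1 / K, K)
  w[fav] <- w[fav] + h
  Cyc <- matrix(0, K, K)
  Cyc[cbind(seq_len(K), c(seq_len(K)[-1], 1L))] <- 1
  M <- a * Cyc + (1 - a) * matrix(w, K, K, byrow = TRUE)
  q * diag(K) + (1 - q) * M
}

# Network-state mean patterns across the three systems: K well-separated
# points, scaled by 'sep' (in channel-SD units).
network_state_means <- function(K, n_systems, sep) {
  pats <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
                c(0, 0, 0), c(1, 0, -1), c(-1, 0, 1))
  pats <- pats[seq_len(K), seq_len(n_systems), drop = FALSE]
  sep * pats
}

#' Generate a staged multichannel recording with planted structure
#'
#' Concatenates stage segments with exponential dwell times. Each segment
#' carries (i) band-shaped innovation noise following the stage's spectral
#' signature, (ii) first-order VAR coupling whose asymmetry equals the
#' stage's `coupling_asymmetry` (the planted arrow of time), and (iii) a
#' hidden K-state Markov "network state" chain whose persistence, cycle
#' bias and occupancy skew derive from the stage parameters; each network
#' state adds a distinct mean offset pattern across the three systems.
#'
#' @param stages list of [stage_spec]; defaults to [default_stage_specs()].
#' @param n_channels total channels; must equal `sum(system_sizes)`.
#' @param system_sizes named integer vector of channels per system.
#' @param fs sampling rate in Hz.
#' @param duration_s total duration in seconds; must be at least the
#'   largest stage mean dwell.
#' @param seed integer RNG seed.
#' @param coupling_strength off-diagonal coupling magnitude shared by all
#'   stages (only its asymmetric fraction differs).
#' @param state_sep network-state mean separation in channel-SD units; 0
#'   disables the network-state layer.
#' @param n_network_states number of planted network states (K).
#' @param network_dwell_frac network-state dwell as a fraction of the stage
#'   dwell.
#' @return list with elements `recording` (a [recording]), `stages`
#'   (ground-truth frame-level [state_sequence] with stage names) and
#'   `network_states` (frame-level [state_sequence] of the planted chain).
#' @export
gen_stage_recording <- function(stages = default_stage_specs(),
                                n_channels = 64,
                                system_sizes = default_system_sizes(),
                                fs = 100, duration_s, seed,
                                coupling_strength = 0.35,
                                state_sep = 1.5,
                                n_network_states = 5,
                                network_dwell_frac = 0.1) {
  stopifnot(length(stages) >= 1, all(vapply(stages, inherits, TRUE,
                                            "stage_spec")))
  if (sum(system_sizes) != n_channels) {
    stop("'system_sizes' must sum to n_channels")
  }
  dwells <- vapply(stages, `[[`, numeric(1), "mean_dwell_s")
  if (duration_s < max(dwells)) {
    stop("duration_s (", duration_s, " s) is shorter than one mean dwell (",
         max(dwells), " s)")
  }
  n_total <- round(duration_s * fs)
  n_stages <- length(stages)
  K <- n_network_states
  channel_ids <- sprintf("ch%02d", seq_len(n_channels))
  system_of <- systems_from_sizes(system_sizes, channel_ids)
  sys_names <- names(system_sizes)
  sys_index <- match(system_of, sys_names)

  set.seed(seed)
  segs <- draw_segments(n_total, fs, vapply(stages, `[[`, 1, "mean_dwell_s"))
  seg_stage <- segs$stage; seg_len <- segs$len

  A_list <- lapply(stages, function(s) {
    build_coupling(n_channels, s$coupling_asymmetry,
                   strength = coupling_strength)
  })
  P_list <- lapply(seq_len(n_stages), function(i) {
    stage_network_P(stages[[i]], i, K, fs, network_dwell_frac)
  })
  mu <- network_state_means(K, length(sys_names), state_sep)

  data <- matrix(0, n_channels, n_total)
  stage_labels <- integer(n_total)
  net_labels <- integer(n_total)
  pos <- 0L
  for (si in seq_along(seg_stage)) {
    k <- seg_stage[si]; len <- seg_len[si]
    idx <- pos + seq_len(len)
    seg <- band_signal(n_channels, len, fs, stages[[k]]$band_powers,
                       A = A_list[[k]])
    if (state_sep > 0) {
      net <- sample_chain(P_list[[k]], len, init = stationary_dist(P_list[[k]]))
      # per-system mean offsets, channels x len
      seg <- seg + t(mu[net, sys_index, drop = FALSE])
      net_labels[idx] <- net
    } else {
      net_labels[idx] <- 1L
    }
    data[, idx] <- seg
    stage_labels[idx] <- k
    pos <- pos + len
  }

  rec <- recording(data, fs = fs, channel_ids = channel_ids,
                   system_of = system_of)
  list(
    recording = rec,
    stages = state_sequence(stage_labels, frame_rate = fs, K = n_stages,
                            state_names = vapply(stages, `[[`, "", "name")),
    network_states = state_sequence(net_labels, frame_rate = fs, K = K)
  )
}

#' Generate a low-rank recording with stage-dependent latent asymmetry
#'
#' Builds `k` latent first-order VAR coordinates whose directed-coupling
#' asymmetry switches with the behavioral stage, projects them onto
#' `n_channels` channels through a random orthonormal mixing matrix and adds
#' white sensor noise. The informative structure therefore lives in exactly
#' `k` latent directions — ground truth for autoencoder dimension sweeps.
#'
#' @param k planted latent dimensionality.
#' @param stage_asymmetries latent coupling asymmetry per stage.
#' @param mean_dwell_s mean stage dwell (seconds), shared by all stages.
#' @param n_channels observed channels.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param noise_sd sensor noise SD relative to unit-SD latent signal.
#' @param seed integer RNG seed.
#' @return list with `recording`, `stages` (frame-level [state_sequence])
#'   and `k`.
#' @export
gen_latent_recording <- function(k = 3, stage_asymmetries = c(0.9, 0.5, 0.1),
                                 mean_dwell_s = 20, n_channels = 64,
                                 fs = 100, duration_s, seed,
                                 noise_sd = 0.3) {
  n_stages <- length(stage_asymmetries)
  n_total <- round(duration_s * fs)
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(n_channels * k), n_channels, k)))
  A_list <- lapply(stage_asymmetries, function(a) {
    build_coupling(k, a, strength = 0.38, ar = 0.5)
  })

  segs <- draw_segments(n_total, fs, rep(mean_dwell_s, n_stages))
  seg_stage <- segs$stage; seg_len <- segs$len

  data <- matrix(0, n_channels, n_total)
  stage_labels <- integer(n_total)
  pos <- 0L
  for (si in seq_along(seg_stage)) {
    st <- seg_stage[si]; len <- seg_len[si]
    idx <- pos + seq_len(len)
    e <- matrix(rnorm(k * len), k, len)
    L <- .var_filter(A_list[[st]], e)
    L <- L / pmax(apply(L, 1, sd), 1e-12)
    data[, idx] <- sqrt(n_channels / k) * (W %*% L) +
      noise_sd * matrix(rnorm(n_channels * len), n_channels, len)
    stage_labels[idx] <- st
    pos <- pos + len
  }
  list(
    recording = recording(data, fs = fs),
    stages = state_sequence(stage_labels, frame_rate = fs, K = n_stages),
    k = k
  )
}
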