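test_that("shifted correlations match the flip-and-correlate oracle and its symmetry", {
  set.seed(11)
  x <- rnorm(200); y <- as.numeric(stats::filter(x, 0.5, "recursive")) + rnorm(200)
  sc <- shifted_correlation_pair(x, y, shift_frames = 1)
  n <- length(x)
  expect_equal(unname(sc["c_forward"]), cor(x[1:(n - 1)], y[2:n]))
  expect_equal(unname(sc["c_reversal"]),
               cor(rev(x)[1:(n - 1)], rev(y)[2:n]))
  # reversal of (x, y) equals forward of (y, x)
  sc_swap <- shifted_correlation_pair(y, x, shift_frames = 1)
  expect_equal(unname(sc["c_reversal"]), unname(sc_swap["c_forward"]),
               tolerance = 1e-12)
  # self-pair: forward and reversal coincide exactly
  sc_self <- shifted_correlation_pair(x, x)
  expect_equal(unname(sc_self["c_forward"]), unname(sc_self["c_reversal"]),
               tolerance = 1e-12)
  w <- capture_warnings(sc0 <- shifted_correlation_pair(rep(1, 50), rnorm(50)))
  expect_match(w, "zero-variance", all = TRUE)
  expect_true(all(is.na(sc0)))
})

test_that("windowed series matches the oracle and satisfies its invariants", {
  rec <- gen_var_recording(4, build_coupling(4, 0.7),
                           duration_s = 12, seed = 13)
  ser <- irreversibility_windows(rec)
  for (w in c(1, 5, 12)) {
    idx <- ((w - 1) * 100 + 1):(w * 100)
    for (pr in list(c(1, 2), c(2, 4), c(3, 4))) {
      expect_equal(ser$pair_matrix[pr[1], pr[2], w],
                   brute_irrev(rec$data[pr[1], idx], rec$data[pr[2], idx]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(apply(ser$pair_matrix, 3, function(M) all(diag(M) == 0))))
  expect_true(all(apply(ser$pair_matrix, 3, isSymmetric)))
  expect_true(all(ser$pair_matrix >= 0 & ser$pair_matrix <= 2))
  expect_true(all(ser$scalar >= 0))
  # two identical channels: zero pair value
  rec2 <- recording(rbind(rec$data[1, ], rec$data[1, ] ), fs = 100)
  ser2 <- irreversibility_windows(rec2)
  expect_lt(max(ser2$scalar), 1e-12)
  # trailing partial window is dropped with a log message
  rec3 <- recording(rec$data[, 1:250], fs = 100)
  expect_message(irreversibility_windows(rec3), "partial window")
})

test_that("null irreversibility shrinks with window count (reversible process)", {
  rec <- gen_var_recording(6, matrix(0, 6, 6), duration_s = 600, seed = 17)
  ser <- irreversibility_windows(rec)
  agg600 <- aggregate_irreversibility(ser)
  # 60-s envelope: per-pair |signed mean| over the first 60 windows
  p <- 6
  ut <- upper.tri(matrix(0, p, p))
  pm60 <- apply(ser$signed[, , 1:60], c(1, 2), mean)
  vals60 <- abs(pm60[ut])
  envelope <- mean(vals60) + 2 * sd(vals60)
  expect_lt(agg600, 0.25 * envelope)
  expect_lt(agg600, mean(vals60))
})

test_that("irreversibility increases with planted unidirectional coupling strength", {
  agg <- vapply(c(0.2, 0.5, 0.8), function(cc) {
    A <- matrix(0, 2, 2); A[2, 1] <- cc
    aggregate_irreversibility(
      irreversibility_windows(gen_var_recording(2, A, duration_s = 300,
                                                seed = 19)))
  }, numeric(1))
  expect_true(all(diff(agg) > 0))
})

test_that("resampling preserves in-band content and removes above-Nyquist content", {
  t0 <- seq(1 / 1000, 10, by = 1 / 1000)
  rec <- recording(rbind(sin(2 * pi * 10 * t0) + 0.1 * rnorm(10000),
                         sin(2 * pi * 300 * t0)), fs = 1000)
  expect_identical(resample_recording(rec, 1000), rec)
  expect_error(resample_recording(rec, 2000), "upsampling")
  dn <- resample_recording(rec, 100)
  expect_equal(dn$fs, 100)
  expect_equal(ncol(dn$data), 1000)
  spec1 <- Mod(fft(dn$data[1, ]))^2
  freqs <- (seq_len(500) - 1) * 100 / 1000
  expect_equal(freqs[which.max(spec1[1:500])], 10, tolerance = 0.2)
  expect_lt(sd(dn$data[2, ]), 0.02 * sd(rec$data[2, ]))
})

test_that("system decomposition partitions pairs and localizes planted asymmetry", {
  # asymmetry confined to the 'parietal' block
  p <- 9
  A <- matrix(0, p, p)
  par_idx <- 7:9
  A[cbind(c(8, 9, 7), c(7, 8, 9))] <- 0.7   # directed ring among parietal
  sys <- setNames(rep(c("visual", "auditory", "parietal"), each = 3),
                  sprintf("ch%02d", 1:p))
  rec <- gen_var_recording(p, A, duration_s = 300, seed = 23,
                           system_of = sys)
  ser <- irreversibility_windows(rec)
  grp <- group_by_system(ser)
  expect_gt(grp$summary$parietal, grp$summary$visual * 3)
  expect_gt(grp$summary$parietal, grp$summary$auditory * 3)
  # pair partition: within + between = all pairs
  masks <- neuroarrow:::system_pair_masks(unname(sys))
  ut <- upper.tri(matrix(0, p, p))
  expect_equal(sum(masks$within & ut) + sum(masks$between & ut),
               p * (p - 1) / 2)
  # single system: between summary is missing
  rec1 <- recording(rec$data[1:3, ], fs = 100)
  g1 <- group_by_system(irreversibility_windows(rec1))
  expect_true(is.na(g1$summary$between))
})

test_that("band means are arithmetic means of their member 1-Hz bins", {
  rec <- gen_var_recording(3, build_coupling(3, 0.8),
                           duration_s = 60, seed = 29)
  bp <- suppressWarnings(band_sweep(rec, lo = 0, hi = 20))
  expect_equal(bp$band_means[["theta"]],
               mean(bp$irreversibility_per_bin[bp$bin_lo_hz %in% 4:6]))
  expect_equal(bp$band_means[["delta"]],
               mean(bp$irreversibility_per_bin[bp$bin_lo_hz %in% 1:3]))
  expect_true(is.na(bp$band_means[["gamma"]]))  # above the sweep range
  expect_error(band_sweep(rec, hi = 80), "Nyquist")
})
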