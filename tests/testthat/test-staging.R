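test_that("spectrogram features have the stated geometry and standardization", {
  set.seed(31)
  rec <- recording(matrix(rnorm(4 * 300 * 256), 4), fs = 256)
  feat <- compute_stage_features(rec)
  # epoch count = floor((duration - win) / step) + 1
  expect_equal(nrow(feat$z_power), (300 - 60) %/% 5 + 1)
  expect_equal(length(feat$freqs_hz), 14)
  expect_true(all(feat$freqs_hz <= 128))
  expect_equal(colMeans(feat$z_power), rep(0, 14), tolerance = 1e-8)
  expect_equal(apply(feat$z_power, 2, sd), rep(1, 14), tolerance = 1e-8)
  expect_false(any(feat$artifact_mask))
})

test_that("frequencies above Nyquist are dropped with a warning", {
  set.seed(32)
  rec <- recording(matrix(rnorm(2 * 100 * 64), 2), fs = 64)
  expect_warning(feat <- compute_stage_features(rec), "Nyquist")
  expect_true(all(feat$freqs_hz <= 32))
})

test_that("a planted oscillatory burst raises z-power at the nearest frequency", {
  set.seed(33)
  fs <- 256
  x <- matrix(rnorm(2 * 300 * fs), 2)
  burst <- seq(120 * fs, 180 * fs)   # 60-s burst of a 10-Hz rhythm
  x[, burst] <- x[, burst] +
    rep(5 * sin(2 * pi * 10 * (burst / fs)), each = nrow(x))
  feat <- compute_stage_features(recording(x, fs = fs))
  fi <- which.min(abs(feat$freqs_hz - 10))
  in_burst <- feat$times_s > 125 & feat$times_s < 175
  expect_gt(mean(feat$z_power[in_burst, fi]),
            mean(feat$z_power[!in_burst, fi]) + 1)
})

test_that("artifact rejection pads around extreme epochs", {
  feat <- structure(
    list(times_s = seq(30, 600, by = 5), freqs_hz = neuroarrow:::logspace(0.5, 128, 14),
         z_power = matrix(0, 115, 14), artifact_mask = rep(FALSE, 115),
         step_s = 5, win_s = 60),
    class = "spectro_features")
  feat$z_power[55, ] <- 20
  out <- reject_artifacts(feat)
  expect_true(out$artifact_mask[55])
  expect_true(all(out$artifact_mask[53:57]))   # +/- 10 s at a 5-s step
  expect_false(any(out$artifact_mask[-(53:57)]))
  # infinite threshold masks nothing
  expect_false(any(reject_artifacts(feat, z_thresh = Inf)$artifact_mask))
  feat$z_power[] <- 20
  expect_error(reject_artifacts(feat), "all epochs")
})

test_that("clustering is deterministic and respects trivial structure", {
  set.seed(35)
  feat <- structure(
    list(times_s = seq(30, 300, by = 5), freqs_hz = neuroarrow:::logspace(0.5, 128, 14),
         z_power = matrix(rnorm(55 * 14), 55, 14),
         artifact_mask = rep(FALSE, 55), step_s = 5, win_s = 60),
    class = "spectro_features")
  s1 <- cluster_stages(feat, k = 3, seed = 4)
  s2 <- cluster_stages(feat, k = 3, seed = 4)
  expect_identical(s1$labels, s2$labels)
  sk1 <- cluster_stages(feat, k = 1, seed = 4)
  expect_true(all(sk1$labels == 1L))
  # artifact epochs receive no label
  feat$artifact_mask[1:5] <- TRUE
  s3 <- cluster_stages(feat, k = 2, seed = 4)
  expect_true(all(is.na(s3$labels[1:5])))
  expect_false(anyNA(s3$labels[-(1:5)]))
})

test_that("stage naming follows spectral content and ignores label order", {
  # construct three clusters with transparent spectra:
  # cluster 1 delta-dominant, cluster 2 gamma-dominant, cluster 3 flat
  freqs <- neuroarrow:::logspace(0.5, 128, 14)
  z <- matrix(0, 90, 14)
  lab <- rep(1:3, each = 30)
  z[lab == 1, freqs <= 4] <- 2
  z[lab == 2, freqs >= 30] <- 2
  feat <- structure(
    list(times_s = seq_len(90) * 5, freqs_hz = freqs, z_power = z,
         artifact_mask = rep(FALSE, 90), step_s = 5, win_s = 60),
    class = "spectro_features")
  seq1 <- state_sequence(lab, frame_rate = 0.2, K = 3)
  named <- assign_stage_names(seq1, feat)
  expect_equal(named$state_names, c("SWS", "AA/REM", "QA"))
  # permuting the cluster indices leaves the name-to-content map unchanged
  perm <- c(3L, 1L, 2L)           # relabel clusters
  seq2 <- state_sequence(perm[lab], frame_rate = 0.2, K = 3)
  named2 <- assign_stage_names(seq2, feat)
  expect_equal(named2$state_names[perm], named$state_names)
})
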