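test_that("backpropagated gradients match numerical differentiation", {
  set.seed(63)
  spec <- autoencoder_spec(d = 2, n_channels = 6, batch = 8)
  params <- neuroarrow:::ae_init_params(spec)
  X <- matrix(rnorm(8 * 6), 8, 6)
  lg <- neuroarrow:::ae_loss_grad(params, spec, X)
  eps <- 1e-6
  for (l in c(1, 3, 4, 6)) {
    for (nm in c("W", if (spec$batchnorm[l]) "gamma")) {
      g <- lg$grads[[l]][[nm]]
      for (ix in sample(length(g), min(4, length(g)))) {
        p2 <- params
        p2[[l]][[nm]][ix] <- p2[[l]][[nm]][ix] + eps
        lp <- neuroarrow:::ae_loss_grad(p2, spec, X)$loss
        p2[[l]][[nm]][ix] <- p2[[l]][[nm]][ix] - 2 * eps
        lm <- neuroarrow:::ae_loss_grad(p2, spec, X)$loss
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[ix], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("architecture widths mirror the 1 : 0.5 : 0.25 : d contraction", {
  sp <- autoencoder_spec(d = 7, n_channels = 64)
  expect_equal(sp$widths, c(64, 32, 16, 7, 16, 32, 64))
  expect_equal(sp$batchnorm, c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  sp2 <- autoencoder_spec(d = 3, n_channels = 32)
  expect_equal(sp2$widths, c(32, 16, 8, 3, 8, 16, 32))
})

test_that("training reconstructs planted low-rank structure below the noise floor", {
  lat <- gen_latent_recording(k = 3, duration_s = 140, seed = 65,
                              noise_sd = 0.5)
  spec <- autoencoder_spec(3, 64, max_epochs = 100, patience = 100)
  ae <- train_autoencoder(lat$recording, spec = spec, seed = 67)
  # injected sensor-noise variance on the standardized training scale:
  # sigma^2 referred to each channel's own variance, averaged over channels
  noise_floor <- mean(0.5^2 / apply(lat$recording$data, 1, var))
  expect_lt(ae$val_mse, noise_floor)
  # capacity: within 10 % of the optimal rank-3 linear reconstruction
  X <- scale(t(lat$recording$data))
  pc <- prcomp(X)
  pca3 <- mean((pc$x[, 1:3] %*% t(pc$rotation[, 1:3]) - X)^2)
  expect_lt(ae$val_mse, 1.1 * pca3)
  expect_lte(min(ae$history$val_mse), ae$history$val_mse[1])
  # recorded validation MSE is exactly the held-out reconstruction error
  expect_equal(reconstruction_mse(ae, lat$recording, frames = ae$val_idx),
               ae$val_mse, tolerance = 1e-10)
  # determinism
  ae2 <- train_autoencoder(lat$recording, spec = spec, seed = 67)
  expect_identical(ae$val_mse, ae2$val_mse)

  tr <- encode_recording(lat$recording, ae)
  expect_equal(nrow(tr$values), 3)
  expect_identical(tr$binary, (tr$values > 0) * 1L)
  expect_error(encode_recording(recording(matrix(rnorm(200), 4), 100), ae),
               "channels")
})

test_that("entropy features have pair combinatorics and match direct evaluation", {
  set.seed(69)
  vals <- matrix(rnorm(7 * 2000), 7)
  tr <- latent_trace(vals, fs = 100)
  fw <- suppressWarnings(
    entropy_feature_windows(tr, window_s = 5, pseudocount = 0))
  expect_equal(ncol(fw$features), 7 * 6 / 2)
  expect_equal(nrow(fw$features), 4)
  # oracle: direct enumeration for a chosen pair/window
  b <- tr$binary
  for (w in 1:2) {
    idx <- ((w - 1) * 500 + 1):(w * 500)
    s4 <- 1 + b[1, idx] + 2 * b[2, idx]
    expect_equal(unname(fw$features[w, "1|2"]),
                 brute_entropy_production(s4, 4), tolerance = 1e-10)
  }
})

test_that("balanced classification is calibrated, separable and deterministic", {
  set.seed(71)
  n <- 90
  y <- rep(1:3, each = n / 3)
  # one perfectly separating feature plus noise
  X <- cbind(y + 0.01 * rnorm(n), matrix(rnorm(n * 3), n))
  cls <- balanced_stage_classification(X, y, seed = 3, n_undersample = 3,
                                       n_splits = 5, num_trees = 100)
  expect_gt(cls$mean_accuracy, 0.95)

  # label shuffling drops accuracy to chance
  y_sh <- sample(y)
  cls0 <- balanced_stage_classification(X[, 2:4], y_sh, seed = 3,
                                        n_undersample = 3, n_splits = 5,
                                        num_trees = 100)
  se <- sd(cls0$accuracies) / sqrt(length(cls0$accuracies))
  expect_lt(abs(cls0$mean_accuracy - 1 / 3), 4 * se + 0.05)

  # fixed seed reproduces the full accuracy distribution
  cls2 <- balanced_stage_classification(X, y, seed = 3, n_undersample = 3,
                                        n_splits = 5, num_trees = 100)
  expect_identical(cls$accuracies, cls2$accuracies)

  expect_error(balanced_stage_classification(X, rep(1, n)), "2 stages")
  expect_error(balanced_stage_classification(X[1:12, ], y[c(1:10, 31:32)]),
               "counts")
})
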