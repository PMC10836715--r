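test_that("VAR generator is deterministic, stationary and rejects unstable coupling", {
  A <- matrix(c(0.3, 0.2, 0.2, 0.3), 2, 2)
  r1 <- gen_var_recording(2, A, duration_s = 10, seed = 7)
  r2 <- gen_var_recording(2, A, duration_s = 10, seed = 7)
  expect_identical(r1$data, r2$data)

  expect_error(gen_var_recording(2, diag(2) * 1.01, duration_s = 1, seed = 1),
               "spectral radius")

  # weak stationarity: first/second-half channel variances within 10 %
  r <- gen_var_recording(4, build_coupling(4, 0.5),
                         duration_s = 300, seed = 3)
  n <- ncol(r$data)
  v1 <- apply(r$data[, 1:(n / 2)], 1, var)
  v2 <- apply(r$data[, (n / 2 + 1):n], 1, var)
  expect_true(all(abs(v1 - v2) / v1 < 0.10))
})

test_that("planted coupling asymmetry drives irreversibility; symmetric and iid are null", {
  A_sym <- matrix(0, 2, 2); A_sym[1, 2] <- A_sym[2, 1] <- 0.4
  A_uni <- matrix(0, 2, 2); A_uni[2, 1] <- 0.8
  r_noise <- gen_var_recording(2, matrix(0, 2, 2), duration_s = 600, seed = 5)
  r_sym <- gen_var_recording(2, A_sym, duration_s = 600, seed = 5)
  r_uni <- gen_var_recording(2, A_uni, duration_s = 600, seed = 5)
  agg <- function(r) aggregate_irreversibility(irreversibility_windows(r))
  expect_lt(agg(r_noise), 0.02)
  expect_lt(agg(r_sym), 0.02)
  expect_gt(agg(r_uni), 5 * agg(r_sym))
})

test_that("Markov sequence generator reproduces its transition matrix", {
  expect_error(gen_markov_sequence(matrix(c(0.5, 0.4, 0.3, 0.7), 2), 10, 1),
               "sum to 1")

  s_const <- gen_markov_sequence(diag(3), 50, seed = 2)
  expect_equal(length(unique(s_const$labels)), 1)

  P <- cycle3(0.9)
  s <- gen_markov_sequence(P, 1e5, seed = 4)
  emp <- estimate_transitions(s)$conditional
  expect_lt(max(abs(emp - P)), 0.01)

  s2 <- gen_markov_sequence(P, 1000, seed = 4)
  expect_identical(s$labels[1:1000], s2$labels)
})

test_that("stage recording plants labels, geometry and dwell structure", {
  one <- list(stage_spec("only", c(broadband = 1), 0.5, 2))
  syn <- gen_stage_recording(one, n_channels = 4,
                             system_sizes = c(a = 2, b = 2), fs = 50,
                             duration_s = 20, seed = 9, state_sep = 0)
  expect_true(all(syn$stages$labels == 1L))
  expect_equal(dim(syn$recording$data), c(4, 1000))

  expect_error(gen_stage_recording(one, n_channels = 5,
                                   system_sizes = c(a = 2, b = 2),
                                   duration_s = 20, seed = 1),
               "sum to n_channels")
  expect_error(gen_stage_recording(one, n_channels = 4,
                                   system_sizes = c(a = 2, b = 2),
                                   duration_s = 1, seed = 1),
               "mean dwell")

  syn64 <- gen_stage_recording(fs = 100, duration_s = 300, seed = 2)
  expect_equal(as.vector(table(syn64$recording$system_of)[c("visual",
                                                            "auditory",
                                                            "parietal")]),
               c(30L, 21L, 13L))
  expect_equal(syn64$network_states$K, 5L)
  expect_false(anyNA(syn64$recording$data))
})

test_that("latent recording is low rank with stage labels covering all stages", {
  lat <- gen_latent_recording(k = 3, duration_s = 120, seed = 6)
  expect_equal(nrow(lat$recording$data), 64)
  expect_setequal(unique(lat$stages$labels), 1:3)
  # rank structure: top-3 PCs carry most of the variance
  pv <- prcomp(t(lat$recording$data))$sdev^2
  expect_gt(sum(pv[1:3]) / sum(pv), 0.8)
})
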