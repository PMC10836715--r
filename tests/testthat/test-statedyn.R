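test_that("state-sequence summaries match hand-counted values", {
  expect_equal(switching_rate(c(1, 1, 2, 2, 2, 3)), 0.4)
  expect_equal(switching_rate(rep(1, 10)), 0)
  expect_equal(switching_rate(rep(1:2, 10)), 1)
  expect_error(switching_rate(1), "length")

  expect_equal(fractional_occupancy(c(1, 1, 2, 3)), c(0.5, 0.25, 0.25))
  expect_equal(max_fractional_occupancy(c(1, 1, 2, 3)), 0.5)
  for (n in c(5, 17, 40)) {
    x <- sample(1:4, n, replace = TRUE)
    expect_equal(sum(fractional_occupancy(x, K = 4)), 1)
  }

  lt <- average_lifetime(c(1, 1, 2, 2, 2, 1), frame_rate = 1, K = 2)
  expect_equal(lt$per_state, c(1.5, 3))
  expect_equal(lt$overall, 2)
  # conservation: visits x mean lifetime sums to the sequence length
  x <- sample(1:3, 200, replace = TRUE)
  lt2 <- average_lifetime(x, frame_rate = 1, K = 3)
  expect_equal(sum(lt2$n_visits * lt2$per_state), 200)
  lt_const <- average_lifetime(rep(2, 30), frame_rate = 10, K = 2)
  expect_equal(lt_const$per_state[2], 3)   # 30 frames at 10 Hz
})

test_that("transition estimation matches hand counts and normalizations", {
  tm <- estimate_transitions(c(1, 2, 1, 2, 1), K = 2)
  expect_equal(tm$joint, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(rowSums(tm$conditional), c(1, 1))
  expect_equal(tm$occupancy, rowSums(tm$joint))

  tm_const <- estimate_transitions(rep(2, 10), K = 3)
  expect_equal(tm_const$joint[2, 2], 1)
  expect_equal(sum(tm_const$joint), 1)

  # NA frames break the chain rather than bridging across
  tm_na <- estimate_transitions(c(1, 1, NA, 2, 2), K = 2)
  expect_equal(tm_na$joint, matrix(c(0.5, 0, 0, 0.5), 2, 2))
})

test_that("entropy production matches closed forms and is relabeling invariant", {
  # symmetric joint: detailed balance, S = 0 exactly
  J <- matrix(c(0.3, 0.2, 0.2, 0.3), 2, 2)
  expect_identical(entropy_production(transition_model(J)), 0)
  expect_identical(entropy_production(transition_model(diag(3) / 3)), 0)

  # 3-state cycle with uniform occupancy: S = 0.8 ln 9 exactly
  Jc <- cycle3(0.9) / 3
  expect_equal(entropy_production(transition_model(Jc)), 0.8 * log(9),
               tolerance = 1e-12)
  expect_equal(entropy_production(transition_model(Jc), units = "bits"),
               0.8 * log2(9), tolerance = 1e-12)

  # invariance under simultaneous state relabeling
  perm <- c(3, 1, 2)
  Jp <- Jc[perm, perm]
  expect_equal(entropy_production(transition_model(Jp)),
               entropy_production(transition_model(Jc)))

  # zero reverse probability: infinite, with a warning
  J0 <- matrix(c(0.5, 0.5, 0, 0), 2, 2, byrow = TRUE)
  expect_warning(s <- entropy_production(transition_model(J0)), "infinite")
  expect_identical(s, Inf)
})

test_that("entropy-production estimator is consistent on sampled cycle chains", {
  s <- gen_markov_sequence(cycle3(0.9), 1e4, seed = 41)
  est <- entropy_production(estimate_transitions(s))
  expect_lt(abs(est - 0.8 * log(9)) / (0.8 * log(9)), 0.10)
  expect_equal(est, brute_entropy_production(s$labels, 3), tolerance = 1e-12)

  s_sym <- gen_markov_sequence(matrix(c(0.7, 0.3, 0.3, 0.7), 2,
                                      byrow = TRUE), 1e4, seed = 43)
  expect_lt(entropy_production(estimate_transitions(s_sym)), 0.01)
})

test_that("determinism, degeneracy and mutual information match worked values", {
  cond <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  tm <- transition_model(cond * 0.5)        # uniform occupancy
  expect_equal(determinism(tm), 0.26550, tolerance = 1e-5)
  expect_equal(degeneracy(tm), 0.11871, tolerance = 1e-5)

  # permutation matrix: fully deterministic
  P4 <- diag(4)[c(2, 3, 4, 1), ]
  expect_equal(determinism(transition_model(P4 / 4)), 1)
  # uniform rows: zero determinism; doubly stochastic: zero degeneracy
  U <- matrix(1 / 9, 3, 3)
  expect_equal(determinism(transition_model(U)), 0)
  expect_equal(degeneracy(transition_model(U)), 0)
  # everything feeds one state: maximal degeneracy
  F1 <- cbind(c(0.5, 0.5), c(0, 0))
  expect_equal(degeneracy(transition_model(F1)), 1)

  expect_equal(mutual_information(
    transition_model(matrix(c(0.4, 0.1, 0.1, 0.4), 2))), 0.27807,
    tolerance = 1e-5)
  # independence: MI = 0; deterministic uniform permutation: MI = log2 K
  pi2 <- c(0.3, 0.7)
  expect_equal(mutual_information(transition_model(outer(pi2, pi2))), 0,
               tolerance = 1e-12)
  expect_equal(mutual_information(transition_model(P4 / 4)), 2)
  # MI bounded by the marginal entropies
  s <- gen_markov_sequence(cycle3(0.8), 2000, seed = 47)
  tm_s <- estimate_transitions(s)
  h_min <- min(neuroarrow:::shannon_entropy(rowSums(tm_s$joint)),
               neuroarrow:::shannon_entropy(colSums(tm_s$joint)))
  expect_lte(mutual_information(tm_s), h_min + 1e-12)
})

test_that("pairwise entropy production detects directed binary coupling", {
  set.seed(51)
  n <- 4000
  a <- rbinom(n, 1, 0.5)
  b_ind <- rbinom(n, 1, 0.5)
  b_lag <- c(0L, a[-n])                      # a drives b at one frame lag
  tr_ind <- rbind(a, b_ind)
  tr_lag <- rbind(a, b_lag)
  s_ind <- pairwise_entropy_production(tr_ind, window = n)
  s_lag <- pairwise_entropy_production(tr_lag, window = n)
  expect_lt(s_ind[1, 1], 0.02)
  expect_gt(s_lag[1, 1], 10 * s_ind[1, 1])

  # oracle equivalence per window, pseudocount-free
  tr <- rbind(a[1:600], b_lag[1:600])
  s <- suppressWarnings(
    pairwise_entropy_production(tr, window = 200, pseudocount = 0))
  for (w in 1:3) {
    idx <- ((w - 1) * 200 + 1):(w * 200)
    s4 <- 1 + tr[1, idx] + 2 * tr[2, idx]
    expect_equal(unname(s[w, 1]), brute_entropy_production(s4, 4),
                 tolerance = 1e-10)
  }
})

test_that("leakage correction orthogonalizes and preserves orthogonal input", {
  set.seed(53)
  n <- 2000
  base <- rnorm(n)
  X <- rbind(base + 0.3 * rnorm(n), base + 0.3 * rnorm(n), rnorm(n))
  rec <- recording(X, fs = 100)
  expect_gt(cor(X[1, ], X[2, ]), 0.8)
  out <- leakage_correct(rec)
  C <- cor(t(out$data))
  expect_lt(max(abs(C - diag(3))), 1e-8)
  # orthogonal input is a fixed point up to scale
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  rec_o <- recording(t(Q), fs = 100)
  out_o <- leakage_correct(rec_o)
  for (i in 1:3) expect_gt(abs(cor(out_o$data[i, ], rec_o$data[i, ])), 0.999999)
  # rank deficiency is reported with the offending channel
  bad <- recording(rbind(base, base, rnorm(n)), fs = 100)
  expect_error(leakage_correct(bad), "rank-deficient")
})

test_that("region PCA reduces each system to a sign-aligned first component", {
  set.seed(57)
  n <- 1000
  common <- rnorm(n)
  X <- rbind(common, common, common,            # rank-1 'visual' system
             rnorm(n), rnorm(n),                # noise 'auditory'
             rnorm(n), rnorm(n))
  sys <- setNames(c("visual", "visual", "visual", "auditory", "auditory",
                    "parietal", "parietal"), sprintf("ch%02d", 1:7))
  rec <- recording(X, fs = 100, system_of = sys)
  out <- region_pca_signals(rec)
  expect_equal(nrow(out$data), 3)
  expect_setequal(out$channel_ids, c("visual", "auditory", "parietal"))
  ev <- attr(out, "explained_variance")
  expect_gt(ev[["visual"]], 0.99)
  expect_gt(cor(out$data[out$channel_ids == "visual", ], common), 0.999)
})

test_that("EM recovers planted Gaussian regimes with monotone likelihood", {
  set.seed(59)
  n <- 3000
  truth <- rep(rep(1:2, length.out = 60), each = n / 60)
  mu <- rbind(c(0, 0, 0), c(5, -5, 5))        # 5-SD separation
  X <- mu[truth, ] + matrix(rnorm(n * 3), n, 3)
  rec <- recording(t(X), fs = 100,
                   system_of = setNames(c("a", "b", "c"),
                                        c("ch01", "ch02", "ch03")))
  fit <- fit_network_states(rec, K = 2, seed = 61, n_restarts = 2)
  expect_gte(perm_accuracy(fit$states$labels, truth, 2), 0.95)
  expect_true(all(diff(fit$log_lik) > -1e-8 * abs(fit$log_lik[-1])))
  expect_equal(rowSums(fit$state_posteriors), rep(1, n), tolerance = 1e-8)

  fit1 <- fit_network_states(rec, K = 1, seed = 61, n_restarts = 1)
  expect_equal(fractional_occupancy(fit1$states), 1)
})

test_that("per-stage metrics respect stage boundaries and reduce to global", {
  seq1 <- state_sequence(c(1, 1, 2, 2, 3, 3, 1, 2), frame_rate = 1, K = 3)
  one_stage <- state_sequence(rep(1L, 8), frame_rate = 1, K = 1)
  m <- suppressWarnings(per_stage_metrics(seq1, one_stage, pseudocount = 0))
  expect_equal(nrow(m), 1)
  expect_equal(m$switching_rate, switching_rate(seq1))
  expect_equal(m$max_fo, max_fractional_occupancy(seq1))
  expect_equal(m$mean_lifetime_s, average_lifetime(seq1)$overall)

  # boundary transitions belong to neither stage
  stages <- state_sequence(c(1, 1, 1, 1, 2, 2, 2, 2), frame_rate = 1, K = 2)
  lab <- seq1$labels
  counts_global <- neuroarrow:::transition_counts(lab, 3)
  counts_1 <- neuroarrow:::transition_counts(lab[1:4], 3)
  counts_2 <- neuroarrow:::transition_counts(lab[5:8], 3)
  boundary <- matrix(0, 3, 3)
  boundary[lab[4], lab[5]] <- 1
  expect_equal(counts_1 + counts_2 + boundary, counts_global)
  m2 <- suppressWarnings(per_stage_metrics(seq1, stages, pseudocount = 0))
  expect_equal(m2$switching_rate[1], switching_rate(lab[1:4]))
  expect_equal(m2$switching_rate[2], switching_rate(lab[5:8]))
})
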