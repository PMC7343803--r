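test_that("channel responses are rectified projections of the drive", {
  b <- make_channel_basis(9, 8)
  S <- stimulus_vector(40)
  # zero drive, zero noise -> zero response
  C0 <- simulate_channel_responses(b$M, S,
    phi = 0, neural_mean = 0,
    neural_sd = 0
  )
  expect_equal(as.vector(C0), rep(0, 9))
  # noiseless response peaks at the channel aligned with the stimulus
  C <- simulate_channel_responses(b$M, S,
    phi = 1, neural_mean = 0,
    neural_sd = 0
  )
  expect_equal(which.max(C), which.min(circ_dist180(b$centers, 40)))
  # rectification floor
  set.seed(1)
  Cn <- simulate_channel_responses(b$M, S, phi = 1, n_trials = 50)
  expect_true(all(Cn >= 0))
})

test_that("noise calibration hits the target signal-to-noise ratio", {
  W <- matrix(1, 1, 1)
  C <- matrix(c(0, 0.7, 1.4), 1, 3) # sd of W %*% C entries = 0.7
  expect_equal(calibrate_noise(W, C, 0.7), 1)
  expect_equal(calibrate_noise(W, 2 * C, 0.7), 2)
  expect_error(calibrate_noise(W, matrix(1, 1, 3), 0.7), "degenerate")
  expect_error(calibrate_noise(W, C, 0), "positive")
  # empirical SNR of a simulated participant within 10% of 0.7
  tab <- generate_trial_table(3, seed = 5)
  sim <- simulate_participant(tab, modulation_params(),
    sim_config(n_voxels = 80),
    seed = 6
  )
  # regenerate the same participant without noise to isolate the signal
  sim0 <- simulate_participant(
    tab, modulation_params(),
    sim_config(n_voxels = 80, noise = FALSE), seed = 6
  )
  # signal sd over bold noise sd
  expect_equal(
    stats::sd(sim0$train$responses) / sim$bold_sd, 0.7,
    tolerance = 0.1
  )
})

test_that("participant simulation matches the study design", {
  tab <- generate_trial_table(3, seed = 9)
  sim <- simulate_participant(tab, modulation_params(phi_test = 0.6),
    config = sim_config(n_voxels = 50), seed = 10
  )
  expect_equal(dim(sim$train$responses), c(72, 50))
  expect_equal(dim(sim$test$responses), c(72, 50))
  # voxel weights: uniform draws normalized to unit row sums
  expect_equal(rowSums(sim$W), rep(1, 50), tolerance = 1e-12)
  # run-matched: test runs repeat the training stimuli
  expect_identical(sim$train$orientation, sim$test$orientation)
  expect_identical(sim$train$run_id, sim$test$run_id)
  # ... with independent noise
  expect_false(identical(sim$train$responses, sim$test$responses))
  # determinism
  sim2 <- simulate_participant(tab, modulation_params(phi_test = 0.6),
    config = sim_config(n_voxels = 50), seed = 10
  )
  expect_identical(sim$test$responses, sim2$test$responses)
  # remembered orientation is the cued side
  expect_equal(
    sim$train$orientation,
    ifelse(tab$cued_side == "left", tab$orient_left, tab$orient_right)
  )
})

test_that("full-size defaults produce 432 x 200 blocks", {
  tab <- generate_trial_table(18, seed = 2)
  sim <- simulate_participant(tab, modulation_params(), sim_config(),
    seed = 3
  )
  expect_equal(dim(sim$train$responses), c(432, 200))
})

test_that("gain suppression lowers noiseless fidelity as gamma grows", {
  tab <- generate_trial_table(2, seed = 21)
  cfg <- sim_config(n_voxels = 40, noise = FALSE)
  gammas <- seq(0, 1, by = 0.125)
  rf_at_gamma <- vapply(gammas, function(g) {
    sim <- simulate_participant(
      tab, modulation_params(phi_test = 1, gamma = g), cfg,
      seed = 22
    )
    cv <- crossval_reconstruct(sim$train, sim$test, zscore = FALSE)
    unname(cv$rf)
  }, numeric(1))
  # strictly decreasing while channel gains stay positive (gamma <= 0.5);
  # beyond that the firing-rate floor clips inverted responses and the
  # suppression saturates (non-increasing up to ~1e-3 rectification ripple)
  expect_true(all(diff(rf_at_gamma[gammas <= 0.5]) < 0))
  expect_true(all(diff(rf_at_gamma) < 1e-3))
  expect_gt(rf_at_gamma[1], 0)
  expect_lt(rf_at_gamma[length(gammas)], 0) # suppression inverts the curve
})

test_that("pseudo-experiment covers states per epoch and is reproducible", {
  part <- tiny_participant(n_runs = 2, n_voxels = 20, seed = 31)
  expect_s3_class(part, "wm_participant")
  bl <- part$hemispheres$left$blocks
  expect_setequal(unique(bl$stimulus$state), "stim")
  expect_setequal(unique(bl$delay1$state), c("cued", "fut_rel", "fut_irr"))
  expect_setequal(unique(bl$delay2$state), c("cued", "fut_irr"))
  # delay-2 block holds RB trials only
  rb_ids <- part$table$trial_id[part$table$condition == "RB"]
  expect_setequal(bl$delay2$trial_id, rb_ids)
  part2 <- tiny_participant(n_runs = 2, n_voxels = 20, seed = 31)
  expect_identical(bl$delay1$responses, part2$hemispheres$left$blocks$delay1$responses)
  expect_error(
    simulate_pseudo_experiment(part$table,
      state_params = list(stim = modulation_params())
    ),
    "missing state parameters"
  )
})
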