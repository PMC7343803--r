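test_that("weight estimation is exact least squares", {
  set.seed(11)
  basis <- make_channel_basis(9, 9)
  C1 <- channel_response(basis, sample(0:179, 30, replace = TRUE))
  W_true <- matrix(runif(5 * 9), 5, 9)
  B1 <- C1 %*% t(W_true)
  # noiseless planted weights recovered to machine precision
  expect_equal(estimate_weights(B1, C1), W_true, tolerance = 1e-12)
  # scalar regression
  expect_equal(
    as.vector(estimate_weights(matrix(2 * c(1, 2, 3)), matrix(c(1, 2, 3)))),
    2
  )
  # random noisy instance vs a generic least-squares oracle
  B1n <- B1 + matrix(rnorm(length(B1)), nrow(B1))
  oracle <- t(stats::lm.fit(C1, B1n)$coefficients)
  expect_equal(estimate_weights(B1n, C1), oracle,
    tolerance = 1e-10,
    ignore_attr = TRUE
  )
  # and vs the textbook normal-equation form B1' C1 (C1' C1)^-1
  printed <- t(B1n) %*% C1 %*% solve(t(C1) %*% C1)
  expect_equal(estimate_weights(B1n, C1), printed, tolerance = 1e-10)
  # rank-deficient channel space is rejected with a clear message
  expect_error(
    estimate_weights(B1[1:5, ], C1[1:5, ]),
    "rank deficient"
  )
  expect_error(estimate_weights(B1[1:10, ], C1), "same number of trials")
})

test_that("model inversion is the pseudo-inverse identity", {
  set.seed(12)
  W <- matrix(runif(40 * 9), 40, 9)
  c_true <- runif(9)
  B2 <- matrix(W %*% c_true, 1, 40)
  expect_equal(as.vector(invert_channels(W, B2)), c_true, tolerance = 1e-12)
  expect_equal(as.vector(invert_channels(W, 0 * B2)), rep(0, 9))
  # random instance vs generic least-squares oracle
  B2n <- matrix(rnorm(6 * 40), 6, 40)
  oracle <- t(stats::lm.fit(W, t(B2n))$coefficients)
  expect_equal(invert_channels(W, B2n), oracle,
    tolerance = 1e-10,
    ignore_attr = TRUE
  )
  # and vs the printed inverse formula (W'W)^-1 W' B2
  printed <- t(solve(t(W) %*% W) %*% t(W) %*% t(B2n))
  expect_equal(invert_channels(W, B2n), printed, tolerance = 1e-10)
  expect_error(invert_channels(matrix(0, 40, 9), B2), "singular")
})

test_that("reconstructions re-center correctly and preserve mass", {
  basis <- make_channel_basis(9, 9)
  # single active channel, centered on that channel's orientation
  C2 <- matrix(0, 1, 9)
  C2[4] <- 1
  rec <- reconstruct(C2, basis, basis$centers[4])
  expect_equal(which.max(rec), 91) # relative angle 0
  expect_equal(attr(rec, "theta")[91], 0)
  # circular shift preserves the curve sum
  expect_equal(sum(rec), sum(basis$M[, 4]))
  # equal channel weights give a flat, symmetric curve (up to basis ripple)
  rec_flat <- reconstruct(matrix(1, 1, 9), basis, 53)
  expect_lt(diff(range(rec_flat)), 1e-4)
})

test_that("representational fidelity has exact closed forms", {
  theta <- seq(-90, 89)
  curve_cos <- cospi(2 * theta / 180)
  expect_equal(representational_fidelity(curve_cos), 0.5)
  expect_equal(representational_fidelity(rep(1, 180)), 0)
  expect_equal(representational_fidelity(-curve_cos), -0.5)
  # linearity
  set.seed(13)
  r1 <- rnorm(180)
  r2 <- rnorm(180)
  expect_equal(
    representational_fidelity(3 * r1 - 2 * r2),
    3 * representational_fidelity(r1) - 2 * representational_fidelity(r2)
  )
})

test_that("z-scoring normalizes voxels independently per set", {
  set.seed(14)
  B <- matrix(rnorm(50 * 8, mean = 3), 50, 8)
  Bz <- zscore_trials(B)
  expect_equal(colMeans(Bz), rep(0, 8), tolerance = 1e-12)
  expect_equal(apply(Bz, 2, sd), rep(1, 8), tolerance = 1e-12)
  Bbad <- B
  Bbad[, 3] <- 1
  expect_error(zscore_trials(Bbad), "index 3")
  expect_error(zscore_trials(B[1, , drop = FALSE]), "2 trials")
})

test_that("noiseless cross-validated reconstructions peak at the truth", {
  tab <- generate_trial_table(3, seed = 15)
  sim <- simulate_participant(tab, modulation_params(phi_test = 1),
    sim_config(n_voxels = 40, noise = FALSE),
    seed = 16
  )
  basis <- make_channel_basis(9, 9)
  peaks <- integer(0)
  for (r in unique(tab$run_id)) {
    tr <- sim$train$run_id != r
    te <- sim$test$run_id == r
    W <- estimate_weights(
      sim$train$responses[tr, ],
      channel_response(basis, sim$train$orientation[tr])
    )
    C2 <- invert_channels(W, sim$test$responses[te, ])
    rec <- reconstruct(C2, basis, sim$test$orientation[te])
    peaks <- c(peaks, apply(rec, 2, which.max))
  }
  expect_true(all(peaks == 91)) # every trial peaks at relative 0
  # the high-level wrapper agrees
  cv <- crossval_reconstruct(sim$train, sim$test, zscore = FALSE)
  expect_equal(cv$n_folds, 3)
  expect_equal(which.max(cv$curves[, 1]), 91, ignore_attr = TRUE)
})

test_that("label-shuffled cross-validation fidelity centers on zero", {
  part <- tiny_participant(n_runs = 3, n_voxels = 24, seed = 17)
  bl <- part$hemispheres$left$blocks
  perms <- make_permutations(bl$stimulus$run_id, 60, seed = 18)
  cv <- crossval_reconstruct(bl$stimulus, bl$stimulus, perms = perms)
  null_mean <- mean(cv$null_rf[, "stim"])
  expect_lt(abs(null_mean), sd(cv$null_rf[, "stim"]))
  expect_gt(cv$rf[["stim"]], max(abs(cv$null_rf[, "stim"])) / 2)
})

test_that("single-run datasets are rejected", {
  part <- tiny_participant(n_runs = 2, n_voxels = 16, seed = 19)
  bl <- part$hemispheres$left$blocks$stimulus
  one_run <- bl
  keep <- bl$run_id == 1
  one_run$responses <- bl$responses[keep, ]
  one_run$run_id <- bl$run_id[keep]
  one_run$orientation <- bl$orientation[keep]
  one_run$trial_id <- bl$trial_id[keep]
  expect_error(crossval_reconstruct(one_run, one_run), "2 runs")
})
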