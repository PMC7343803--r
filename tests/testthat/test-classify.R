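test_that("ridge logistic matches glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6)
  y <- as.numeric(X %*% c(1, -1, 0.5, 0, 0, 0) + rnorm(n) > 0)
  pen <- 10
  ours <- wmiem:::ridge_logistic(X, y, penalty = pen)
  # glmnet minimizes (1/n) * nll + lambda ||beta||^2 / 2 for alpha = 0
  g <- glmnet::glmnet(X, y,
    family = "binomial", alpha = 0, lambda = pen / n,
    standardize = FALSE, thresh = 1e-14
  )
  expect_equal(ours[1], as.numeric(g$a0), tolerance = 1e-4)
  expect_equal(ours[-1], as.vector(g$beta), tolerance = 1e-4)
})

test_that("majorized solver agrees with the Newton solver", {
  set.seed(22)
  n <- 90
  X <- matrix(rnorm(n * 8), n, 8)
  labs <- sample(c(15, 75, 135), n, replace = TRUE)
  Y <- outer(labs, c(15, 75, 135), `==`) * 1
  newton <- sapply(1:3, function(j) wmiem:::ridge_logistic(X, Y[, j], 10))
  X1 <- cbind(1, X)
  H0 <- crossprod(X1) / 4
  diag(H0) <- diag(H0) + c(0, rep(10, 8))
  mm <- wmiem:::ridge_logistic_mm(X1, Y, 10, chol(H0), tol = 1e-9)
  expect_equal(mm, newton, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("decoder separates separable classes and respects the penalty", {
  set.seed(23)
  n <- 60
  labs <- rep(c(15, 75, 135), each = n / 3)
  mu <- outer(labs, c(15, 75, 135), `==`) * 4
  X <- mu + matrix(rnorm(n * 3, sd = 0.3), n, 3)
  m <- train_classifier(X, labs, penalty = 1)
  ev <- predict_evidence(m, X)
  expect_equal(
    c(15, 75, 135)[apply(ev, 1, which.max)], labs
  ) # 100% training accuracy on a separable set
  expect_equal(rowSums(ev), rep(1, n), tolerance = 1e-12)
  # stronger penalty shrinks coefficients
  m_big <- train_classifier(X, labs, penalty = 100)
  expect_lt(
    sum(m_big$coefs[-1, ]^2), sum(m$coefs[-1, ]^2)
  )
  expect_error(train_classifier(X, rep(15, n)), "single class")
  expect_error(train_classifier(X, labs + 1), "outside")
})

test_that("shuffled labels decode at chance", {
  set.seed(24)
  n <- 90
  X <- matrix(rnorm(n * 10), n, 10)
  labs <- rep(c(15, 75, 135), each = n / 3)
  acc <- replicate(10, {
    sh <- sample(labs)
    m <- train_classifier(X[1:60, ], sh[1:60])
    ev <- predict_evidence(m, X[61:90, ])
    mean(c(15, 75, 135)[apply(ev, 1, which.max)] == sh[61:90])
  })
  expect_equal(mean(acc), 1 / 3, tolerance = 0.1)
})

test_that("evidence differences follow their definition and bounds", {
  ev <- rbind(
    c(1, 1, 1) / 3,
    c(0.6, 0.3, 0.1)
  )
  colnames(ev) <- c("15", "75", "135")
  expect_equal(evidence_difference(ev[1, , drop = FALSE], 15, 135), 0)
  expect_equal(evidence_difference(ev[2, , drop = FALSE], 15, 135), 0.5)
  expect_equal(evidence_difference(ev, c(15, 75), c(75, 135)), c(0, 0.2))
  expect_error(evidence_difference(ev, 15, 15), "differ")
  expect_error(evidence_difference(ev, 20, 135), "must be one of")
  # bounded in [-1, 1] for normalized evidence
  set.seed(25)
  r <- matrix(runif(30), 10, 3)
  r <- r / rowSums(r)
  colnames(r) <- c("15", "75", "135")
  d <- evidence_difference(r, rep(15, 10), rep(75, 10))
  expect_true(all(d >= -1 & d <= 1))
})

test_that("cross-validated decoding recovers the state structure", {
  part <- tiny_participant(n_runs = 3, n_voxels = 30, seed = 26)
  bl <- part$hemispheres$right$blocks
  cc <- crossval_classify(bl$stimulus, bl$delay1)
  expect_setequal(names(cc$state_means), c("cued", "fut_rel", "fut_irr"))
  expect_gt(cc$state_means[["cued"]], cc$state_means[["fut_irr"]])
  # one record per delay-1 trial
  expect_equal(nrow(cc$evidence), nrow(part$table))
  # permutation nulls center near zero
  perms <- make_permutations(bl$stimulus$run_id, 20, seed = 27)
  cc_p <- crossval_classify(bl$stimulus, bl$delay1, perms = perms)
  expect_lt(
    abs(mean(cc_p$null_means[, "cued"])),
    cc_p$state_means[["cued"]] / 2
  )
})

test_that("noiseless stimulus-epoch decoding yields positive cued evidence", {
  part <- tiny_participant(
    n_runs = 2, n_voxels = 30, seed = 28,
    noise = FALSE
  )
  bl <- part$hemispheres$left$blocks
  cc <- crossval_classify(bl$stimulus, bl$delay1, zscore = FALSE)
  expect_gt(cc$state_means[["cued"]], 0)
})
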