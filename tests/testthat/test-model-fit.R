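cfg0 <- noiseless_fit_cfg()

test_that("the fitting cost is zero at the generating parameters", {
  p <- modulation_params(phi_test = 0.7, gamma = 0.4)
  tg <- make_fit_targets(p, cfg0, seed = 41)
  expect_equal(fit_cost(p, tg, cfg0, seed = 41), 0)
  # a wrong memory strength costs more on noiseless targets
  expect_gt(
    fit_cost(modulation_params(phi_test = 0.3, gamma = 0.4), tg, cfg0, 41),
    0
  )
  # the cost sums both jointly fitted curves symmetrically
  curves <- simulate_state_curves(modulation_params(0.3, 0.4), cfg0, 41)
  expect_equal(
    fit_cost(modulation_params(0.3, 0.4), tg, cfg0, 41),
    sum((curves$state - tg$state)^2) + sum((curves$held - tg$held)^2)
  )
})

test_that("grid search evaluates the factorial grid and finds the vertex", {
  p <- modulation_params(phi_test = 0.6, gamma = 0.8) # both on the grid
  tg <- make_fit_targets(p, cfg0, seed = 42)
  g <- grid_search(c("phi_test", "gamma"), tg, cfg0, seed = 42)
  expect_equal(g$n_eval, 121) # 11^2
  expect_equal(g$params$phi_test, 0.6)
  expect_equal(g$params$gamma, 0.8)
  # one-at-a-time sweep is available and much cheaper
  g1 <- grid_search(c("phi_test", "gamma"), tg, cfg0,
    seed = 42,
    grid_type = "one_at_a_time"
  )
  expect_equal(g1$n_eval, 23)
  expect_error(grid_search(character(0), tg, cfg0), "one free parameter")
})

test_that("refinement descends and is deterministic", {
  p <- modulation_params(phi_test = 0.55)
  tg <- make_fit_targets(p, cfg0, seed = 43)
  start <- modulation_params(phi_test = 0.6) # nearest grid vertex
  f <- refine_fit(start, "phi_test", tg, cfg0, seed = 43)
  expect_lte(f$sse, fit_cost(start, tg, cfg0, seed = 43))
  expect_equal(f$params$phi_test, 0.55, tolerance = 0.02)
  f2 <- refine_fit(start, "phi_test", tg, cfg0, seed = 43)
  expect_equal(f, f2)
  # starting exactly at a zero-cost vertex returns the vertex untouched
  tg0 <- make_fit_targets(modulation_params(phi_test = 0.6), cfg0, seed = 44)
  f0 <- refine_fit(
    modulation_params(phi_test = 0.6), "phi_test", tg0, cfg0,
    seed = 44
  )
  expect_identical(f0$params$phi_test, 0.6)
  expect_equal(f0$sse, 0)
})

test_that("fit diagnostics relate as expected", {
  tg <- make_fit_targets(modulation_params(phi_test = 0.6), cfg0, seed = 45)
  tg$se <- rep(0.05, 180)
  f <- fit_state_model("phi_test", tg, cfg0, seed = 45, grid_steps = 5)
  expect_lte(f$adj_r2, f$r2)
  expect_gte(f$sse, 0)
  expect_lte(f$r2, 1)
  expect_true(f$se_band_fraction >= 0 && f$se_band_fraction <= 1)
})

test_that("nested F-tests use the fixed-parameter counting convention", {
  mk <- function(free, sse) {
    structure(
      list(free = free, n_free = length(free), sse = sse),
      class = "fit_result"
    )
  }
  cmp <- nested_f_test(mk("phi_test", 2), mk(c("phi_test", "gamma"), 1))
  # F = ((2 - 1) / 1) / (1 / (24 - 6 - 2)) = 16 with df (1, 16)
  expect_equal(cmp$f_stat, 16)
  expect_equal(cmp$df_num, 1)
  expect_equal(cmp$df_den, 16)
  expect_equal(cmp$p, stats::pf(16, 1, 16, lower.tail = FALSE))
  # no improvement -> F = 0, p = 1
  cmp0 <- nested_f_test(mk("phi_test", 1), mk(c("phi_test", "mu"), 1))
  expect_equal(cmp0$f_stat, 0)
  expect_equal(cmp0$p, 1)
  # a full model can never fit worse than its restriction: clamped
  cmp_clamp <- nested_f_test(mk("phi_test", 1), mk(c("phi_test", "mu"), 1.2))
  expect_equal(cmp_clamp$sse_full, 1)
  expect_error(
    nested_f_test(mk("gamma", 2), mk(c("phi_test", "mu"), 1)),
    "not nested"
  )
})

test_that("mechanism comparison reports one row per model with nested tests", {
  tg <- make_fit_targets(
    modulation_params(phi_test = 0.6), cfg0,
    seed = 46
  )
  res <- compare_mechanisms(tg, cfg0,
    seed = 46,
    models = list(
      phi = "phi_test",
      "phi+gamma" = c("phi_test", "gamma")
    ),
    grid_steps = 5
  )
  expect_equal(nrow(res$table), 2)
  expect_named(res$comparisons, "phi_vs_phi+gamma")
  expect_true(all(c("sse", "r2", "adj_r2") %in% names(res$table)))
  # targets had no gain modulation: adding gamma should not be significant
  expect_gt(res$comparisons[["phi_vs_phi+gamma"]]$p, 0.05)
})
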