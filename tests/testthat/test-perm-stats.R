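test_that("within-run permutations preserve run structure and pairings", {
  tab <- generate_trial_table(3, seed = 31)
  perms <- make_permutations(tab$run_id, 25, seed = 32)
  for (p in perms[1:5]) {
    expect_setequal(p, seq_len(nrow(tab)))
    # shuffling stays within runs
    expect_equal(tab$run_id[p], tab$run_id)
    pt <- permute_labels(tab, p)
    # per-run label multiset identical before/after
    for (r in unique(tab$run_id)) {
      expect_setequal(
        paste(pt$orient_left, pt$orient_right)[pt$run_id == r],
        paste(tab$orient_left, tab$orient_right)[tab$run_id == r]
      )
    }
    # pairing intact: permuted (left, right) pairs are original pairs
    expect_true(all(
      paste(pt$orient_left, pt$orient_right) %in%
        paste(tab$orient_left, tab$orient_right)
    ))
  }
  # deterministic under the seed
  expect_identical(perms, make_permutations(tab$run_id, 25, seed = 32))
})

test_that("signed-rank statistic matches the classical Wilcoxon mapping", {
  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(9)
    v <- suppressWarnings(wilcox.test(x)$statistic) # sum of positive ranks
    n <- length(x)
    expect_equal(signed_rank_stat(x), unname(2 * v - n * (n + 1) / 2))
  }
  expect_equal(signed_rank_stat(c(0, 0)), 0)
})

test_that("group p-values count null exceedances with doubling and cap", {
  obs <- c(1, 2, 3, 4, 5, 6) # saturates the signed-rank statistic
  # null: 100 rows, exactly 2 of them all-positive (tie the observed)
  set.seed(34)
  null <- matrix(rnorm(100 * 6), 100, 6)
  null[1:98, 1] <- -abs(null[1:98, 1]) # rows 1..98 contain a negative
  null[99:100, ] <- abs(null[99:100, ])
  gt <- group_pvalue(obs, null)
  expect_equal(gt$p_right, 2 / 100) # ties count as exceeding
  expect_equal(gt$p_two, 2 * 2 / 100)
  # observed at the null median -> p_two capped at 1
  sym <- rbind(matrix(1, 50, 6) * rep(c(1, -1), each = 25), 0 * obs)
  gt2 <- group_pvalue(c(1e-9, -1e-9, 0, 0, 0, 0), sym)
  expect_lte(gt2$p_two, 1)
  expect_gte(gt2$p_two, 0.9)
  # constructed null: observed signed-rank statistic (one small negative
  # entry, stat = 19) exceeded by exactly the 5 all-positive rows
  # (stat = 21) out of 200 -> p_two = 0.05
  obs3 <- c(-1, 2, 3, 4, 5, 6)
  null3 <- rbind(
    matrix(rep(c(1, 2, 3, 4, 5, 6), each = 5), 5, 6), # stat 21
    matrix(rep(c(-1, -2, 3, 4, 5, 6), each = 195), 195, 6) # stat 15
  )
  gt3 <- group_pvalue(obs3, null3)
  expect_equal(gt3$p_right, 5 / 200)
  expect_equal(gt3$p_two, 0.05)
  expect_error(group_pvalue(1, matrix(1, 10, 1)), "2 participants")
})

test_that("p-values are invariant to monotone rescaling of the statistic", {
  set.seed(35)
  obs <- rnorm(7, mean = 0.5)
  null <- matrix(rnorm(200 * 7), 200, 7)
  g1 <- group_pvalue(obs, null)
  mono <- function(x) sign(x) * abs(x)^3 # odd, strictly increasing
  g2 <- group_pvalue(mono(obs), mono(null))
  expect_equal(g1$p_two, g2$p_two)
  expect_equal(g1$p_right, g2$p_right)
})

test_that("repeated-measures F matches aov and hand computation", {
  # 2 subjects x 3 states, hand-decomposed
  m <- rbind(c(1, 2, 3), c(2, 4, 6))
  # grand 3; state means 1.5, 3, 4.5; subject means 2, 4
  # SS_state = 2 * (2.25 + 0 + 2.25) = 9; SS_sub = 3 * (1 + 1) = 6
  # SS_tot = 4 + 1 + 0 + 1 + 1 + 9 = 16; SS_err = 1
  # F = (9 / 2) / (1 / 2) = 9
  expect_equal(wmiem:::rm_anova_F(m), 9)
  # against aov with an Error(subject) stratum
  set.seed(36)
  mm <- matrix(rnorm(8 * 4), 8, 4)
  df <- data.frame(
    y = as.vector(mm),
    subject = factor(rep(1:8, 4)),
    state = factor(rep(1:4, each = 8))
  )
  fit <- summary(stats::aov(y ~ state + Error(subject), data = df))
  f_aov <- fit[["Error: Within"]][[1]]["state", "F value"]
  expect_equal(wmiem:::rm_anova_F(mm), f_aov)
})

test_that("permutation ANOVA p-values behave at the boundaries", {
  # identical state means for every subject -> F = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 3, 4), each = 5) * 0 + rep(rnorm(5), 4), 5, 4)
  null <- lapply(1:50, function(i) matrix(rnorm(20), 5, 4))
  res <- perm_rm_anova(m0, null)
  expect_equal(res$f_stat, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, c(3, 12))
  # strong observed effect -> small p
  m1 <- matrix(rep(c(0, 0, 0, 10), each = 5), 5, 4) + rnorm(20, sd = 0.1)
  res1 <- perm_rm_anova(m1, null)
  expect_lt(res1$p, 0.05)
  expect_true(res1$p >= 0 && res1$p <= 1)
  expect_error(perm_rm_anova(m1[, 1, drop = FALSE], null), "2 states")
  m_na <- m1
  m_na[1, 1] <- NA
  expect_error(perm_rm_anova(m_na, null), "missing")
})

test_that("zero exceedance fractions format as a resolution bound", {
  expect_equal(format_pvalue(0, 1000), "< 0.001")
  expect_equal(format_pvalue(0.02, 1000), "0.02")
})
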