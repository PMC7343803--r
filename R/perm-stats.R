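#' Within-run label permutations
#'
#' Generates permutation index vectors that shuffle trials within each run
#' only, so that per-run label counts are preserved exactly. Shuffling
#' trial indices (rather than individual labels) keeps within-trial
#' left/right orientation pairings intact: every label attached to a trial
#' travels with it.
#'
#' @param run_id per-trial run identifier.
#' @param n_perm number of permutations.
#' @param seed integer seed; permutation `p` is reproducible given
#'   `(seed, n_perm)`.
#' @return list of `n_perm` integer index vectors of length
#'   `length(run_id)`.
#' @export
make_permutations <- function(run_id, n_perm = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(run_id)
  runs <- unique(run_id)
  lapply(seq_len(n_perm), function(p) {
    idx <- seq_len(n)
    for (r in runs) {
      rows <- which(run_id == r)
      idx[rows] <- rows[sample.int(length(rows))]
    }
    idx
  })
}

#' Permute a trial table's orientation labels within runs
#'
#' Applies one within-run permutation to a trial table, reassigning the
#' (left, right) orientation and base labels jointly across trials of the
#' same run. The permuted label pairs are a reordering of the original
#' pairs within each run.
#'
#' @param table a `trial_table`.
#' @param perm an index vector from [make_permutations()].
#' @return the table with permuted `orient_*`, `base_*`, `jitter_*`
#'   columns.
#' @export
permute_labels <- function(table, perm) {
  stopifnot(length(perm) == nrow(table))
  cols <- c(
    "orient_left", "orient_right", "base_left", "base_right",
    "jitter_left", "jitter_right"
  )
  cols <- intersect(cols, names(table))
  table[cols] <- table[perm, cols]
  table
}

#' Signed-rank statistic of a sample against zero
#'
#' The signed sum of ranks of the absolute values (zeros dropped, ties
#' mid-ranked). Only the rank of this statistic among its permutation
#' distribution matters for inference, so any strictly monotone variant
#' (e.g. the classical sum of positive ranks) yields identical p-values.
#'
#' @param x numeric vector.
#' @return the signed rank sum.
#' @export
signed_rank_stat <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return(0)
  sum(sign(x) * rank(abs(x)))
}

#' Permutation group-level test of participant means against zero
#'
#' Second-level inference: the observed per-participant statistics are
#' summarized by a signed-rank statistic against zero, as is each row of
#' the permutation null (one permuted per-participant mean per
#' participant, jointly indexed by permutation). One-tailed p-values are
#' the fraction of null statistics at least as extreme as the observed one
#' (ties count as exceeding, which is conservative); the two-tailed
#' p-value doubles the smaller one-tailed p, capped at 1. A raw fraction
#' of 0 means "p < 1/n_perm"; use [format_pvalue()] for reporting.
#'
#' @param observed per-participant observed statistics (length >= 2).
#' @param null_matrix `n_perm x participants` matrix of permuted
#'   statistics.
#' @return list of class `group_test`: `observed_stat`, `null_stats`,
#'   `p_right`, `p_left`, `p_two`, `n_perm`.
#' @export
group_pvalue <- function(observed, null_matrix) {
  null_matrix <- as.matrix(null_matrix)
  if (length(observed) < 2) stop("need >= 2 participants")
  if (ncol(null_matrix) != length(observed)) {
    stop("null_matrix must have one column per participant")
  }
  obs <- signed_rank_stat(observed)
  nulls <- apply(null_matrix, 1, signed_rank_stat)
  if (all(nulls == nulls[1]) && obs == nulls[1]) {
    warning("all statistics tied; permutation p-value is degenerate")
  }
  p_right <- mean(nulls >= obs)
  p_left <- mean(nulls <= obs)
  structure(
    list(
      observed_stat = obs, null_stats = nulls,
      p_right = p_right, p_left = p_left,
      p_two = min(1, 2 * min(p_right, p_left)),
      n_perm = length(nulls)
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "group_test: signed-rank stat %.1f, p_two = %s (%d permutations)\n",
    x$observed_stat, format_pvalue(x$p_two, x$n_perm), x$n_perm
  ))
  invisible(x)
}

#' Format a permutation p-value for reporting
#'
#' Zero exceedance fractions are reported as `< 1/n_perm`; the raw
#' fraction is what machine-readable outputs keep.
#'
#' @param p raw permutation fraction.
#' @param n_perm number of permutations.
#' @return character scalar.
#' @export
format_pvalue <- function(p, n_perm) {
  if (p <= 0) sprintf("< %.4g", 1 / n_perm) else sprintf("%.4g", p)
}

# One-way repeated-measures F (subjects x states matrix).
rm_anova_F <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  s <- ncol(mat)
  grand <- mean(mat)
  ss_state <- n * sum((colMeans(mat) - grand)^2)
  ss_sub <- s * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- max(ss_tot - ss_state - ss_sub, 0)
  df1 <- s - 1
  df2 <- (s - 1) * (n - 1)
  ms_state <- ss_state / df1
  ms_err <- ss_err / df2
  if (ms_state == 0) return(0)
  if (ms_err == 0) return(Inf)
  ms_state / ms_err
}

#' Permutation repeated-measures ANOVA across states
#'
#' Computes the one-way repeated-measures F over states for the observed
#' subjects x states matrix and for each permuted replicate, and returns
#' the one-tailed p-value as the fraction of null F values exceeding (or
#' tying, conservatively) the observed F.
#'
#' @param state_means `subjects x states` matrix of observed means.
#' @param null_state_means `n_perm x subjects x states` array of permuted
#'   means (or a list of `subjects x states` matrices).
#' @return list with `f_stat`, `df`, `p`, `null_f`, `n_perm`.
#' @export
perm_rm_anova <- function(state_means, null_state_means) {
  state_means <- as.matrix(state_means)
  if (nrow(state_means) < 2 || ncol(state_means) < 2) {
    stop("need >= 2 subjects and >= 2 states")
  }
  if (anyNA(state_means)) stop("missing cells in state_means")
  if (is.list(null_state_means)) {
    null_f <- vapply(null_state_means, rm_anova_F, numeric(1))
  } else {
    null_f <- vapply(
      seq_len(dim(null_state_means)[1]),
      function(p) rm_anova_F(null_state_means[p, , ]),
      numeric(1)
    )
  }
  f <- rm_anova_F(state_means)
  list(
    f_stat = f,
    df = c(ncol(state_means) - 1, (ncol(state_means) - 1) * (nrow(state_means) - 1)),
    p = mean(null_f >= f),
    null_f = null_f,
    n_perm = length(null_f)
  )
}
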