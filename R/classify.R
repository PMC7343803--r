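# L2-penalized (ridge) logistic regression fitted by Newton/IRLS.
# Minimizes -loglik + penalty/2 * ||beta||^2 (intercept unpenalized).
# beta0 allows warm starts (e.g. across label permutations).
ridge_logistic <- function(X, y, penalty = 10, maxit = 100L, tol = 1e-9,
                           beta0 = NULL) {
  X <- cbind(1, as.matrix(X))
  p <- ncol(X)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  pen <- c(0, rep(penalty, p - 1))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, mu - y)) + pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, g)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Fixed-Hessian (majorization) solver for the same ridge logistic
# objective: the Bernoulli variance is bounded by 1/4, so
# H0 = X'X/4 + penalty majorizes every true Hessian and can be factored
# once and reused across classes and label permutations. Monotone descent,
# linear convergence; used for the permutation nulls where thousands of
# refits share one design matrix. X1 = cbind(1, X); Y is an
# n x n_classes 0/1 indicator matrix; returns the coefficient matrix.
ridge_logistic_mm <- function(X1, Y, penalty, chol0, beta = NULL,
                              maxit = 500L, tol = 1e-6) {
  p <- ncol(X1)
  if (is.null(beta)) beta <- matrix(0, p, ncol(Y))
  pen <- c(0, rep(penalty, p - 1))
  for (it in seq_len(maxit)) {
    mu <- 1 / (1 + exp(-X1 %*% beta))
    g <- crossprod(X1, mu - Y) + pen * beta
    step <- backsolve(chol0, forwardsolve(t(chol0), g))
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Train a three-class penalized logistic-regression decoder
#'
#' One-vs-rest decoding of base-orientation bins: for each of the three
#' base orientations a binary L2-penalized logistic regression is trained
#' to distinguish that bin from the other two (default penalty 10 on the
#' squared coefficient norm; the intercept is unpenalized). The penalty is
#' the coefficient of `||beta||^2 / 2` added to the summed negative
#' log-likelihood, convertible to other parameterizations by dividing by
#' the training-set size.
#'
#' @param B `trials x voxels` training responses (z-scored per run).
#' @param base_labels per-trial base bin, values in `classes`.
#' @param penalty L2 penalty (>= 0).
#' @param classes the three base orientations.
#' @param tol Newton convergence tolerance on the coefficient step.
#' @param init optional `wm_classifier` used as a warm start (e.g. the
#'   observed-label model when retraining under label permutations).
#' @return object of class `wm_classifier` with one coefficient vector per
#'   class.
#' @export
train_classifier <- function(B, base_labels, penalty = 10,
                             classes = c(15, 75, 135), tol = 1e-9,
                             init = NULL) {
  B <- as.matrix(B)
  bad <- setdiff(unique(base_labels), classes)
  if (length(bad)) {
    stop("base labels outside {", paste(classes, collapse = ","), "}: ",
      paste(bad, collapse = ", "))
  }
  present <- classes %in% base_labels
  if (sum(present) < 2) stop("training set contains a single class")
  coefs <- vapply(
    seq_along(classes),
    function(j) {
      ridge_logistic(B, as.numeric(base_labels == classes[j]), penalty,
        tol = tol, beta0 = if (!is.null(init)) init$coefs[, j]
      )
    },
    numeric(ncol(B) + 1)
  )
  colnames(coefs) <- as.character(classes)
  structure(
    list(coefs = coefs, classes = classes, penalty = penalty),
    class = "wm_classifier"
  )
}

#' @export
print.wm_classifier <- function(x, ...) {
  cat(sprintf(
    "wm_classifier: %d-class one-vs-rest ridge logistic (penalty %g), %d voxels\n",
    length(x$classes), x$penalty, nrow(x$coefs) - 1
  ))
  invisible(x)
}

#' Classifier evidence for each base-orientation bin
#'
#' Per trial, the raw evidence for a bin is the fitted probability of its
#' one-vs-rest model; `normalize = TRUE` (the default reading) rescales
#' the three values to sum to 1.
#'
#' @param model a `wm_classifier`.
#' @param B `trials x voxels` test responses.
#' @param normalize normalize evidence across the three bins.
#' @return `trials x 3` matrix of evidence values, columns named by class;
#'   raw (unnormalized) probabilities in attribute `raw`.
#' @export
predict_evidence <- function(model, B, normalize = TRUE) {
  B <- cbind(1, as.matrix(B))
  raw <- 1 / (1 + exp(-B %*% model$coefs))
  out <- if (normalize) raw / rowSums(raw) else raw
  attr(out, "raw") <- raw
  out
}

#' Evidence difference for the tested versus absent orientation
#'
#' The decoding statistic: classifier evidence for the tested
#' (contralateral) item's bin minus evidence for the bin that was not
#' presented on that trial. Positive values mean evidence in favor of the
#' tested orientation; negative values mean less evidence than for a
#' never-presented orientation (suppression). With normalized evidence the
#' difference is bounded in `[-1, 1]`.
#'
#' @param evidence `trials x 3` evidence matrix from [predict_evidence()].
#' @param tested_bin,absent_bin per-trial base bins (tested item's bin and
#'   the unique bin matching neither item).
#' @return numeric vector of evidence differences.
#' @export
evidence_difference <- function(evidence, tested_bin, absent_bin) {
  classes <- colnames(evidence)
  ti <- match(as.character(tested_bin), classes)
  ai <- match(as.character(absent_bin), classes)
  if (anyNA(ti) || anyNA(ai)) {
    stop("bins must be one of {", paste(classes, collapse = ","), "}")
  }
  if (any(ti == ai)) stop("tested and absent bins must differ")
  n <- nrow(evidence)
  evidence[cbind(seq_len(n), ti)] - evidence[cbind(seq_len(n), ai)]
}

#' Leave-one-run-out classification with evidence differences
#'
#' Trains the three-class decoder on all training trials outside the
#' held-out run (all trial types pooled) and scores each held-out test
#' trial with the evidence difference between its tested bin and the base
#' bin absent on that trial. Evidence differences are averaged per state
#' across trials and folds. Optional within-run label permutations
#' retrain the decoder with shuffled training bins and re-score the
#' original test trials.
#'
#' @param train_block training `voxel_block` with `base` labels.
#' @param test_block test `voxel_block` with `base`, `state` and the
#'   trial's absent bin (computed from `base` and the held item's base via
#'   `absent_base`, see Details) . If `test_block$absent_base` is `NULL`
#'   it is derived as the class matching neither `base` nor the base of
#'   `held_orientation`.
#' @param penalty L2 penalty (default 10).
#' @param classes base bins.
#' @param zscore z-score responses per voxel within each run first.
#' @param perms optional list of permutation index vectors over training
#'   trials.
#' @return list with `evidence` (per-trial records), `state_means` (named
#'   per-state mean evidence difference), and `null_means`
#'   (`n_perm x states`) when permutations are given.
#' @export
crossval_classify <- function(train_block, test_block = train_block,
                              penalty = 10, classes = c(15, 75, 135),
                              zscore = TRUE, perms = NULL) {
  runs <- sort(unique(test_block$run_id))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  B_tr_all <- train_block$responses
  B_te_all <- test_block$responses
  if (zscore) {
    B_tr_all <- zscore_by_run(B_tr_all, train_block$run_id)
    B_te_all <- zscore_by_run(B_te_all, test_block$run_id)
  }
  absent <- test_block$absent_base
  if (is.null(absent)) {
    held_base <- vapply(
      test_block$held_orientation,
      function(th) classes[which.min(circ_dist180(classes, th))],
      numeric(1)
    )
    absent <- vapply(
      seq_along(held_base),
      function(i) setdiff(classes, c(test_block$base[i], held_base[i])),
      numeric(1)
    )
  }
  states <- if (is.null(test_block$state)) {
    rep("all", nrow(B_te_all))
  } else {
    test_block$state
  }
  state_levels <- sort(unique(states))
  n_perm <- length(perms)
  records <- list()
  null_sum <- if (n_perm) {
    matrix(0, n_perm, length(state_levels),
      dimnames = list(NULL, state_levels)
    )
  }
  n_state <- stats::setNames(numeric(length(state_levels)), state_levels)
  for (r in runs) {
    tr <- which(train_block$run_id != r)
    te <- which(test_block$run_id == r)
    if (!length(te)) next
    model <- train_classifier(
      B_tr_all[tr, , drop = FALSE], train_block$base[tr], penalty, classes
    )
    ev <- predict_evidence(model, B_te_all[te, , drop = FALSE])
    diff <- evidence_difference(ev, test_block$base[te], absent[te])
    records[[length(records) + 1L]] <- data.frame(
      trial_id = test_block$trial_id[te], run_id = r,
      state = states[te],
      tested_bin = test_block$base[te], absent_bin = absent[te],
      evidence_tested = ev[cbind(
        seq_along(te),
        match(as.character(test_block$base[te]), colnames(ev))
      )],
      evidence_diff = diff,
      stringsAsFactors = FALSE
    )
    for (s in unique(states[te])) {
      n_state[s] <- n_state[s] + sum(states[te] == s)
    }
    if (n_perm) {
      for (p in seq_len(n_perm)) {
        labs_p <- train_block$base[perms[[p]][tr]]
        model_p <- train_classifier(
          B_tr_all[tr, , drop = FALSE], labs_p, penalty, classes
        )
        ev_p <- predict_evidence(model_p, B_te_all[te, , drop = FALSE])
        diff_p <- evidence_difference(ev_p, test_block$base[te], absent[te])
        for (s in unique(states[te])) {
          cols <- states[te] == s
          null_sum[p, s] <- null_sum[p, s] + sum(diff_p[cols])
        }
      }
    }
  }
  records <- do.call(rbind, records)
  state_means <- vapply(
    state_levels,
    function(s) mean(records$evidence_diff[records$state == s]),
    numeric(1)
  )
  out <- list(evidence = records, state_means = state_means)
  if (n_perm) out$null_means <- sweep(null_sum, 2, n_state, `/`)
  out
}
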