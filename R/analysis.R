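#' Analyze one simulated participant
#'
#' Runs the leave-one-run-out IEM (and optionally the three-class
#' decoder) on a pseudo-experimental participant: training on the
#' stimulus-epoch patterns of each hemisphere, testing on the stimulus
#' epoch (the `stim` state) and on the delay epochs (`cued`, `fut_rel`,
#' `fut_irr`), re-centering each trial on its own item's orientation, and
#' pooling trials across hemispheres and epochs per state. Optional
#' within-run label permutations (shared across hemispheres, preserving
#' within-trial orientation pairings) yield per-state null means.
#'
#' @param part a `wm_participant` from [simulate_pseudo_experiment()].
#' @param basis analysis `channel_basis`.
#' @param n_perm number of training-label permutations (0 for none).
#' @param seed seed for the permutation stream.
#' @param penalty classifier L2 penalty.
#' @param classify also run the evidence-difference decoder.
#' @param classify_n_perm permutations for the decoder null (retraining a
#'   classifier per permutation is costly; defaults to `n_perm`).
#' @return list with `rf` (named per-state mean fidelity), `rf_null`
#'   (`n_perm x states`), `curves` (pooled per-state mean re-centered
#'   reconstructions), `n_trials`, and with `classify = TRUE` also `ev`
#'   and `ev_null`.
#' @export
analyze_participant <- function(part, basis = make_channel_basis(9, 9),
                                n_perm = 0L, seed = 1L, penalty = 10,
                                classify = TRUE,
                                classify_n_perm = n_perm) {
  stopifnot(inherits(part, "wm_participant"))
  states <- c("stim", "cued", "fut_rel", "fut_irr")
  run_id <- part$hemispheres$left$blocks$stimulus$run_id
  perms <- if (n_perm > 0) make_permutations(run_id, n_perm, seed)
  n_cperm <- if (classify) min(classify_n_perm, n_perm) else 0L
  n_points <- nrow(basis$M)
  cos2 <- cospi(2 * (seq(-n_points / 2, n_points / 2 - 1) *
    180 / n_points) / 180)
  rf_sum <- ev_sum <- stats::setNames(numeric(4), states)
  n_rf <- n_ev <- stats::setNames(numeric(4), states)
  curve_sum <- matrix(0, n_points, 4, dimnames = list(NULL, states))
  curve_held_sum <- matrix(0, n_points, 4, dimnames = list(NULL, states))
  rf_null_sum <- if (n_perm > 0) {
    matrix(0, n_perm, 4, dimnames = list(NULL, states))
  }
  ev_null_sum <- if (n_cperm > 0) {
    matrix(0, n_cperm, 4, dimnames = list(NULL, states))
  }
  pinv_mult <- function(sW, B2) {
    # channel responses through the truncated pseudo-inverse of W
    keep <- sW$d > 1e-8 * sW$d[1]
    t(sW$v[, keep, drop = FALSE] %*%
      ((t(sW$u[, keep, drop = FALSE]) %*% t(B2)) / sW$d[keep]))
  }
  # Projections of the channel curves onto the cos/sin 2-cycle: for a
  # trial centered on integer orientation c, RF = cos(2c) a'C2 +
  # sin(2c) b'C2, exactly equal to re-centering the full curve.
  sin2 <- sinpi(2 * (seq(-n_points / 2, n_points / 2 - 1) *
    180 / n_points) / 180)
  proj_a <- as.vector(crossprod(basis$M, cos2)) / n_points
  proj_b <- as.vector(crossprod(basis$M, sin2)) / n_points
  for (hemi in c("left", "right")) {
    bl <- part$hemispheres[[hemi]]$blocks
    train <- bl$stimulus
    epochs <- names(bl)
    runs <- sort(unique(train$run_id))
    C1all <- channel_response(basis, train$orientation)
    if (classify) {
      Bc_tr <- zscore_by_run(train$responses, train$run_id)
      Bc_te <- lapply(bl, function(b) zscore_by_run(b$responses, b$run_id))
      classes <- part$base_set
      held_base <- lapply(bl, function(b) {
        vapply(b$held_orientation, function(th) {
          classes[which.min(circ_dist180(classes, th))]
        }, numeric(1))
      })
      absent <- lapply(epochs, function(ep) {
        vapply(seq_along(held_base[[ep]]), function(i) {
          setdiff(classes, c(bl[[ep]]$base[i], held_base[[ep]][i]))
        }, numeric(1))
      })
      names(absent) <- epochs
    }
    for (r in runs) {
      tr <- which(train$run_id != r)
      B1z <- zscore_trials(train$responses[tr, , drop = FALSE])
      C1 <- channel_response(basis, train$orientation[tr])
      te_idx <- lapply(bl, function(b) which(b$run_id == r))
      fold <- lapply(epochs, function(ep) {
        te <- te_idx[[ep]]
        if (!length(te)) return(NULL)
        b <- bl[[ep]]
        B2z <- zscore_trials(b$responses[te, , drop = FALSE])
        idx <- outer(
          seq(-n_points / 2, n_points / 2 - 1),
          round(b$orientation[te] * n_points / 180), `+`
        ) %% n_points + 1
        smat <- outer(b$state[te], states, `==`) * 1 # n_te x 4 indicator
        idx_h <- outer(
          seq(-n_points / 2, n_points / 2 - 1),
          round(b$held_orientation[te] * n_points / 180), `+`
        ) %% n_points + 1
        list(
          te = te, B2z = B2z, st = b$state[te], smat = smat,
          cos2c = cospi(2 * b$orientation[te] / 180),
          sin2c = sinpi(2 * b$orientation[te] / 180),
          flat = cbind(as.vector(idx), rep(seq_along(te), each = n_points)),
          flat_h = cbind(
            as.vector(idx_h),
            rep(seq_along(te), each = n_points)
          )
        )
      })
      names(fold) <- epochs
      # observed fit: keep full re-centered curves
      sW <- svd(estimate_weights(B1z, C1))
      for (ep in epochs) {
        f <- fold[[ep]]
        if (is.null(f)) next
        C2 <- pinv_mult(sW, f$B2z)
        curves <- basis$M %*% t(C2)
        rec <- matrix(curves[f$flat], n_points, length(f$te))
        rec_h <- matrix(curves[f$flat_h], n_points, length(f$te))
        rf <- as.vector(crossprod(cos2, rec)) / n_points
        for (s in unique(f$st)) {
          sel <- f$st == s
          rf_sum[s] <- rf_sum[s] + sum(rf[sel])
          n_rf[s] <- n_rf[s] + sum(sel)
          curve_sum[, s] <- curve_sum[, s] +
            rowSums(rec[, sel, drop = FALSE])
          curve_held_sum[, s] <- curve_held_sum[, s] +
            rowSums(rec_h[, sel, drop = FALSE])
        }
      }
      # permutations: weights from permuted labels, fidelity via the
      # two-vector projection (no curves materialized)
      for (p in seq_len(n_perm)) {
        C1p <- C1all[perms[[p]][tr], , drop = FALSE]
        G <- crossprod(C1p)
        Wp <- t(solve(G, crossprod(C1p, B1z)))
        sWp <- svd(Wp)
        for (ep in epochs) {
          f <- fold[[ep]]
          if (is.null(f)) next
          C2p <- pinv_mult(sWp, f$B2z)
          rf_p <- f$cos2c * as.vector(C2p %*% proj_a) +
            f$sin2c * as.vector(C2p %*% proj_b)
          rf_null_sum[p, ] <- rf_null_sum[p, ] + crossprod(f$smat, rf_p)
        }
      }
      if (classify) {
        model <- train_classifier(
          Bc_tr[tr, , drop = FALSE], train$base[tr], penalty, classes
        )
        score_cls <- function(coefs) {
          # per-epoch, per-state sums of evidence differences
          out <- stats::setNames(numeric(4), states)
          for (ep in epochs) {
            te <- te_idx[[ep]]
            if (!length(te)) next
            raw <- 1 / (1 + exp(-cbind(1, Bc_te[[ep]][te, , drop = FALSE]) %*% coefs))
            ev <- raw / rowSums(raw)
            colnames(ev) <- as.character(classes)
            d <- evidence_difference(ev, bl[[ep]]$base[te], absent[[ep]][te])
            out <- out + as.vector(crossprod(fold[[ep]]$smat, d))
          }
          out
        }
        obs_ev <- score_cls(model$coefs)
        for (ep in epochs) {
          te <- te_idx[[ep]]
          if (!length(te)) next
          cnt <- colSums(fold[[ep]]$smat)
          n_ev <- n_ev + cnt
        }
        ev_sum <- ev_sum + obs_ev
        if (n_cperm > 0) {
          X1 <- cbind(1, Bc_tr[tr, , drop = FALSE])
          H0 <- crossprod(X1) / 4
          diag(H0) <- diag(H0) + c(0, rep(penalty, ncol(X1) - 1))
          chol0 <- chol(H0)
          # refit permutations in batches: one majorized solve over a
          # stacked coefficient matrix (3 classes x batch)
          for (batch in split(seq_len(n_cperm), ceiling(seq_len(n_cperm) / 20))) {
            Yb <- do.call(cbind, lapply(batch, function(p) {
              outer(train$base[perms[[p]][tr]], classes, `==`) * 1
            }))
            coefs_b <- ridge_logistic_mm(X1, Yb, penalty, chol0,
              tol = 1e-4
            )
            for (j in seq_along(batch)) {
              ev_null_sum[batch[j], ] <- ev_null_sum[batch[j], ] +
                score_cls(coefs_b[, 3 * (j - 1) + 1:3, drop = FALSE])
            }
          }
        }
      }
    }
  }
  out <- list(
    rf = rf_sum / n_rf,
    curves = sweep(curve_sum, 2, n_rf, `/`),
    curves_held = sweep(curve_held_sum, 2, n_rf, `/`),
    n_trials = n_rf,
    theta = seq(-n_points / 2, n_points / 2 - 1) * 180 / n_points
  )
  if (n_perm > 0) out$rf_null <- sweep(rf_null_sum, 2, n_rf, `/`)
  if (classify) {
    out$ev <- ev_sum / n_ev
    if (n_cperm > 0) out$ev_null <- sweep(ev_null_sum, 2, n_ev, `/`)
  }
  out
}

#' Simulate and analyze a group of participants
#'
#' The package's core experiment: simulates `n_participants`
#' pseudo-experimental datasets (each with its own trial table and
#' weights), analyzes each with the IEM (and optionally the decoder),
#' and performs permutation-based group inference: per-state signed-rank
#' tests of the participant means against zero and a permutation
#' repeated-measures ANOVA across the three delay-period states.
#'
#' @param n_participants number of simulated participants.
#' @param n_runs runs per participant.
#' @param state_params named per-state [modulation_params()].
#' @param config a [sim_config()].
#' @param basis analysis `channel_basis`.
#' @param n_perm label permutations per participant.
#' @param seed master seed; everything (tables, data, permutations)
#'   derives from it.
#' @param classify also run the decoder.
#' @param classify_n_perm decoder permutations (see
#'   [analyze_participant()]).
#' @param penalty classifier L2 penalty.
#' @param epochs which trial epochs to simulate and analyze.
#' @return object of class `wm_group`: `rf` / `ev`
#'   (`participants x states` matrices of observed means), `rf_null` /
#'   `ev_null` (`n_perm x participants x states` arrays), `curves`
#'   (states-named list of `180 x participants` matrices), group
#'   `tests` (per-state [group_pvalue()] results and `anova` across
#'   delay states), `n_perm`, `seed`.
#' @export
run_group_analysis <- function(n_participants = 6L, n_runs = 18L,
                               state_params = default_state_params(),
                               config = sim_config(),
                               basis = make_channel_basis(9, 9),
                               n_perm = 1000L, seed = 1L,
                               classify = TRUE,
                               classify_n_perm = n_perm,
                               penalty = 10,
                               epochs = c(
                                 "stimulus", "delay1", "delay2"
                               )) {
  states <- c("stim", "cued", "fut_rel", "fut_irr")
  seeds <- matrix(derive_seeds(seed, 3L * n_participants), ncol = 3)
  rf <- ev <- matrix(NA_real_, n_participants, 4,
    dimnames = list(NULL, states)
  )
  rf_null <- if (n_perm > 0) array(0, c(n_perm, n_participants, 4))
  n_cperm <- if (classify) min(classify_n_perm, n_perm) else 0L
  ev_null <- if (n_cperm > 0) {
    array(0, c(n_cperm, n_participants, 4))
  }
  curves <- NULL
  for (i in seq_len(n_participants)) {
    table <- generate_trial_table(n_runs, seeds[i, 1])
    part <- simulate_pseudo_experiment(table, state_params, config,
      seed = seeds[i, 2], epochs = epochs
    )
    res <- analyze_participant(part, basis,
      n_perm = n_perm,
      seed = seeds[i, 3], penalty = penalty, classify = classify,
      classify_n_perm = classify_n_perm
    )
    rf[i, ] <- res$rf[states]
    if (is.null(curves)) {
      curves <- curves_held <- lapply(states, function(s) {
        matrix(NA_real_, length(res$theta), n_participants)
      })
      names(curves) <- names(curves_held) <- states
      theta <- res$theta
    }
    for (s in states) {
      curves[[s]][, i] <- res$curves[, s]
      curves_held[[s]][, i] <- res$curves_held[, s]
    }
    if (n_perm > 0) rf_null[, i, ] <- res$rf_null[, states]
    if (classify) {
      ev[i, ] <- res$ev[states]
      if (!is.null(ev_null)) ev_null[, i, ] <- res$ev_null[, states]
    }
  }
  tests <- list()
  if (n_perm > 0) {
    tests$rf <- lapply(stats::setNames(seq_along(states), states), function(j) {
      group_pvalue(rf[, j], rf_null[, , j])
    })
    delay <- match(c("cued", "fut_rel", "fut_irr"), states)
    tests$rf_anova <- perm_rm_anova(
      rf[, delay],
      rf_null[, , delay, drop = FALSE]
    )
  }
  if (classify && !is.null(ev_null)) {
    tests$ev <- lapply(stats::setNames(seq_along(states), states), function(j) {
      group_pvalue(ev[, j], ev_null[, , j])
    })
  }
  structure(
    list(
      rf = rf, ev = if (classify) ev, rf_null = rf_null,
      ev_null = ev_null, curves = curves, curves_held = curves_held,
      theta = theta,
      tests = tests, states = states, n_perm = n_perm, seed = seed
    ),
    class = "wm_group"
  )
}

#' @export
print.wm_group <- function(x, ...) {
  cat(sprintf(
    "wm_group: %d participants, %d permutations\n", nrow(x$rf), x$n_perm
  ))
  df <- summary(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarize a group analysis
#'
#' @param object a `wm_group`.
#' @param ... unused.
#' @return `data.frame` with one row per state: mean fidelity, its
#'   permutation p-value, mean evidence difference and its p-value.
#' @export
summary.wm_group <- function(object, ...) {
  df <- data.frame(
    state = object$states,
    mean_rf = colMeans(object$rf),
    stringsAsFactors = FALSE
  )
  if (!is.null(object$tests$rf)) {
    df$p_rf <- vapply(object$states, function(s) {
      object$tests$rf[[s]]$p_two
    }, numeric(1))
  }
  if (!is.null(object$ev)) {
    df$mean_ev_diff <- colMeans(object$ev)
    if (!is.null(object$tests$ev)) {
      df$p_ev <- vapply(object$states, function(s) {
        object$tests$ev[[s]]$p_two
      }, numeric(1))
    }
  }
  rownames(df) <- NULL
  df
}

#' Fitting targets from a group analysis
#'
#' Extracts the grand-mean re-centered reconstruction of one state
#' (centered on the remembered orientation) together with the matching
#' curve re-centered on the held-out orientation, plus the
#' between-participant standard error of the state curve — the inputs the
#' modulation-model fitting consumes.
#'
#' @param group a `wm_group` from [run_group_analysis()].
#' @param state one of `"stim"`, `"cued"`, `"fut_rel"`, `"fut_irr"`.
#' @return a `fit_targets` list (`state`, `held`, `se`).
#' @export
group_fit_targets <- function(group, state = "fut_irr") {
  stopifnot(inherits(group, "wm_group"), state %in% group$states)
  n <- ncol(group$curves[[state]])
  structure(
    list(
      state = rowMeans(group$curves[[state]]),
      held = rowMeans(group$curves_held[[state]]),
      se = apply(group$curves[[state]], 1, stats::sd) / sqrt(n)
    ),
    class = "fit_targets"
  )
}
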