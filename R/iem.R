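#' Estimate channel weights from training data
#'
#' Ordinary least squares of voxel responses on predicted channel
#' responses: the voxels x channels weight matrix solving
#' `B1 ~ C1 W'`. Equivalent to the normal-equation form
#' `W = B1' C1 (C1' C1)^-1`, but solved by QR factorization.
#'
#' @param B1 `trials x voxels` training responses.
#' @param C1 `trials x channels` predicted channel responses.
#' @return `voxels x channels` weight matrix.
#' @export
estimate_weights <- function(B1, C1) {
  B1 <- as.matrix(B1)
  C1 <- as.matrix(C1)
  if (nrow(B1) != nrow(C1)) {
    stop("B1 and C1 must have the same number of trials (rows)")
  }
  qc <- qr(C1)
  if (qc$rank < ncol(C1)) {
    stop(sprintf(
      "channel design is rank deficient (rank %d < %d channels); training orientations do not span the channel space",
      qc$rank, ncol(C1)
    ))
  }
  t(qr.coef(qc, B1))
}

#' Invert the encoding model on test data
#'
#' Estimates per-trial channel responses from test voxel patterns via the
#' model inverse `C2 = (W' W)^-1 W' B2` (least squares through the
#' estimated weights). The solve uses the singular value decomposition of
#' `W`: directions whose singular value falls below `tol` times the
#' largest are projected out instead of inverted. One such direction
#' arises structurally whenever the channel set nearly tiles orientation
#' space (the channels sum to an almost constant curve) and the data have
#' been mean-centered per voxel: that constant channel combination is
#' then unconstrained by the data, and inverting it would amplify noise
#' by many orders of magnitude without carrying orientation information.
#' For well-conditioned weights the result equals the textbook inverse
#' formula to machine precision.
#'
#' @param W `voxels x channels` weight matrix.
#' @param B2 `trials x voxels` test responses.
#' @param tol relative singular-value cutoff.
#' @return `trials x channels` matrix of estimated channel responses.
#' @export
invert_channels <- function(W, B2, tol = 1e-8) {
  W <- as.matrix(W)
  B2 <- as.matrix(B2)
  if (ncol(B2) != nrow(W)) {
    stop("B2 must have one column per voxel (row of W)")
  }
  s <- svd(W)
  if (!all(is.finite(s$d)) || s$d[1] <= 0) {
    stop("W'W is singular: estimated weights do not span the channel space")
  }
  keep <- s$d > tol * s$d[1]
  t(s$v[, keep, drop = FALSE] %*%
    ((t(s$u[, keep, drop = FALSE]) %*% t(B2)) / s$d[keep]))
}

#' Build re-centered orientation reconstructions
#'
#' The trial-wise reconstruction is the weighted sum of the hypothetical
#' channels, weighted by the estimated channel responses, then circularly
#' shifted so that relative orientation 0 corresponds to the trial's
#' presented/remembered orientation. The returned grid spans -90..89
#' degrees; re-centering is a pure circular shift and preserves the sum of
#' the curve.
#'
#' @param C2 `trials x channels` estimated channel responses.
#' @param basis the analysis `channel_basis`.
#' @param true_orientation per-trial orientation(s) to center on, degrees
#'   (rounded to the nearest grid step).
#' @return `180 x trials` matrix of class `reconstruction`; rows are
#'   relative orientations -90..89, stored in attribute `theta`.
#' @export
reconstruct <- function(C2, basis, true_orientation) {
  C2 <- matrix(C2, ncol = basis$k)
  n <- nrow(C2)
  if (length(true_orientation) == 1L) {
    true_orientation <- rep(true_orientation, n)
  }
  stopifnot(length(true_orientation) == n)
  curves <- basis$M %*% t(C2) # 180 x trials
  recenter_curves(curves, true_orientation)
}

# Circularly shift 180-point curves (columns) so that row 91 (relative
# angle 0) is each column's own center orientation.
recenter_curves <- function(curves, centers) {
  n_points <- nrow(curves)
  step <- 180 / n_points
  u <- seq(-n_points / 2, n_points / 2 - 1)
  idx <- outer(u, round(centers / step), `+`) %% n_points + 1
  out <- matrix(
    curves[cbind(as.vector(idx), rep(seq_len(ncol(curves)), each = n_points))],
    n_points, ncol(curves)
  )
  structure(out, theta = u * step, class = c("reconstruction", "matrix"))
}

#' Representational fidelity of a re-centered reconstruction
#'
#' The cosine-weighted vector mean `RF = mean(r(theta) cos(2 theta))` over
#' the re-centered grid (-90..89 degrees). Positive values indicate a
#' reconstruction peaked at the true orientation, values near zero a flat
#' (information-free) curve, and negative values an inverted
#' (suppressed) representation.
#'
#' @param recon a `reconstruction` (vector or `180 x trials` matrix from
#'   [reconstruct()]).
#' @return numeric vector, one fidelity per trial/curve.
#' @export
representational_fidelity <- function(recon) {
  if (is.null(dim(recon))) recon <- matrix(recon, ncol = 1)
  theta <- attr(recon, "theta")
  if (is.null(theta)) {
    n_points <- nrow(recon)
    theta <- seq(-n_points / 2, n_points / 2 - 1) * 180 / n_points
  }
  as.vector(crossprod(cospi(2 * theta / 180), recon)) / nrow(recon)
}

#' Z-score voxel responses across trials
#'
#' Each voxel (column) is centered and scaled to unit variance across
#' trials. Training and test sets must be normalized independently; this
#' removes non-orientation-selective baseline shifts between trial epochs.
#'
#' @param B `trials x voxels` matrix (>= 2 trials).
#' @return matrix of the same shape with column means 0 and sds 1.
#' @export
zscore_trials <- function(B) {
  B <- as.matrix(B)
  if (nrow(B) < 2) stop("need at least 2 trials to z-score")
  s <- apply(B, 2, stats::sd)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop(
      "zero-variance voxel(s) cannot be z-scored: index ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  scale(B, center = TRUE, scale = s)
}

# Z-score per voxel within each run (the convention used before epoch
# averaging / classification).
zscore_by_run <- function(B, run_id) {
  B <- as.matrix(B)
  for (r in unique(run_id)) {
    rows <- run_id == r
    B[rows, ] <- zscore_trials(B[rows, , drop = FALSE])
  }
  B
}

#' Leave-one-run-out IEM reconstruction
#'
#' For each run: estimate channel weights from all other runs' training
#' trials (all trial types pooled), invert the model on the held-out run's
#' test trials, and re-center each trial's reconstruction on its own
#' remembered orientation. Curves and representational fidelity are then
#' averaged per state across trials and folds.
#'
#' Label permutations for null distributions re-use the per-fold
#' factorizations: each permutation shuffles the *training* orientation
#' labels within runs (trial pairings intact), re-estimates the weights,
#' and re-scores the unchanged test data.
#'
#' @param train_block training `voxel_block` (e.g. stimulus epoch).
#' @param test_block test `voxel_block` (same runs; may be the same block).
#' @param basis analysis `channel_basis` (9 channels, exponent 9 by
#'   default).
#' @param center `"orientation"` to re-center on each trial's remembered
#'   orientation, `"held"` to re-center on the held-out orientation.
#' @param zscore z-score train and test sets per fold (default `TRUE`).
#' @param perms optional list of within-run permutation index vectors over
#'   the training trials (see [make_permutations()]); per-state mean
#'   fidelities are recomputed for each.
#' @return list with `curves` (per-state mean re-centered 180-point
#'   curves), `rf` (named per-state mean fidelity), `rf_trials`
#'   (per-trial fidelities with states), `n_folds`, and `null_rf`
#'   (`length(perms) x states` matrix) when permutations are supplied.
#' @export
crossval_reconstruct <- function(train_block, test_block = train_block,
                                 basis = make_channel_basis(9, 9),
                                 center = c("orientation", "held"),
                                 zscore = TRUE, perms = NULL) {
  center <- match.arg(center)
  runs <- sort(unique(test_block$run_id))
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  states <- if (is.null(test_block$state)) {
    rep("all", nrow(test_block$responses))
  } else {
    test_block$state
  }
  state_levels <- sort(unique(states))
  n_points <- nrow(basis$M)
  n_perm <- length(perms)

  curve_sum <- matrix(0, n_points, length(state_levels),
    dimnames = list(NULL, state_levels)
  )
  n_state <- stats::setNames(numeric(length(state_levels)), state_levels)
  rf_trials <- list()
  null_sum <- if (n_perm) {
    matrix(0, n_perm, length(state_levels),
      dimnames = list(NULL, state_levels)
    )
  }

  cos2 <- cospi(2 * (seq(-n_points / 2, n_points / 2 - 1) * 180 / n_points) / 180)
  for (r in runs) {
    tr <- which(train_block$run_id != r)
    te <- which(test_block$run_id == r)
    if (!length(te)) next
    B1 <- train_block$responses[tr, , drop = FALSE]
    B2 <- test_block$responses[te, , drop = FALSE]
    if (zscore) {
      B1 <- zscore_trials(B1)
      B2 <- zscore_trials(B2)
    }
    labs <- train_block$orientation[tr]
    C1 <- channel_response(basis, labs)
    centers <- switch(center,
      orientation = test_block$orientation[te],
      held = test_block$held_orientation[te]
    )
    st <- states[te]
    W <- estimate_weights(B1, C1)
    C2 <- invert_channels(W, B2)
    rec <- reconstruct(C2, basis, centers)
    rf <- representational_fidelity(rec)
    rf_trials[[length(rf_trials) + 1L]] <- data.frame(
      trial_id = test_block$trial_id[te], run_id = r, state = st, rf = rf,
      stringsAsFactors = FALSE
    )
    for (s in unique(st)) {
      cols <- st == s
      curve_sum[, s] <- curve_sum[, s] + rowSums(rec[, cols, drop = FALSE])
      n_state[s] <- n_state[s] + sum(cols)
    }
    if (n_perm) {
      # recentering indices are fixed across permutations
      step <- 180 / n_points
      u <- seq(-n_points / 2, n_points / 2 - 1)
      idx <- outer(u, round(centers / step), `+`) %% n_points + 1
      flat_idx <- cbind(as.vector(idx), rep(seq_along(te), each = n_points))
      all_labs <- train_block$orientation
      for (p in seq_len(n_perm)) {
        labs_p <- all_labs[perms[[p]][tr]]
        C1p <- channel_response(basis, labs_p)
        Wp <- estimate_weights(B1, C1p)
        C2p <- invert_channels(Wp, B2)
        curves_p <- basis$M %*% t(C2p)
        rec_p <- matrix(curves_p[flat_idx], n_points, length(te))
        rf_p <- as.vector(crossprod(cos2, rec_p)) / n_points
        for (s in unique(st)) {
          cols <- st == s
          null_sum[p, s] <- null_sum[p, s] + sum(rf_p[cols])
        }
      }
    }
  }
  rf_trials <- do.call(rbind, rf_trials)
  curves <- sweep(curve_sum, 2, n_state, `/`)
  rf <- vapply(
    state_levels,
    function(s) mean(rf_trials$rf[rf_trials$state == s]), numeric(1)
  )
  out <- list(
    curves = curves, rf = rf, rf_trials = rf_trials,
    n_folds = length(runs), theta = seq(-n_points / 2, n_points / 2 - 1) *
      180 / n_points
  )
  if (n_perm) out$null_rf <- sweep(null_sum, 2, n_state, `/`)
  out
}
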