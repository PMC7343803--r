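#' Configuration of the simulation-based model fitting
#'
#' The fitting procedure simulates reconstructions under candidate
#' modulation parameters and compares them to target curves. This object
#' fixes the simulation size (runs, voxels), the analysis basis, whether
#' the generative noise sources are on, whether per-fold z-scoring is
#' applied (on by default with noise; off for noiseless fits, where there
#' are no baseline shifts to remove and a zero-drive candidate would have
#' nothing to scale), and how many replicate simulations are averaged per
#' cost evaluation to tame the noisy objective.
#'
#' @param n_runs runs per simulated dataset (>= 2; the study design uses
#'   18).
#' @param n_rep replicate simulations averaged per cost evaluation.
#' @param sim a [sim_config()].
#' @param basis analysis `channel_basis`.
#' @param zscore z-score train/test per fold inside the IEM.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_runs = 18L, n_rep = 5L, sim = sim_config(),
                       basis = make_channel_basis(9, 9),
                       zscore = sim$noise) {
  structure(
    list(
      n_runs = as.integer(n_runs), n_rep = as.integer(n_rep),
      sim = sim, basis = basis, zscore = isTRUE(zscore)
    ),
    class = "fit_config"
  )
}

# Parameter bounds of the modulation model.
param_bounds <- function() {
  list(
    phi_test = c(0, 1), gamma = c(-1, 1), mu = c(-1, 1), omega = c(0, 1)
  )
}

as_mod_params <- function(values) {
  do.call(modulation_params, as.list(values))
}

#' Simulate the joint state/held-out reconstruction curves
#'
#' Runs the forward simulation at the candidate parameters and the
#' leave-one-run-out IEM, returning the mean re-centered reconstruction of
#' the simulated state (centered on each trial's remembered orientation)
#' together with the mean curve re-centered on the held-out orientation,
#' averaged over `n_rep` replicate simulated participants.
#'
#' @param params [modulation_params()] candidate.
#' @param cfg a [fit_config()].
#' @param seed integer seed; the same seed always yields the same curves.
#' @return list with 180-point numeric vectors `state` and `held`.
#' @export
simulate_state_curves <- function(params, cfg = fit_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 2L * cfg$n_rep)
  n_points <- nrow(cfg$basis$M)
  acc_state <- numeric(n_points)
  acc_held <- numeric(n_points)
  for (r in seq_len(cfg$n_rep)) {
    table <- generate_trial_table(cfg$n_runs, seeds[2 * r - 1])
    sim <- simulate_participant(table, params, cfg$sim, seeds[2 * r])
    cv_state <- crossval_reconstruct(sim$train, sim$test,
      basis = cfg$basis, center = "orientation", zscore = cfg$zscore
    )
    cv_held <- crossval_reconstruct(sim$train, sim$test,
      basis = cfg$basis, center = "held", zscore = cfg$zscore
    )
    acc_state <- acc_state + cv_state$curves[, 1]
    acc_held <- acc_held + cv_held$curves[, 1]
  }
  list(state = acc_state / cfg$n_rep, held = acc_held / cfg$n_rep)
}

#' Build fitting targets from known generating parameters
#'
#' Convenience wrapper producing target curves by simulating at known
#' parameters (used for parameter-recovery studies; any pair of 180-point
#' curves, e.g. experimental reconstructions, can be supplied to the
#' fitting functions instead).
#'
#' @inheritParams simulate_state_curves
#' @param se optional 180-point between-subject standard-error band of the
#'   state curve, used for the standard-error adherence diagnostic.
#' @return list of class `fit_targets` with `state`, `held`, `se`.
#' @export
make_fit_targets <- function(params, cfg = fit_config(), seed = 1L,
                             se = NULL) {
  curves <- simulate_state_curves(params, cfg, seed)
  structure(
    list(state = curves$state, held = curves$held, se = se),
    class = "fit_targets"
  )
}

#' Sum-squared-error cost of a candidate parameter vector
#'
#' Simulates at the candidate and returns the summed squared deviation of
#' both jointly fitted curves (state of interest and held-out
#' orientation) from their targets. Fitting both curves simultaneously
#' reduces over-fitting of the state of interest.
#'
#' @param params [modulation_params()] candidate.
#' @param targets a `fit_targets` (or list with `state` and `held`).
#' @param cfg a [fit_config()].
#' @param seed integer seed shared by all cost evaluations of one fit.
#' @return scalar sum squared error.
#' @export
fit_cost <- function(params, targets, cfg = fit_config(), seed = 1L) {
  curves <- simulate_state_curves(params, cfg, seed)
  sum((curves$state - targets$state)^2) + sum((curves$held - targets$held)^2)
}

#' Grid search over free modulation parameters
#'
#' Evaluates the cost on a grid of `grid_steps` points per free parameter
#' spanning its full range: the full factorial by default, or a
#' one-parameter-at-a-time sweep (others held at their fixed values) via
#' `grid_type = "one_at_a_time"`.
#'
#' @param free character vector of free parameter names, subset of
#'   `c("phi_test", "gamma", "mu", "omega")`.
#' @param targets a `fit_targets`.
#' @param cfg a [fit_config()].
#' @param seed integer seed shared across evaluations.
#' @param fixed named list of values for non-free parameters (default 0;
#'   `phi_test` defaults to 0 as well when not free).
#' @param grid_steps points per free parameter.
#' @param grid_type `"factorial"` or `"one_at_a_time"`.
#' @return list with `params` (best full candidate), `sse`, `n_eval`.
#' @export
grid_search <- function(free, targets, cfg = fit_config(), seed = 1L,
                        fixed = list(), grid_steps = 11L,
                        grid_type = c("factorial", "one_at_a_time")) {
  grid_type <- match.arg(grid_type)
  bounds <- param_bounds()
  if (!length(free)) stop("need at least one free parameter")
  free <- match.arg(free, names(bounds), several.ok = TRUE)
  base_vals <- list(phi_test = 0, gamma = 0, mu = 0, omega = 0)
  base_vals[names(fixed)] <- fixed
  axes <- lapply(free, function(p) {
    seq(bounds[[p]][1], bounds[[p]][2], length.out = grid_steps)
  })
  names(axes) <- free
  eval_at <- function(vals) {
    cand <- base_vals
    cand[names(vals)] <- vals
    fit_cost(as_mod_params(cand), targets, cfg, seed)
  }
  if (grid_type == "factorial") {
    grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
    sse <- vapply(
      seq_len(nrow(grid)),
      function(i) eval_at(as.list(grid[i, , drop = FALSE])),
      numeric(1)
    )
    best <- which.min(sse)
    vals <- as.list(grid[best, , drop = FALSE])
    n_eval <- nrow(grid)
    best_sse <- sse[best]
  } else {
    vals <- base_vals[free]
    n_eval <- 0L
    for (p in free) {
      sse <- vapply(axes[[p]], function(v) {
        vv <- vals
        vv[[p]] <- v
        eval_at(vv)
      }, numeric(1))
      vals[[p]] <- axes[[p]][which.min(sse)]
      n_eval <- n_eval + grid_steps
    }
    best_sse <- eval_at(vals)
    n_eval <- n_eval + 1L
  }
  cand <- base_vals
  cand[names(vals)] <- vals
  list(params = as_mod_params(cand), sse = best_sse, n_eval = n_eval)
}

#' Refine a fit with bounded derivative-free search
#'
#' Local refinement from a starting candidate (typically the best grid
#' vertex) using Nelder-Mead on a sinusoidal reparameterization that
#' enforces the parameter bounds; all cost evaluations share one seed, so
#' replicate-averaged objectives are deterministic and the search is
#' reproducible. The best candidate ever evaluated (including the start)
#' is returned, so the refined error never exceeds the starting error.
#'
#' @param start starting [modulation_params()] (e.g. from
#'   [grid_search()]).
#' @param free free parameter names.
#' @param targets a `fit_targets`.
#' @param cfg a [fit_config()].
#' @param seed integer seed.
#' @param maxit maximum simplex iterations.
#' @return object of class `fit_result`: `params`, `free`, `n_free`,
#'   `sse` (joint), `sse_state`, `r2`, `adj_r2`, `se_band_fraction`,
#'   `curves` (fitted state/held), `df_data`, `n_eval`.
#' @export
refine_fit <- function(start, free, targets, cfg = fit_config(),
                       seed = 1L, maxit = 200L) {
  bounds <- param_bounds()
  free <- match.arg(free, names(bounds), several.ok = TRUE)
  base_vals <- unclass(start)[c("phi_test", "gamma", "mu", "omega")]
  lo <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  hi <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  to_x <- function(t) lo + (hi - lo) * (sin(t) + 1) / 2
  to_t <- function(x) asin(pmin(1, pmax(-1, 2 * (x - lo) / (hi - lo) - 1)))
  best <- new.env(parent = emptyenv())
  best$sse <- Inf
  best$vals <- base_vals
  obj <- function(t) {
    vals <- base_vals
    vals[free] <- as.list(to_x(t))
    sse <- fit_cost(as_mod_params(vals), targets, cfg, seed)
    if (is.finite(sse) && sse < best$sse) {
      best$sse <- sse
      best$vals <- vals
    }
    if (!is.finite(sse)) stop("non-finite cost at candidate")
    sse
  }
  t0 <- to_t(unlist(base_vals[free]))
  start_sse <- obj(t0)
  if (start_sse > 0) {
    if (length(free) == 1L) {
      stats::optimize(function(t) obj(t), interval = c(-pi / 2, pi / 2),
        tol = 1e-6)
    } else {
      suppressWarnings(stats::optim(t0, obj,
        method = "Nelder-Mead",
        control = list(maxit = maxit, reltol = 1e-10)
      ))
    }
  }
  fitted <- simulate_state_curves(as_mod_params(best$vals), cfg, seed)
  finalize_fit(best$vals, free, fitted, targets)
}

# Assemble a fit_result from fitted curves and targets.
finalize_fit <- function(vals, free, fitted, targets, df_data = 24L) {
  sse_state <- sum((fitted$state - targets$state)^2)
  sse <- sse_state + sum((fitted$held - targets$held)^2)
  ss_tot <- sum((targets$state - mean(targets$state))^2)
  r2 <- if (ss_tot > 0) 1 - sse_state / ss_tot else NA_real_
  n_free <- length(free)
  adj_r2 <- if (is.na(r2)) {
    NA_real_
  } else {
    1 - (1 - r2) * (df_data - 1) / (df_data - 1 - n_free)
  }
  sef <- if (!is.null(targets$se)) {
    mean(abs(fitted$state - targets$state) <= targets$se)
  } else {
    NA_real_
  }
  structure(
    list(
      params = as_mod_params(vals), free = free, n_free = n_free,
      sse = sse, sse_state = sse_state, r2 = r2, adj_r2 = adj_r2,
      se_band_fraction = sef, curves = fitted, df_data = df_data
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "fit_result [%s free]: phi=%.3f gamma=%.3f mu=%.3f omega=%.3f | SSE=%.4g R2=%.3f adjR2=%.3f\n",
    paste(x$free, collapse = ","), p$phi_test, p$gamma, p$mu, p$omega,
    x$sse, x$r2, x$adj_r2
  ))
  invisible(x)
}

#' Fit one model (grid search then refinement)
#'
#' @inheritParams grid_search
#' @param grid_steps points per free parameter in the initializing grid.
#' @param maxit refinement iterations.
#' @return a `fit_result` (see [refine_fit()]).
#' @export
fit_state_model <- function(free, targets, cfg = fit_config(), seed = 1L,
                            fixed = list(), grid_steps = 11L,
                            maxit = 200L,
                            grid_type = c("factorial", "one_at_a_time")) {
  g <- grid_search(free, targets, cfg, seed,
    fixed = fixed,
    grid_steps = grid_steps, grid_type = match.arg(grid_type)
  )
  refine_fit(g$params, free, targets, cfg, seed, maxit = maxit)
}

#' Nested F-test between two fitted models
#'
#' `F = [(SSE_r - SSE_f) / (p_f - p_r)] / [SSE_f / (df_data - n_full)]`
#' where `df_data = 24` (the effective number of data degrees of freedom:
#' 8 tuning curves, each described by a center, height, and width) and the
#' parameter count of the full model is `n_fixed + n_free` with 6 fixed
#' generative parameters (the two noise amplitudes, neural noise sd,
#' stimulus uncertainty, and the shift sigmoid's slope and midpoint).
#' Comparing a memory-strength-only model to memory strength + gain thus
#' uses df (1, 16). If the full model's refined error exceeds the
#' restricted one (possible only through numerical noise, since the models
#' are nested), the full error is clamped to the restricted error and the
#' test reports no improvement.
#'
#' @param restricted,full `fit_result`s with nested free-parameter sets.
#' @param df_data effective data degrees of freedom.
#' @param n_fixed count of fixed generative parameters.
#' @return list of class `nested_f`: `f_stat`, `df_num`, `df_den`, `p`,
#'   `sse_restricted`, `sse_full`.
#' @export
nested_f_test <- function(restricted, full, df_data = 24L, n_fixed = 6L) {
  if (!all(restricted$free %in% full$free) ||
    length(full$free) <= length(restricted$free)) {
    stop("models are not nested (restricted$free must be a strict subset)")
  }
  sse_r <- restricted$sse
  sse_f <- min(full$sse, sse_r)
  df_num <- full$n_free - restricted$n_free
  df_den <- df_data - (n_fixed + full$n_free)
  if (df_den <= 0) stop("non-positive denominator degrees of freedom")
  f <- if (sse_f == 0) {
    if (sse_r == sse_f) 0 else Inf
  } else {
    ((sse_r - sse_f) / df_num) / (sse_f / df_den)
  }
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  structure(
    list(
      f_stat = f, df_num = df_num, df_den = df_den, p = p,
      sse_restricted = sse_r, sse_full = sse_f
    ),
    class = "nested_f"
  )
}

#' @export
print.nested_f <- function(x, ...) {
  cat(sprintf(
    "nested F(%d,%d) = %.3f, p = %.4g\n", x$df_num, x$df_den, x$f_stat, x$p
  ))
  invisible(x)
}

#' Fit and compare a family of modulation models
#'
#' Fits each model in `models` (named character vectors of free
#' parameters) to the same targets with a shared seed, reports sum squared
#' error, R-squared and adjusted R-squared per model, and nested F-tests
#' of every model against each strict sub-model in the family.
#'
#' @param targets a `fit_targets`.
#' @param cfg a [fit_config()].
#' @param seed integer seed.
#' @param models named list of free-parameter sets.
#' @param grid_steps,maxit passed to [fit_state_model()].
#' @return list with `fits` (named `fit_result`s), `table`
#'   (per-model summary `data.frame`), `comparisons` (named `nested_f`
#'   list, names `restricted_vs_full`).
#' @export
compare_mechanisms <- function(targets, cfg = fit_config(), seed = 1L,
                               models = list(
                                 phi = "phi_test",
                                 "phi+gamma" = c("phi_test", "gamma"),
                                 "phi+mu" = c("phi_test", "mu"),
                                 "phi+omega" = c("phi_test", "omega")
                               ),
                               grid_steps = 11L, maxit = 200L) {
  fits <- lapply(models, function(free) {
    fit_state_model(free, targets, cfg, seed,
      grid_steps = grid_steps,
      maxit = maxit
    )
  })
  table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(
      model = nm, free = paste(f$free, collapse = "+"),
      phi_test = f$params$phi_test, gamma = f$params$gamma,
      mu = f$params$mu, omega = f$params$omega,
      sse = f$sse, r2 = f$r2, adj_r2 = f$adj_r2,
      se_band_fraction = f$se_band_fraction,
      stringsAsFactors = FALSE
    )
  }))
  comparisons <- list()
  nms <- names(fits)
  for (i in seq_along(fits)) {
    for (j in seq_along(fits)) {
      fi <- fits[[i]]
      fj <- fits[[j]]
      if (all(fi$free %in% fj$free) && fj$n_free > fi$n_free) {
        comparisons[[paste0(nms[i], "_vs_", nms[j])]] <-
          nested_f_test(fi, fj)
      }
    }
  }
  list(fits = fits, table = table, comparisons = comparisons)
}
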