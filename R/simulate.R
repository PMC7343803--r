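#' Simulator configuration
#'
#' Generative settings of the forward model of voxel responses. Defaults
#' follow the study conditions: 200 voxels per (hemisphere-equivalent)
#' pool, 9 tuning channels raised to the 8th power, Gaussian stimulus
#' drive (amplitude 1, sd 18 degrees), "neural" noise with mean 0.2 and sd
#' 0.05 added to the stimulus drive, and BOLD noise calibrated to a
#' signal-to-noise ratio of 0.7 (sd of the noiseless signal over sd of the
#' BOLD noise).
#'
#' @param n_voxels voxels per simulated pool.
#' @param k number of tuning channels.
#' @param exponent_sim tuning exponent of the simulated channels.
#' @param stim_amplitude,stim_sd Gaussian stimulus drive parameters.
#' @param neural_mean,neural_sd Gaussian neural noise parameters.
#' @param target_snr target signal-to-noise ratio for BOLD noise.
#' @param noise if `FALSE`, both noise sources are switched off (used for
#'   noiseless round-trip checks).
#' @param phi_train stimulus strength for training data (1: training
#'   mimics the stimulus-presentation period).
#' @param width_variant width-modulation convention, see
#'   [compute_modulations()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_voxels = 200L, k = 9L, exponent_sim = 8,
                       stim_amplitude = 1, stim_sd = 18,
                       neural_mean = 0.2, neural_sd = 0.05,
                       target_snr = 0.7, noise = TRUE, phi_train = 1,
                       width_variant = "consistent") {
  structure(
    list(
      n_voxels = as.integer(n_voxels), k = as.integer(k),
      exponent_sim = exponent_sim, stim_amplitude = stim_amplitude,
      stim_sd = stim_sd, neural_mean = neural_mean, neural_sd = neural_sd,
      target_snr = target_snr, noise = isTRUE(noise),
      phi_train = phi_train, width_variant = width_variant
    ),
    class = "sim_config"
  )
}

#' Default modulation parameters per working-memory state
#'
#' The pseudo-experiment's generating parameters for the four states:
#' near-full memory strength for perceived stimuli, reduced strength for
#' cued items, essentially no sustained drive for un-cued future-relevant
#' items, and strong gain suppression (with moderate drive) for un-cued
#' future-irrelevant items, which inverts the reconstruction.
#'
#' @return named list of [modulation_params()] for
#'   `stim`, `cued`, `fut_rel`, `fut_irr`.
#' @export
default_state_params <- function() {
  list(
    stim = modulation_params(phi_test = 0.98),
    cued = modulation_params(phi_test = 0.61),
    fut_rel = modulation_params(phi_test = 0.03),
    fut_irr = modulation_params(phi_test = 0.49, gamma = 0.95)
  )
}

#' Simulate rectified channel responses to a stimulus
#'
#' `C = M' (phi * S + eps_neural)`, floored at 0 to reflect a firing rate.
#' The neural noise is added to the 180-point stimulus drive before the
#' channel projection.
#'
#' @param M `n_points x k` channel matrix (possibly modulated).
#' @param S stimulus drive: vector of length `n_points` or
#'   `n_points x n_trials` matrix.
#' @param phi stimulus strength scaling.
#' @param n_trials number of trials (when `S` is a single vector).
#' @param neural_mean,neural_sd Gaussian neural noise parameters; set the
#'   sd to 0 for deterministic responses.
#' @return `k x n_trials` matrix of non-negative channel responses.
#' @export
simulate_channel_responses <- function(M, S, phi = 1, n_trials = NULL,
                                       neural_mean = 0.2, neural_sd = 0.05) {
  if (is.null(dim(S))) {
    n_trials <- if (is.null(n_trials)) 1L else n_trials
    S <- matrix(S, nrow = length(S), ncol = n_trials)
  }
  n_points <- nrow(S)
  n_trials <- ncol(S)
  eps <- if (neural_sd > 0 || neural_mean != 0) {
    matrix(stats::rnorm(n_points * n_trials, neural_mean, neural_sd),
      n_points, n_trials
    )
  } else {
    0
  }
  pmax(crossprod(M, phi * S + eps), 0)
}

#' Calibrate BOLD noise to a target signal-to-noise ratio
#'
#' SNR is defined as the standard deviation of the noiseless signal
#' entries (`W C` over all trials and voxels) divided by the BOLD noise
#' standard deviation; the returned sd makes that ratio equal
#' `target_snr`.
#'
#' @param W `voxels x channels` weight matrix.
#' @param C `channels x trials` channel responses.
#' @param target_snr target ratio (> 0).
#' @return the BOLD noise standard deviation.
#' @export
calibrate_noise <- function(W, C, target_snr = 0.7) {
  if (!is.finite(target_snr) || target_snr <= 0) {
    stop("`target_snr` must be positive")
  }
  s <- stats::sd(as.vector(W %*% C))
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: sd of W %*% C is zero")
  }
  s / target_snr
}

# Draw a voxels x channels weight matrix: uniform(0, 1), rows normalized
# to sum to 1.
draw_weights <- function(n_voxels, k) {
  W <- matrix(stats::runif(n_voxels * k), n_voxels, k)
  W / rowSums(W)
}

# Assemble a voxel_block from channel responses plus BOLD noise.
make_voxel_block <- function(C, W, bold_sd, run_id, trial_id, orientation,
                             base = NULL, held_orientation = NULL,
                             state = NULL) {
  B <- t(W %*% C)
  if (bold_sd > 0) {
    B <- B + matrix(stats::rnorm(length(B), 0, bold_sd), nrow(B), ncol(B))
  }
  structure(
    list(
      responses = B, run_id = run_id, trial_id = trial_id,
      orientation = orientation, base = base,
      held_orientation = held_orientation, state = state
    ),
    class = "voxel_block"
  )
}

#' @export
print.voxel_block <- function(x, ...) {
  cat(sprintf(
    "voxel_block: %d trials x %d voxels, %d runs%s\n",
    nrow(x$responses), ncol(x$responses), length(unique(x$run_id)),
    if (!is.null(x$state)) {
      paste0(", states: ", paste(sort(unique(x$state)), collapse = "/"))
    } else ""
  ))
  invisible(x)
}

# Channel responses for a set of trials sharing config; per-trial
# modulated bases are computed once per unique remembered orientation.
simulate_trials_C <- function(basis, orientations, params, config,
                              phi) {
  n <- length(orientations)
  n_points <- length(basis$grid)
  neural_sd <- if (config$noise) config$neural_sd else 0
  neural_mean <- if (config$noise) config$neural_mean else 0
  uo <- unique(orientations)
  S_u <- vapply(
    uo,
    function(th) {
      stimulus_vector(th, config$stim_amplitude, config$stim_sd, n_points)
    },
    numeric(n_points)
  )
  modulated <- !is.null(params) &&
    (params$gamma != 0 || params$mu != 0 || params$omega != 0)
  C <- matrix(0, basis$k, n)
  for (j in seq_along(uo)) {
    cols <- which(orientations == uo[j])
    M <- if (modulated) {
      modulate_basis(basis, params, uo[j], config$width_variant)
    } else {
      basis$M
    }
    C[, cols] <- simulate_channel_responses(
      M, S_u[, j], phi = phi, n_trials = length(cols),
      neural_mean = neural_mean, neural_sd = neural_sd
    )
  }
  C
}

#' Simulate one participant's run-matched training and test data
#'
#' Reproduces the study's simulation design: channel weights drawn
#' uniformly and row-normalized, 18 runs of 24 trials (or whatever the
#' trial table provides), training data generated from the unmodulated
#' tuning channels at full stimulus strength (`phi_train = 1`), and test
#' data generated from the state-modulated channels at memory strength
#' `phi_test`. Each test run repeats the stimuli of the matching training
#' run with independent noise; only the contralateral (cued-side) item is
#' represented. The remembered orientation of each trial is the cued
#' side's orientation; the other side's orientation is carried along as
#' the held-out orientation.
#'
#' @param table a `trial_table` from [generate_trial_table()].
#' @param params [modulation_params()] of the simulated test state.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `train` and `test` `voxel_block`s, the weight matrix
#'   `W`, the calibrated `bold_sd`, plus `config` and `params`.
#' @export
simulate_participant <- function(table, params = modulation_params(),
                                 config = sim_config(), seed = 1L) {
  set.seed(as.integer(seed))
  theta <- ifelse(table$cued_side == "left", table$orient_left,
    table$orient_right
  )
  held <- ifelse(table$cued_side == "left", table$orient_right,
    table$orient_left
  )
  base <- ifelse(table$cued_side == "left", table$base_left,
    table$base_right
  )
  basis <- make_channel_basis(config$k, config$exponent_sim)
  W <- draw_weights(config$n_voxels, config$k)
  C_train <- simulate_trials_C(basis, theta, NULL, config,
    phi = config$phi_train
  )
  C_test <- simulate_trials_C(basis, theta, params, config,
    phi = params$phi_test
  )
  bold_sd <- if (config$noise) {
    calibrate_noise(W, C_train, config$target_snr)
  } else {
    0
  }
  train <- make_voxel_block(C_train, W, bold_sd, table$run_id,
    table$trial_id, theta,
    base = base, held_orientation = held
  )
  test <- make_voxel_block(C_test, W, bold_sd, table$run_id,
    table$trial_id, theta,
    base = base, held_orientation = held
  )
  list(
    train = train, test = test, W = W, bold_sd = bold_sd,
    config = config, params = params
  )
}

#' Simulate a pseudo-experimental dataset for one participant
#'
#' Stands in for the (unavailable) experimental fMRI data: two
#' hemisphere-equivalent pools of voxels, each representing the
#' contralateral item only, with per-epoch blocks whose generating
#' parameters depend on each item's working-memory state. The stimulus
#' epoch uses the `stim` parameters for both items; during delay 1 the
#' cued-side item uses `cued` and the other item `fut_rel` (RB trials) or
#' `fut_irr` (RS trials); during delay 2 (RB trials only) the roles
#' reverse (`cued` for the second-cued item, `fut_irr` for the
#' already-tested one). BOLD noise is calibrated once per hemisphere from
#' the stimulus-epoch signal.
#'
#' @param table a `trial_table`.
#' @param state_params named list of [modulation_params()] covering
#'   `stim`, `cued`, `fut_rel`, `fut_irr`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param epochs which epochs to generate.
#' @return object of class `wm_participant`: list with the `table`, the
#'   long state labels, and per-hemisphere lists of `voxel_block`s
#'   (`stimulus`, `delay1`, `delay2`).
#' @export
simulate_pseudo_experiment <- function(table,
                                       state_params = default_state_params(),
                                       config = sim_config(), seed = 1L,
                                       epochs = c(
                                         "stimulus", "delay1", "delay2"
                                       )) {
  need <- c("stim", "cued", "fut_rel", "fut_irr")
  missing_states <- setdiff(need, names(state_params))
  if (length(missing_states)) {
    stop(
      "missing state parameters: ",
      paste(missing_states, collapse = ", ")
    )
  }
  set.seed(as.integer(seed))
  labels <- label_states(table)
  basis <- make_channel_basis(config$k, config$exponent_sim)
  all_bases <- sort(unique(c(table$base_left, table$base_right)))
  hemis <- list()
  for (hemi in c("left", "right")) {
    side <- if (hemi == "left") "right" else "left" # contralateral item
    ori <- if (side == "left") table$orient_left else table$orient_right
    base <- if (side == "left") table$base_left else table$base_right
    other_ori <- if (side == "left") table$orient_right else table$orient_left
    W <- draw_weights(config$n_voxels, config$k)
    blocks <- list()
    bold_sd <- NULL
    for (ep in intersect(c("stimulus", "delay1", "delay2"), epochs)) {
      lab <- labels[labels$epoch == ep & labels$side == side, ]
      if (!nrow(lab)) next
      idx <- match(lab$trial_id, table$trial_id)
      st <- lab$state
      C <- matrix(0, config$k, nrow(lab))
      for (s in unique(st)) {
        rows <- which(st == s)
        p <- state_params[[s]]
        C[, rows] <- simulate_trials_C(
          basis, ori[idx][rows], p, config, phi = p$phi_test
        )
      }
      if (ep == "stimulus") {
        bold_sd <- if (config$noise) {
          calibrate_noise(W, C, config$target_snr)
        } else {
          0
        }
      }
      blocks[[ep]] <- make_voxel_block(
        C, W, bold_sd, table$run_id[idx], table$trial_id[idx],
        ori[idx],
        base = base[idx], held_orientation = other_ori[idx], state = st
      )
    }
    hemis[[hemi]] <- list(W = W, bold_sd = bold_sd, blocks = blocks)
  }
  structure(
    list(
      table = table, labels = labels, hemispheres = hemis,
      base_set = all_bases, config = config, state_params = state_params
    ),
    class = "wm_participant"
  )
}

#' @export
print.wm_participant <- function(x, ...) {
  cat(sprintf(
    "wm_participant: %d trials, %d runs, %d voxels per hemisphere\n",
    nrow(x$table), length(unique(x$table$run_id)), x$config$n_voxels
  ))
  invisible(x)
}
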