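#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end pipeline; all
#' defaults are the study's design values: 6 participants, 18 runs of 24
#' trials, 200 voxels per hemisphere pool, a 9-channel analysis basis
#' raised to the 9th power over simulated tuning channels raised to the
#' 8th, SNR 0.7, L2 penalty 10, and 1,000 label permutations.
#'
#' @param seed master seed for the whole pipeline.
#' @param n_participants simulated participants.
#' @param n_runs runs per participant (24 trials each).
#' @param n_voxels voxels per hemisphere pool.
#' @param k channels.
#' @param exponent_iem analysis-basis exponent.
#' @param exponent_sim simulated tuning exponent.
#' @param target_snr BOLD signal-to-noise target.
#' @param width_variant width-modulation convention.
#' @param n_perm label permutations for the fidelity null.
#' @param classify_n_perm label permutations for the decoder null (capped
#'   at `n_perm`).
#' @param penalty decoder L2 penalty.
#' @param state_params named per-state generating [modulation_params()].
#' @param do_fit also fit modulation models to the group curves.
#' @param fit_state state whose curves are fit.
#' @param fit_models named free-parameter sets for [compare_mechanisms()].
#' @param fit_n_runs,fit_n_rep,fit_n_voxels size of the fitting
#'   simulations.
#' @param write_data also write the simulated voxel responses to CSV.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_participants = 6L, n_runs = 18L,
                       n_voxels = 200L, k = 9L, exponent_iem = 9,
                       exponent_sim = 8, target_snr = 0.7,
                       width_variant = "consistent",
                       n_perm = 1000L, classify_n_perm = 100L,
                       penalty = 10,
                       state_params = default_state_params(),
                       do_fit = FALSE, fit_state = "fut_irr",
                       fit_models = list(
                         phi = "phi_test",
                         "phi+gamma" = c("phi_test", "gamma")
                       ),
                       fit_n_runs = 6L, fit_n_rep = 2L,
                       fit_n_voxels = 100L,
                       write_data = FALSE) {
  structure(
    list(
      seed = as.integer(seed), n_participants = as.integer(n_participants),
      n_runs = as.integer(n_runs), n_voxels = as.integer(n_voxels),
      k = as.integer(k), exponent_iem = exponent_iem,
      exponent_sim = exponent_sim, target_snr = target_snr,
      width_variant = width_variant, n_perm = as.integer(n_perm),
      classify_n_perm = as.integer(classify_n_perm), penalty = penalty,
      state_params = state_params, do_fit = isTRUE(do_fit),
      fit_state = fit_state, fit_models = fit_models,
      fit_n_runs = as.integer(fit_n_runs),
      fit_n_rep = as.integer(fit_n_rep),
      fit_n_voxels = as.integer(fit_n_voxels),
      write_data = isTRUE(write_data)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [run_config()] may appear in the file; missing fields keep
#' their defaults. `state_params` entries are given as mappings of
#' `phi_test`/`gamma`/`mu`/`omega`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$state_params)) {
    raw$state_params <- lapply(raw$state_params, function(p) {
      do.call(modulation_params, p)
    })
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

# Serialize a config (and anything jsonlite can handle) and hash it, so
# outputs can carry provenance of the exact configuration.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(
    unclass_deep(config),
    auto_unbox = TRUE, digits = NA
  )), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Write / read a voxel block as CSV
#'
#' Plain-text serialization of a `voxel_block`: metadata columns
#' (`trial_id`, `run_id`, `orientation`, `held_orientation`, `base`,
#' `state`) followed by one column per voxel.
#'
#' @param block a `voxel_block`.
#' @param path CSV file path.
#' @return `write_voxel_block` returns `path` invisibly;
#'   `read_voxel_block` returns a `voxel_block`.
#' @export
write_voxel_block <- function(block, path) {
  meta <- data.frame(
    trial_id = block$trial_id, run_id = block$run_id,
    orientation = block$orientation,
    held_orientation = if (is.null(block$held_orientation)) NA else block$held_orientation,
    base = if (is.null(block$base)) NA else block$base,
    state = if (is.null(block$state)) NA else block$state
  )
  resp <- as.data.frame(block$responses)
  names(resp) <- sprintf("v%04d", seq_len(ncol(resp)))
  utils::write.csv(cbind(meta, resp), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_block
#' @export
read_voxel_block <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vox <- grep("^v[0-9]+$", names(df))
  structure(
    list(
      responses = as.matrix(df[, vox]),
      run_id = df$run_id, trial_id = df$trial_id,
      orientation = df$orientation,
      held_orientation = if (all(is.na(df$held_orientation))) NULL else df$held_orientation,
      base = if (all(is.na(df$base))) NULL else df$base,
      state = if (all(is.na(df$state))) NULL else df$state
    ),
    class = "voxel_block"
  )
}

#' Run the full analysis pipeline
#'
#' Executes design -> simulate -> reconstruct/classify -> permutation
#' stats (-> optional model fitting) and writes all results under
#' `out_dir`: per-participant trial tables (`trials_p*.csv`), the
#' per-participant state means (`fidelity.csv`), grand-mean re-centered
#' reconstruction curves with between-subject standard errors
#' (`curves.csv`), permutation test results (`stats.json`), optional model
#' fits (`fits.json`, `model_table.csv`), and a `summary.json` carrying
#' the full configuration and its hash. The pipeline is deterministic
#' given `config$seed`. If `out_dir` already contains a `summary.json`
#' with the same configuration hash the run is skipped (unless
#' `force = TRUE`).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param force re-run even if outputs with the same hash exist.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the `wm_group` result, the summary
#'   list, and the optional fit comparison.
#' @export
run_pipeline <- function(config = run_config(), out_dir, force = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(...)
  summary_path <- file.path(out_dir, "summary.json")
  if (!force && file.exists(summary_path)) {
    prev <- jsonlite::read_json(summary_path)
    if (identical(prev$config_hash, hash)) {
      say("outputs up to date (config hash ", hash, "); skipping")
      return(invisible(NULL))
    }
  }
  # same seed derivation as run_group_analysis, so the written trial
  # tables and data are exactly those entering the analysis
  part_seeds <- matrix(
    derive_seeds(config$seed, 3L * config$n_participants),
    ncol = 3
  )
  fit_seed <- derive_seeds(config$seed + 1L, 1L)
  basis <- make_channel_basis(config$k, config$exponent_iem)
  sim_cfg <- sim_config(
    n_voxels = config$n_voxels, k = config$k,
    exponent_sim = config$exponent_sim, target_snr = config$target_snr,
    width_variant = config$width_variant
  )

  say("stage design: ", config$n_participants, " trial tables")
  tables <- lapply(seq_len(config$n_participants), function(i) {
    tab <- generate_trial_table(config$n_runs, part_seeds[i, 1])
    utils::write.csv(tab, file.path(out_dir, sprintf("trials_p%02d.csv", i)),
      row.names = FALSE
    )
    tab
  })

  say("stage simulate + reconstruct + classify")
  group <- run_group_analysis(
    n_participants = config$n_participants, n_runs = config$n_runs,
    state_params = config$state_params, config = sim_cfg, basis = basis,
    n_perm = config$n_perm, seed = config$seed, classify = TRUE,
    classify_n_perm = config$classify_n_perm, penalty = config$penalty
  )
  if (config$write_data) {
    say("stage simulate: writing voxel responses")
    for (i in seq_len(config$n_participants)) {
      part <- simulate_pseudo_experiment(
        tables[[i]], config$state_params, sim_cfg, part_seeds[i, 2]
      )
      for (hemi in names(part$hemispheres)) {
        for (ep in names(part$hemispheres[[hemi]]$blocks)) {
          write_voxel_block(
            part$hemispheres[[hemi]]$blocks[[ep]],
            file.path(out_dir, sprintf("data_p%02d_%s_%s.csv", i, hemi, ep))
          )
        }
      }
    }
  }

  fid <- data.frame(
    participant = rep(seq_len(config$n_participants), times = 4),
    state = rep(group$states, each = config$n_participants),
    rf = as.vector(group$rf),
    evidence_diff = as.vector(group$ev)
  )
  utils::write.csv(fid, file.path(out_dir, "fidelity.csv"),
    row.names = FALSE
  )
  curves <- do.call(rbind, lapply(group$states, function(s) {
    data.frame(
      state = s, theta = group$theta,
      mean = rowMeans(group$curves[[s]]),
      se = apply(group$curves[[s]], 1, stats::sd) / sqrt(ncol(group$curves[[s]])),
      mean_held = rowMeans(group$curves_held[[s]])
    )
  }))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
    row.names = FALSE
  )

  say("stage stats")
  stats_out <- list(
    config_hash = hash, seed = config$seed, n_perm = config$n_perm,
    states = lapply(stats::setNames(group$states, group$states), function(s) {
      list(
        mean_rf = mean(group$rf[, s]),
        rf_p_two = group$tests$rf[[s]]$p_two,
        rf_p_label = format_pvalue(group$tests$rf[[s]]$p_two, config$n_perm),
        mean_evidence_diff = mean(group$ev[, s]),
        ev_p_two = if (!is.null(group$tests$ev)) group$tests$ev[[s]]$p_two
      )
    }),
    rf_anova = list(
      f = group$tests$rf_anova$f_stat, df = group$tests$rf_anova$df,
      p = group$tests$rf_anova$p
    )
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )

  comparison <- NULL
  if (config$do_fit) {
    say("stage fit: ", config$fit_state)
    targets <- group_fit_targets(group, config$fit_state)
    fcfg <- fit_config(
      n_runs = config$fit_n_runs, n_rep = config$fit_n_rep,
      sim = sim_config(
        n_voxels = config$fit_n_voxels, k = config$k,
        exponent_sim = config$exponent_sim,
        target_snr = config$target_snr,
        width_variant = config$width_variant
      ),
      basis = basis
    )
    comparison <- compare_mechanisms(targets, fcfg,
      seed = fit_seed,
      models = config$fit_models
    )
    utils::write.csv(comparison$table,
      file.path(out_dir, "model_table.csv"),
      row.names = FALSE
    )
    fits_out <- list(
      config_hash = hash, state = config$fit_state,
      models = lapply(comparison$fits, function(f) {
        list(
          free = f$free, params = unclass(f$params), sse = f$sse,
          r2 = f$r2, adj_r2 = f$adj_r2,
          se_band_fraction = f$se_band_fraction
        )
      }),
      comparisons = lapply(comparison$comparisons, function(cmp) {
        list(
          f = cmp$f_stat, df = c(cmp$df_num, cmp$df_den), p = cmp$p
        )
      })
    )
    jsonlite::write_json(fits_out, file.path(out_dir, "fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }

  summary_out <- list(
    config_hash = hash,
    config = unclass_deep(config),
    states = stats_out$states,
    rf_anova = stats_out$rf_anova,
    epochs = epoch_spec(),
    state_mapping = list(
      delay1 = list(RB = c(cued = "first-cued", fut_rel = "second-cued"),
                    RS = c(cued = "cued", fut_irr = "un-cued")),
      delay2 = list(RB = c(cued = "second-cued", fut_irr = "first-cued"))
    )
  )
  jsonlite::write_json(summary_out, summary_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  say("done: ", out_dir)
  invisible(list(group = group, summary = summary_out,
    comparison = comparison))
}
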