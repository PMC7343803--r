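# Shared fixtures, all generated in code.

# Small pseudo-experimental participant (fast; defaults keep all states).
tiny_participant <- function(n_runs = 3, n_voxels = 30, seed = 101,
                             state_params = default_state_params(),
                             noise = TRUE) {
  tab <- generate_trial_table(n_runs, seed)
  simulate_pseudo_experiment(
    tab, state_params,
    sim_config(n_voxels = n_voxels, noise = noise),
    seed = seed + 1
  )
}

# Noiseless fitting configuration at reduced problem size.
noiseless_fit_cfg <- function(n_voxels = 40, n_runs = 2) {
  fit_config(
    n_runs = n_runs, n_rep = 1,
    sim = sim_config(n_voxels = n_voxels, noise = FALSE),
    zscore = FALSE
  )
}

# Noisy fitting configuration at reduced problem size.
noisy_fit_cfg <- function(n_voxels = 60, n_runs = 4, n_rep = 2) {
  fit_config(
    n_runs = n_runs, n_rep = n_rep,
    sim = sim_config(n_voxels = n_voxels, noise = TRUE)
  )
}
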