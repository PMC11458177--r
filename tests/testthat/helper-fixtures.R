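# Fixtures are generated in code; nothing is stored on disk.

# Noiseless (or noisy) single-delay dataset with the pre-translocated
# distance pinned to C, for closure (parameter-recovery) studies.
closure_dataset <- function(condition, C, t_grid = default_time_grid(),
                            n_replicates = 1L, noise_sd = 0, seed = NULL) {
  des <- experiment_design(dt1 = 0, condition = condition,
                           excluded_length = C, v_gammaS = 0,
                           noise_sd = noise_sd, n_replicates = n_replicates,
                           seed = seed, t_grid = t_grid)
  simulate_dataset(des)
}

# Multi-delay kinematic dataset: common terminal dissociation rate so peak
# times read arrival times (see clpb_conditions docs).
kinematic_dataset <- function(condition = "atp_atpgs_1to1",
                              dt1 = c(300, 420, 600),
                              t_grid = default_time_grid(),
                              n_replicates = 1L, noise_sd = 0, seed = NULL) {
  cond <- clpb_conditions(condition)
  des <- experiment_design(dt1 = dt1, condition = condition,
                           k_end = cond$k_end_kinematic,
                           noise_sd = noise_sd, n_replicates = n_replicates,
                           seed = seed, t_grid = t_grid)
  simulate_dataset(des)
}

# normalize + replicate-average a dataset into fit-ready traces
normalized_traces <- function(ds, n_baseline = 10L) {
  by_sub <- split(ds$traces,
                  vapply(ds$traces, function(tc) tc$meta$substrate,
                         character(1)))
  lapply(by_sub, function(reps) {
    reps <- lapply(reps, relative_enhancement, n_baseline = n_baseline)
    if (length(reps) >= 2L) average_replicates(reps) else reps[[1]]
  })
}

# coarser grid to keep optimizer-heavy unit tests quick
grid_coarse <- function(n = 400L) default_time_grid(1e-2, 5000, n)

rel_err <- function(x, ref) abs(x / ref - 1)
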