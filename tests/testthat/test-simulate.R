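test_that("pre-translocated distance follows the linear ATPgS model", {
  des <- experiment_design(dt1 = c(0, 600), excluded_length = 48,
                           v_gammaS = 0.09, noise_sd = 0, n_replicates = 1L)
  expect_identical(pretranslocation_distance(des, 0), 48)
  expect_equal(pretranslocation_distance(des, 600), 102)
  # a delay long enough to consume the shortest substrate is a design error
  expect_error(
    experiment_design(dt1 = 2000, excluded_length = 48, v_gammaS = 0.09,
                      noise_sd = 0, n_replicates = 1L),
    "shortest substrate")
})

test_that("the noiseless path is the identity on the model signal", {
  sub <- substrate_spec("X", 265, labeling_efficiency = 1)
  des <- experiment_design(substrates = list(sub), dt1 = 0,
                           k_end = c(X = 0.05), excluded_length = 93,
                           v_gammaS = 0, extent_of_binding = 1, F0 = 0,
                           noise_sd = 0, n_replicates = 1L,
                           t_grid = grid_coarse())
  tc <- simulate_timecourse(sub, des)
  p <- scheme_params(des$k_U, 0.05, (265 - 93) / des$m,
                     F1 = des$F1, F2 = des$F2)
  expect_identical(tc$y, signal_model(p, des$t_grid)$y)
})

test_that("simulation is deterministic per (seed, replicate) with independent streams", {
  des <- experiment_design(dt1 = 600, noise_sd = 0.02, n_replicates = 2L,
                           seed = 123L, t_grid = grid_coarse())
  s1 <- des$substrates[[1]]
  a <- simulate_timecourse(s1, des, replicate_index = 1L)
  b <- simulate_timecourse(s1, des, replicate_index = 1L)
  expect_identical(a$y, b$y)
  c2 <- simulate_timecourse(s1, des, replicate_index = 2L)
  expect_false(identical(a$y, c2$y))
  # a noisy design without a seed is refused
  expect_error(experiment_design(dt1 = 600, noise_sd = 0.02, seed = NULL),
               "seed")
})

test_that("the best-labeled construct shows the largest peak amplitude", {
  des <- experiment_design(dt1 = 600, noise_sd = 0, n_replicates = 1L,
                           t_grid = grid_coarse())
  peaks <- vapply(des$substrates, function(s)
    max(simulate_timecourse(s, des)$y - des$F0), numeric(1))
  expect_identical(names(which.max(peaks)), "RepA-Titin_2")
})

test_that("dataset assembly counts traces and records the generating truth", {
  des <- experiment_design(dt1 = 600, noise_sd = 0, n_replicates = 3L,
                           t_grid = grid_coarse(100L))
  ds <- simulate_dataset(des)
  expect_length(ds$traces, 9L)
  expect_identical(ds$manifest$true_params$k_U, des$k_U)
  expect_identical(ds$manifest$true_params$m, des$m)
})

test_that("a written dataset reads back with identical arrays", {
  dir <- withr::local_tempdir()
  des <- experiment_design(dt1 = 300, noise_sd = 0.02, n_replicates = 2L,
                           seed = 5L, t_grid = grid_coarse(120L))
  ds <- simulate_dataset(des, dir = dir)
  back <- read_dataset(dir)
  expect_identical(names(back$traces), names(ds$traces))
  for (k in names(ds$traces)) {
    expect_identical(back$traces[[k]]$t, ds$traces[[k]]$t)
    expect_identical(back$traces[[k]]$y, ds$traces[[k]]$y)
    expect_identical(back$traces[[k]]$meta$L, ds$traces[[k]]$meta$L)
  }
  expect_equal(back$manifest$true_params$k_U, des$k_U)
})
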