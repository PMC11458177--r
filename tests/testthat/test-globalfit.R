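# Optimizer-facing tests run on a coarsened sampling grid; the full-scale
# recovery studies for the three nucleotide conditions live in
# test-acceptance.R.

test_that("noiseless closure on a coarse grid recovers the generating truth", {
  ds <- closure_dataset("atp_atpgs_1to1", C = 93, t_grid = grid_coarse())
  traces <- normalized_traces(ds)
  fit <- fit_global(traces, C = 93, n_starts = 10, seed = 101)
  expect_lt(rel_err(fit$m, 56.5), 0.005)
  expect_lt(rel_err(fit$k_U, 0.017), 0.005)
  expect_lt(max(rel_err(fit$k_end,
                        unlist(ds$manifest$true_params$k_end)[names(fit$k_end)])),
            0.02)
  # objective invariance: trace order is irrelevant
  fit_perm <- fit_global(traces[c(3, 1, 2)], C = 93, n_starts = 10, seed = 101)
  expect_equal(fit_perm$m, fit$m, tolerance = 1e-6)
  expect_equal(fit_perm$k_U, fit$k_U, tolerance = 1e-6)
  # a common amplitude rescaling moves only F1/F2
  scaled <- lapply(traces, function(tc) { tc$y <- tc$y * 4; tc })
  fit_sc <- fit_global(scaled, C = 93, n_starts = 10, seed = 101)
  expect_equal(fit_sc$m, fit$m, tolerance = 1e-5)
  expect_equal(fit_sc$k_U, fit$k_U, tolerance = 1e-5)
  expect_equal(unname(fit_sc$F1 / fit$F1), rep(4, 3), tolerance = 1e-4)
})

test_that("a single substrate length triggers the joint-identifiability flag", {
  ds <- closure_dataset("atp_atpgs_1to1", C = 93, t_grid = grid_coarse(200L))
  tr <- normalized_traces(ds)[2]
  expect_warning(fit <- fit_global(tr, C = 93, n_starts = 10, seed = 3),
                 "weakly identified")
  expect_true(fit$flags$weak_identifiability)
})

test_that("seed and start count are enforced", {
  ds <- closure_dataset("atp_atpgs_1to1", C = 93, t_grid = grid_coarse(150L))
  traces <- normalized_traces(ds)
  expect_error(fit_global(traces, C = 93, n_starts = 10), "seed")
  expect_error(fit_global(traces, C = 93, n_starts = 3, seed = 1), "n_starts")
  expect_error(fit_global(traces, C = 400, n_starts = 10, seed = 1), "reaches")
})

test_that("local-n mode agrees with the constrained mode on clean data", {
  ds <- closure_dataset("atp_atpgs_1to1", C = 93, t_grid = grid_coarse())
  traces <- normalized_traces(ds)
  loc <- fit_local_n(traces, n_starts = 10, seed = 21)
  # slope of n vs L estimates 1/m; x-intercept estimates C
  expect_lt(rel_err(1 / loc$n_vs_L$slope, 56.5), 0.02)
  expect_lt(abs(loc$n_vs_L$x_intercept - 93), 2)
  expect_lt(rel_err(loc$k_U, 0.017), 0.05)
  # two traces of equal length cannot support the n vs L line
  expect_error(fit_local_n(traces[c(1, 1)], n_starts = 10, seed = 21),
               "distinct substrate lengths")
})

test_that("bootstrap intervals collapse on noiseless data and reject n_boot = 0", {
  ds <- closure_dataset("atp_atpgs_1to1", C = 93, t_grid = grid_coarse(150L))
  traces <- normalized_traces(ds)
  fit <- fit_global(traces, C = 93, n_starts = 10, seed = 5)
  expect_error(bootstrap_uncertainty(fit, n_boot = 0, seed = 1), "positive")
  ci <- bootstrap_uncertainty(fit, n_boot = 12, seed = 7)
  widths <- ci$ci[, 2] - ci$ci[, 1]
  expect_lt(widths["m"] / fit$m, 1e-3)
  expect_lt(widths["k_U"] / fit$k_U, 1e-3)
})

test_that("replicate summaries use inverse-variance weights and report spread", {
  s <- replicate_summary(c(0.017, 0.017, 0.017))
  expect_equal(s$mean, 0.017)
  expect_equal(s$sd, 0)
  expect_equal(replicate_summary(c(0.016, 0.017, 0.018))$mean, 0.017)
  w <- replicate_summary(c(1, 3), sd = c(0.1, 1))
  manual <- (1 / 0.1^2 * 1 + 1 / 1^2 * 3) / (1 / 0.1^2 + 1 / 1^2)
  expect_equal(w$mean, manual)
  expect_lt(w$mean, 2)  # pulled toward the tight value
  expect_warning(replicate_summary(0.017), "single value")
})
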