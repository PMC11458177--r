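test_that("relative enhancement implements |F0av - Ft| / F0av", {
  t <- 0:99
  flat <- timecourse(t, rep(3.7, 100))
  expect_identical(relative_enhancement(flat)$y, rep(0, 100))
  y <- rep(5, 100); y[50] <- 6
  tc <- relative_enhancement(timecourse(t, y), n_baseline = 10)
  expect_equal(tc$y[50], 0.2)
  expect_identical(tc$meta$normalization, "relative")
  expect_error(relative_enhancement(tc), "already normalized")
  expect_error(relative_enhancement(timecourse(t, y - 5)), "not positive")
})

test_that("normalization of a noiseless synthetic trace recovers the scaled model", {
  sub <- substrate_spec("X", 265, 1)
  des <- experiment_design(substrates = list(sub), dt1 = 0,
                           k_end = c(X = 0.05), excluded_length = 93,
                           v_gammaS = 0, F0 = 5, noise_sd = 0,
                           n_replicates = 1L, t_grid = grid_coarse())
  raw <- simulate_timecourse(sub, des)
  rel <- relative_enhancement(raw)
  model <- signal_model(scheme_params(des$k_U, 0.05, (265 - 93) / des$m,
                                    des$F1, des$F2), des$t_grid)$y
  expect_lt(max(abs(rel$y - model / 5)), 1e-12)
})

test_that("relative enhancement is invariant to the raw intensity scale", {
  sub <- substrate_spec("X", 265, 1)
  des <- experiment_design(substrates = list(sub), dt1 = 0,
                           k_end = c(X = 0.05), excluded_length = 93,
                           v_gammaS = 0, noise_sd = 0, n_replicates = 1L,
                           t_grid = grid_coarse(150L))
  raw <- simulate_timecourse(sub, des)
  scaled <- raw
  scaled$y <- raw$y * 7.3
  expect_equal(relative_enhancement(raw)$y, relative_enhancement(scaled)$y,
               tolerance = 1e-12)
})

test_that("replicate averaging returns pointwise mean and sample sd", {
  t <- 0:9
  a <- timecourse(t, rep(1, 10))
  avg <- average_replicates(list(a, a))
  expect_identical(avg$y, a$y)
  expect_identical(avg$sd, rep(0, 10))
  b <- timecourse(t, rep(0, 10)); c2 <- timecourse(t, rep(2, 10))
  avg2 <- average_replicates(list(b, c2))
  expect_identical(avg2$y, rep(1, 10))
  expect_equal(avg2$sd, rep(sqrt(2), 10))
  mis <- timecourse(t + 0.5, rep(1, 10))
  expect_error(average_replicates(list(a, mis)), "interpolate")
})

test_that("averaging and normalizing commute on identical clean baselines", {
  sub <- substrate_spec("X", 265, 1)
  des <- experiment_design(substrates = list(sub), dt1 = 0,
                           k_end = c(X = 0.05), excluded_length = 93,
                           v_gammaS = 0, noise_sd = 0, n_replicates = 1L,
                           t_grid = grid_coarse(150L))
  raw <- simulate_timecourse(sub, des)
  path1 <- relative_enhancement(average_replicates(list(raw, raw)))
  path2 <- average_replicates(lapply(list(raw, raw), relative_enhancement))
  expect_equal(path1$y, path2$y, tolerance = 1e-14)
})

test_that("replicate mean tracks the truth at simulation noise levels", {
  des <- experiment_design(dt1 = 600, noise_sd = 0.02, n_replicates = 5L,
                           seed = 99L, t_grid = grid_coarse())
  s3 <- des$substrates[["RepA-Titin_3"]]
  reps <- lapply(1:5, function(r) simulate_timecourse(s3, des, r))
  avg <- average_replicates(reps)
  des0 <- des; des0$noise_sd <- 0
  truth <- simulate_timecourse(s3, des0)$y
  # sd is estimated from 4 df, so use the matching t quantile
  thr <- stats::qt(0.995, df = 4)
  ok <- abs(avg$y - truth) <= thr * pmax(avg$sd, 1e-12) / sqrt(5) |
    abs(avg$y - truth) < 1e-9
  expect_gte(mean(ok), 0.97)
})

test_that("local-polynomial smoothing reproduces polynomials, even at endpoints", {
  t <- default_time_grid(1e-2, 5000, 300)     # log-spaced, deliberately
  line <- timecourse(t, 2.5 + 0.3 * t)
  expect_lt(max(abs(smooth_timecourse(line, 11, 3)$y - line$y) /
                  pmax(abs(line$y), 1)), 1e-10)
  cubic <- timecourse(t, 1 + t - 1e-3 * t^2 + 1e-7 * t^3)
  expect_lt(max(abs(smooth_timecourse(cubic, 21, 3)$y - cubic$y) /
                  pmax(abs(cubic$y), 1)), 1e-9)
  expect_identical(smooth_timecourse(line, 1)$y, line$y)
  expect_error(smooth_timecourse(line, 10), "odd")
  expect_error(smooth_timecourse(line, 3, 5), "odd|poly")
})

test_that("smoothing keeps the detected peak near the noiseless truth", {
  sub <- substrate_spec("X", 362, 1)
  des <- experiment_design(substrates = list(sub), dt1 = 0,
                           k_end = c(X = 0.017), excluded_length = 93,
                           v_gammaS = 0, noise_sd = 0.02, n_replicates = 1L,
                           seed = 17L)
  noisy <- relative_enhancement(simulate_timecourse(sub, des))
  des0 <- des; des0$noise_sd <- 0
  clean <- relative_enhancement(simulate_timecourse(sub, des0))
  pk_noisy <- detect_peak(noisy, window = 51, poly_order = 3)
  pk_clean <- detect_peak(clean, window = 51, poly_order = 3)
  spacing <- diff(des$t_grid)[pk_clean$index]
  expect_lt(abs(pk_noisy$peak_time - pk_clean$peak_time), 5 * spacing)
})
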