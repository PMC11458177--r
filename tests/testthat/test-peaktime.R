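test_that("empirical peak detection matches the analytic peak location", {
  p <- scheme_params(0.017, 0.017, 4.5, F1 = 1, F2 = 0.05)
  grid <- default_time_grid()
  tc <- signal_model(p, grid)
  pk <- detect_peak(tc)
  ana <- peak_time_of_signal(p)
  spacing <- grid[pk$index + 1L] - grid[pk$index]
  expect_true(pk$has_peak)
  expect_lt(abs(pk$peak_time - ana$peak_time), 2 * spacing)
})

test_that("monotone traces are flagged instead of yielding a boundary peak", {
  t <- seq(0, 100, length.out = 500)
  rising <- timecourse(t, 1 - exp(-0.05 * t), normalization = "relative")
  expect_false(detect_peak(rising)$has_peak)
})

test_that("exact ties resolve to the earliest peak", {
  t <- seq_len(401)
  y <- rep(0, 401)
  y[96:104] <- c(1:4, 5, 4:1) / 5           # symmetric peak centred at t = 100
  y[196:204] <- c(1:4, 5, 4:1) / 5          # identical twin at t = 200
  tc <- timecourse(t, y, normalization = "relative")
  pk <- detect_peak(tc, window = 3, poly_order = 1)
  expect_equal(pk$peak_time, 100)
})

test_that("length vs peak time recovers an exact generating line", {
  L <- c(168, 265, 362)
  tp <- (L - 71) / 0.098
  fit <- fit_length_vs_peaktime(tp, L)
  expect_equal(fit$slope, 0.098, tolerance = 1e-12)
  expect_equal(fit$intercept, 71, tolerance = 1e-10)
  fit2 <- fit_length_vs_peaktime(c(0, 100), c(50, 150))
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, 50)
  expect_error(fit_length_vs_peaktime(100, 168), ">= 2 points")
  expect_error(fit_length_vs_peaktime(c(10, 10), c(168, 265)), "degenerate")
})

test_that("halving a point's sd is equivalent to replicating it fourfold", {
  tp <- c(100, 200, 300)
  L <- c(150, 260, 350)
  sd <- c(4, 4, 4)
  dup <- fit_length_vs_peaktime(c(tp, rep(tp[2], 3)), c(L, rep(L[2], 3)),
                                sd = c(sd, rep(4, 3)))
  half <- fit_length_vs_peaktime(tp, L, sd = c(4, 2, 4))
  expect_equal(dup$slope, half$slope, tolerance = 1e-12)
  expect_equal(dup$intercept, half$intercept, tolerance = 1e-12)
})

test_that("pre-translocation vs delay-time line recovers the generating model", {
  fit <- fit_pretranslocation_vs_dt1(c(300, 420, 600), c(75, 85.8, 102))
  expect_equal(fit$slope, 0.09, tolerance = 1e-12)
  expect_equal(fit$intercept, 48, tolerance = 1e-10)
  expect_error(fit_pretranslocation_vs_dt1(600, 97), ">= 2 points")
  flat <- fit_pretranslocation_vs_dt1(c(300, 420, 600), c(80, 80, 80))
  expect_equal(flat$slope, 0)
})

test_that("peak-time pipeline on noiseless multi-delay data is internally consistent", {
  ds <- kinematic_dataset()
  pk <- run_peaktime_pipeline(ds)
  slopes <- pk$per_dt1$slope_aa_per_s
  # the per-delay kinematic rate does not depend on the delay time
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-3)
  # the per-delay rate is invariant to a common amplitude rescaling
  ds_scaled <- ds
  ds_scaled$traces <- lapply(ds$traces, function(tc) { tc$y <- tc$y * 3; tc })
  pk_scaled <- run_peaktime_pipeline(ds_scaled)
  expect_equal(pk_scaled$per_dt1$slope_aa_per_s, slopes, tolerance = 1e-6)
  # intercept bias relative to the generating C is the same at every delay
  C_true <- 48 + 0.09 * pk$per_dt1$dt1_s
  bias <- pk$per_dt1$intercept_aa - C_true
  expect_lt(diff(range(bias)), 0.5)
  # the delay-time line returns the generating pre-translocation rate
  expect_lt(abs(pk$dt1_fit$slope / 0.09 - 1), 0.01)
})
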