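test_that("parameter and geometry validation rejects bad inputs", {
  expect_error(scheme_params(-0.1, 0.1, 3), "k_U")
  expect_error(scheme_params(0.1, 0, 3), "k_end")
  expect_error(scheme_params(0.1, 0.1, -1), "n")
  expect_error(translocation_geometry(168, 200, 56.5), "pre-translocated")
  expect_error(last_intermediate_fraction(scheme_params(0.1, 0.1, 2),
                                          c(1, 1, 2)),
               "strictly increasing")
})

test_that("no flux has completed the chain at t = 0 and n = 0 degenerates to one step", {
  p <- scheme_params(0.02, 0.05, 3.4)
  expect_identical(last_intermediate_fraction(p, 0), 0)
  expect_identical(product_fraction(p, 0), 0)
  expect_identical(signal_model(p, 0)$y, 0)
  # with zero unfolding steps the initially bound species decays exponentially
  t <- c(0, 1, 10, 100, 400)
  p0 <- scheme_params(0.02, 0.05, 0)
  expect_equal(last_intermediate_fraction(p0, t), exp(-0.05 * t))
  expect_equal(product_fraction(p0, t), 1 - exp(-0.05 * t))
})

test_that("closed-form fractions match the linear-chain ODE at a transit-scale time", {
  p <- scheme_params(0.017, 0.1, 3)
  t <- c(50, 200, 800)
  o <- ode_oracle(p, t)
  li <- last_intermediate_fraction(p, t)
  pr <- product_fraction(p, t)
  expect_lt(max(abs(li - o$last_intermediate) / o$last_intermediate), 1e-8)
  expect_lt(max(abs(pr - o$product) / o$product), 1e-8)
})

test_that("product fraction saturates at one well past the chain transit", {
  p <- scheme_params(0.017, 0.1, 3)
  # past the far tail of the arrival distribution plus many dissociation lives
  t_late <- stats::qgamma(1e-9, 3, 0.017, lower.tail = FALSE) + 50 / 0.1
  expect_lt(abs(product_fraction(p, t_late) - 1), 1e-6)
})

test_that("equal amplitudes give a monotone rise to the common plateau", {
  p <- scheme_params(0.017, 0.05, 3, F1 = 0.8, F2 = 0.8)
  tc <- signal_model(p, default_time_grid(1e-2, 20000, 500))
  expect_true(all(diff(tc$y) > -1e-12))
  expect_lt(abs(tc$y[length(tc$y)] - 0.8), 1e-4)
  expect_false(peak_time_of_signal(p)$has_peak)
})

test_that("signal with F1 > F2 has a single interior maximum located accurately", {
  n <- (362 - 93) / 56.5
  p <- scheme_params(0.017, 0.01, n, F1 = 1, F2 = 0.3)
  dense <- seq(1, 4000, length.out = 2e5)
  y <- signal_model(p, dense)$y
  # count slope reversals above numerical jitter
  dy <- diff(y)
  s <- sign(dy[abs(dy) > 1e-9 * max(y)])
  sign_changes <- sum(diff(s) != 0)
  expect_identical(sign_changes, 1L)
  pk <- peak_time_of_signal(p)
  expect_true(pk$has_peak)
  i <- which.max(y)
  expect_lt(abs(pk$peak_time - dense[i]), 0.5)
  expect_lt(abs(pk$peak_height - y[i]) / y[i], 1e-6)
})

test_that("analytic peak time agrees with brute-force grid and grows with n", {
  p <- scheme_params(0.0042, 0.02, 2, F1 = 1, F2 = 0.2)
  dense <- seq(1, 3e4, length.out = 1e5)
  y <- signal_model(p, dense)$y
  i <- which.max(y)
  pk <- peak_time_of_signal(p)
  # the top is flat to ~1e-13 over tens of seconds, so compare by height and
  # require the locations to agree to a few grid steps
  expect_lt(abs(pk$peak_time - dense[i]), 1)
  expect_gte(pk$peak_height, max(y) - 1e-11)
  pts <- vapply(1:10, function(n)
    peak_time_of_signal(scheme_params(0.017, 0.05, n, 1, 0.2))$peak_time,
    numeric(1))
  expect_true(all(diff(pts) > 0))
  # inverted amplitudes: no peak is reported, not a silent number
  expect_false(peak_time_of_signal(scheme_params(0.017, 0.05, 3,
                                                 F1 = 0.2, F2 = 1))$has_peak)
})

test_that("steps_from_length implements the reduced-length relation", {
  expect_equal(steps_from_length(362, C = 93, m = 56.5), 269 / 56.5)
  expect_equal(steps_from_length(168, C = 168, m = 56.5), 0)
  expect_error(steps_from_length(168, C = 200, m = 56.5), "pre-translocated")
})

test_that("ode oracle reproduces the textbook two-step solution and conserves mass", {
  k1 <- 0.03; k2 <- 0.011
  t <- c(5, 50, 200, 1000)
  o <- ode_oracle(scheme_params(k1, k2, 1), t)
  b_exact <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  expect_lt(max(abs(o$last_intermediate - b_exact)), 1e-10)
  o5 <- ode_oracle(scheme_params(0.055, 0.1, 5), default_time_grid(1, 2000, 50),
                   full = TRUE)
  totals <- rowSums(attr(o5, "states"))
  expect_lt(max(abs(totals - 1)), 1e-10)
  expect_error(ode_oracle(scheme_params(0.1, 0.1, 2.5), 1:3), "integer")
})
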