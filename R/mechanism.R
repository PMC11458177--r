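#' Parameters of the n-step sequential unfolding mechanism
#'
#' One pre-bound motor-substrate complex steps through `n` sequential
#' unfolding events, each with rate constant `k_U`, to reach the last
#' intermediate (motor at the fluorophore), then dissociates from the
#' C-terminal end with rate constant `k_end`. Only the last intermediate and
#' the released unfolded product are fluorescent, with amplitudes `F1` and
#' `F2`; all earlier intermediates are dark. `n` may be non-integer because
#' it derives from a substrate length divided by the kinetic step-size.
#'
#' @param k_U unfolding rate constant (1/s), > 0.
#' @param k_end terminal dissociation rate constant (1/s), > 0.
#' @param n number of sequential unfolding steps (real, >= 0).
#' @param F1 fluorescence amplitude of the last intermediate (>= 0).
#' @param F2 fluorescence amplitude of the unfolded, dissociated product
#'   (>= 0). The trace has an interior peak only when `F1 > F2`.
#' @return an object of class `scheme_params`.
#' @export
scheme_params <- function(k_U, k_end, n, F1 = 1, F2 = 0) {
  check_scalar(k_U, "k_U", lower = 0, strict_lower = TRUE)
  check_scalar(k_end, "k_end", lower = 0, strict_lower = TRUE)
  check_scalar(n, "n", lower = 0)
  check_scalar(F1, "F1", lower = 0)
  check_scalar(F2, "F2", lower = 0)
  structure(list(k_U = k_U, k_end = k_end, n = n, F1 = F1, F2 = F2),
            class = "scheme_params")
}

#' @export
print.scheme_params <- function(x, ...) {
  cat(sprintf(
    "<scheme_params> k_U = %g /s, k_end = %g /s, n = %g steps, F1 = %g, F2 = %g\n",
    x$k_U, x$k_end, x$n, x$F1, x$F2))
  invisible(x)
}

#' Substrate geometry for the length-to-steps conversion
#'
#' @param L total substrate length (aa), > 0.
#' @param C amino acids unavailable for stepping at the moment of mixing:
#'   pre-translocated distance plus excluded length (aa), in `[0, L]`.
#' @param m kinetic step-size: average amino acids unfolded between two
#'   rate-limiting steps (aa), > 0.
#' @return an object of class `translocation_geometry`.
#' @export
translocation_geometry <- function(L, C, m) {
  check_scalar(L, "L", lower = 0, strict_lower = TRUE)
  check_scalar(m, "m", lower = 0, strict_lower = TRUE)
  check_scalar(C, "C", lower = 0)
  if (C > L)
    stop_usage(paste0("pre-translocated + excluded length C (%g aa) exceeds ",
                      "substrate length L (%g aa): substrate fully ",
                      "pre-translocated"), C, L)
  structure(list(L = L, C = C, m = m), class = "translocation_geometry")
}

#' Number of kinetic steps from substrate geometry
#'
#' The reduced length `L - C` (amino acids still to be unfolded after the
#' pre-incubation) divided by the kinetic step-size: `n = (L - C) / m`.
#' Generically non-integer; the signal model accepts real `n`.
#'
#' @param geom a [translocation_geometry], or a length `L` when `C` and `m`
#'   are given separately.
#' @param C,m optional; used when `geom` is a bare length.
#' @return number of steps (real, >= 0).
#' @export
steps_from_length <- function(geom, C = NULL, m = NULL) {
  if (!inherits(geom, "translocation_geometry"))
    geom <- translocation_geometry(L = geom, C = C, m = m)
  (geom$L - geom$C) / geom$m
}

# last-intermediate occupancy ---------------------------------------------
#
# I(t) = inverse Laplace of k_U^n / ((s + k_U)^n (s + k_end)), i.e. the
# convolution of the gamma(n, k_U) arrival density with the exponential
# survival of the terminal state. Evaluated piecewise:
#   k_U >  k_end : regularized lower incomplete gamma closed form (log space)
#   k_U <= k_end : positive-term Kummer series M(n, n+1, x), x = (k_end-k_U)t,
#                  for x <= 500; boundary-layer Gauss-Legendre quadrature of
#                  the exact integral for larger x (contribution confined to
#                  u = t - tau within ~45/(k_end - k_U) of the arrival time).
# All branches are cancellation-free; k_U = k_end is exact (x = 0).

li_closed <- function(t, k_U, k_end, n) {
  if (n == 0) return(exp(-k_end * t))
  out <- numeric(length(t))
  pos <- t > 0
  if (!any(pos)) return(out)
  tt <- t[pos]
  a <- k_U - k_end
  if (a > 0) {
    lg <- n * (log(k_U) - log(a)) +
      stats::pgamma(tt, shape = n, rate = a, log.p = TRUE) - k_end * tt
    out[pos] <- exp(lg)
    return(out)
  }
  b <- -a                                  # k_end - k_U >= 0
  x <- b * tt
  v <- numeric(length(tt))
  ser <- x <= 500
  if (any(ser)) {
    xs <- x[ser]
    term <- rep(1, length(xs))
    s <- rep(1, length(xs))
    j <- 1
    repeat {
      term <- term * xs / j * (n + j - 1) / (n + j)
      s <- s + term
      if (max(term / s) < 1e-17 || j > 5000L) break
      j <- j + 1
    }
    v[ser] <- exp(n * log(k_U) + n * log(tt[ser]) - lgamma(n + 1) -
                    k_end * tt[ser]) * s
  }
  if (any(!ser)) {
    tq <- tt[!ser]
    gl <- gauss_legendre_01(80L)
    ustar <- 45 / b
    u <- gl$x * ustar
    w <- gl$w * ustar
    J <- vapply(tq, function(ti) sum(w * exp((n - 1) * log(ti - u) - b * u)),
                numeric(1))
    v[!ser] <- exp(n * log(k_U) - k_U * tq - lgamma(n)) * J
  }
  out[pos] <- v
  out
}

li_quadrature <- function(t, k_U, k_end, n) {
  if (n == 0) return(exp(-k_end * t))
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    lo <- stats::qgamma(1e-16, shape = n, rate = k_U)
    hi <- min(ti, stats::qgamma(1e-16, shape = n, rate = k_U, lower.tail = FALSE))
    if (lo >= hi) return(0)
    val <- tryCatch(
      stats::integrate(function(tau)
        stats::dgamma(tau, shape = n, rate = k_U) * exp(-k_end * (ti - tau)),
        lo, hi, rel.tol = 1e-12, abs.tol = 1e-280, subdivisions = 1000L)$value,
      error = function(e) NA_real_)
    if (is.na(val)) {
      # retry split at the gamma mode for hard peak/interval combinations
      mid <- min(max(lo * 1.0000001, (n - 1) / k_U), hi * 0.9999999)
      f <- function(tau)
        stats::dgamma(tau, shape = n, rate = k_U) * exp(-k_end * (ti - tau))
      val <- stats::integrate(f, lo, mid, rel.tol = 1e-11, abs.tol = 1e-280,
                              subdivisions = 1000L)$value +
        stats::integrate(f, mid, hi, rel.tol = 1e-11, abs.tol = 1e-280,
                         subdivisions = 1000L)$value
    }
    val
  }, numeric(1))
}

resolve_backend <- function(backend) {
  backend <- match.arg(backend, c("auto", "closed", "quadrature"))
  if (backend == "auto") "closed" else backend
}

#' Fraction of complexes in the last intermediate
#'
#' Occupancy of the state in which the motor has completed all `n` unfolding
#' steps and sits at the C-terminal fluorophore but has not yet dissociated.
#' This is the inverse Laplace transform of
#' `k_U^n / ((s + k_U)^n (s + k_end))` evaluated on `t`.
#'
#' @param params a [scheme_params].
#' @param t time grid (s), nonnegative, strictly increasing.
#' @param backend `"closed"` (piecewise analytic, default) or `"quadrature"`
#'   (independent adaptive numerical integration of the arrival convolution;
#'   slower, used for cross-checks).
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
last_intermediate_fraction <- function(params, t, backend = "auto") {
  stopifnot(inherits(params, "scheme_params"))
  check_time_grid(t)
  backend <- resolve_backend(backend)
  f <- switch(backend, closed = li_closed, quadrature = li_quadrature)
  f(t, params$k_U, params$k_end, params$n)
}

#' Cumulative fraction dissociated as unfolded product
#'
#' The probability that the full chain (all `n` unfolding steps plus the
#' terminal dissociation) has completed by time `t`. Equal to the gamma-chain
#' completion probability minus the last-intermediate occupancy; nondecreasing
#' with limit 1.
#'
#' @inheritParams last_intermediate_fraction
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
product_fraction <- function(params, t, backend = "auto") {
  stopifnot(inherits(params, "scheme_params"))
  check_time_grid(t)
  li <- last_intermediate_fraction(params, t, backend)
  arrived <- if (params$n == 0) rep(1, length(t))
             else stats::pgamma(t, shape = params$n, rate = params$k_U)
  pmin(pmax(arrived - li, 0), 1)
}

#' Model fluorescence signal of the sequential mechanism
#'
#' `F(t) = F1 * last_intermediate_fraction + F2 * product_fraction`. With
#' `F1 > F2` the trace shows the experimental shape: a lag while the motor is
#' unfolding, a rise as it reaches the fluorophore, and a decay toward `F2`
#' as it dissociates.
#'
#' @inheritParams last_intermediate_fraction
#' @return a [timecourse] with normalization `"relative"`.
#' @export
signal_model <- function(params, t = default_time_grid(), backend = "auto") {
  stopifnot(inherits(params, "scheme_params"))
  li <- last_intermediate_fraction(params, t, backend)
  pr <- product_fraction(params, t, backend)
  timecourse(t, params$F1 * li + params$F2 * pr, normalization = "relative")
}

#' Analytic peak time of the model signal
#'
#' Locates the interior maximum of [signal_model()] by bracketed golden-section
#' refinement from a coarse log-spaced grid. A peak exists only when
#' `F1 > F2` and `n > 0`; otherwise the result is flagged.
#'
#' @param params a [scheme_params].
#' @param t_max optional upper end of the search window (s); by default wide
#'   enough to contain the chain transit plus several dissociation lifetimes.
#' @return list with `has_peak` (logical), `peak_time` (s, `NA` if flagged),
#'   and `peak_height`.
#' @export
peak_time_of_signal <- function(params, t_max = NULL) {
  stopifnot(inherits(params, "scheme_params"))
  if (params$F1 <= params$F2 || params$n == 0)
    return(list(has_peak = FALSE, peak_time = NA_real_, peak_height = NA_real_))
  if (is.null(t_max))
    t_max <- stats::qgamma(1e-9, shape = params$n, rate = params$k_U,
                           lower.tail = FALSE) + 20 / params$k_end
  grid <- exp(seq(log(t_max * 1e-6), log(t_max), length.out = 600L))
  y <- signal_model(params, grid)$y
  i <- which.max(y)
  if (i == 1L || i == length(grid))
    return(list(has_peak = FALSE, peak_time = NA_real_, peak_height = NA_real_))
  f <- function(tt) -signal_model(params, tt)$y
  opt <- stats::optimize(f, lower = grid[i - 1L], upper = grid[i + 1L],
                         tol = max(1e-6, 1e-6 * grid[i]))
  list(has_peak = TRUE, peak_time = opt$minimum, peak_height = -opt$objective)
}
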