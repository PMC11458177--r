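#' Relative fluorescence enhancement
#'
#' Converts a raw trace to relative enhancement
#' `|F0_av - F(t)| / F0_av`, where `F0_av` is the mean of the first
#' `n_baseline` points (collected during the lag, before any signal change).
#' The ratio removes the instrument's arbitrary intensity scale so traces
#' from different substrates and sessions are comparable.
#'
#' @param raw a raw [timecourse].
#' @param n_baseline number of initial points averaged for the baseline
#'   (>= 2, default 10).
#' @return a [timecourse] flagged `"relative"`.
#' @export
relative_enhancement <- function(raw, n_baseline = 10L) {
  stopifnot(is_timecourse(raw))
  if (raw$meta$normalization != "raw")
    stop_usage("input is already normalized; relative_enhancement needs a raw trace")
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 2L || n_baseline >= length(raw$t))
    stop_usage("n_baseline must be >= 2 and smaller than the trace length")
  F0 <- mean(raw$y[seq_len(n_baseline)])
  if (F0 <= 0)
    stop_usage("baseline average F0_av = %g is not positive; cannot normalize", F0)
  out <- raw
  out$y <- abs(F0 - raw$y) / F0
  out$sd <- if (!is.null(raw$sd)) raw$sd / F0 else NULL
  out$meta$normalization <- "relative"
  out
}

#' Pointwise average of replicate traces
#'
#' Replicates must share the time grid and normalization state exactly; no
#' silent interpolation is performed. Returns the pointwise mean with the
#' sample standard deviation attached.
#'
#' @param traces list of >= 2 [timecourse] objects on a common grid.
#' @return a [timecourse] carrying per-point `sd` and `n_averaged`.
#' @export
average_replicates <- function(traces) {
  if (!is.list(traces) || length(traces) < 2L ||
      !all(vapply(traces, is_timecourse, logical(1))))
    stop_usage("average_replicates needs a list of >= 2 timecourse objects")
  t0 <- traces[[1]]$t
  norm <- traces[[1]]$meta$normalization
  for (tc in traces[-1]) {
    if (length(tc$t) != length(t0) || any(tc$t != t0))
      stop_usage("replicate grids differ; refusing to interpolate")
    if (tc$meta$normalization != norm)
      stop_usage("replicates mix raw and relative traces")
  }
  Y <- vapply(traces, `[[`, numeric(length(t0)), "y")
  out <- traces[[1]]
  out$y <- rowMeans(Y)
  out$sd <- apply(Y, 1, stats::sd)
  out$meta$replicate <- NA_integer_
  out$meta$n_averaged <- length(traces)
  out
}

#' Local-polynomial (Savitzky-Golay-type) smoothing
#'
#' For every sample, fits a polynomial of degree `poly_order` in time to the
#' surrounding `window` points by least squares and evaluates it at that
#' sample. Fitting in actual time (not sample index) makes the smoother
#' polynomial-reproducing on the log-spaced grids this assay uses; endpoints
#' are handled by shrinking the window to the available points, so the
#' operation is idempotent on polynomials of degree <= `poly_order`
#' everywhere, including the ends. `window = 1` is the identity.
#'
#' @param trace a [timecourse].
#' @param window odd window width in points; must exceed `poly_order` and be
#'   at most a third of the trace length.
#' @param poly_order polynomial degree (default 3).
#' @return the smoothed [timecourse].
#' @export
smooth_timecourse <- function(trace, window = 11L, poly_order = 3L) {
  stopifnot(is_timecourse(trace))
  window <- as.integer(window)
  poly_order <- as.integer(poly_order)
  if (window == 1L) return(trace)
  N <- length(trace$t)
  if (window %% 2L == 0L || window <= poly_order || window > N %/% 3L)
    stop_usage("window must be odd, > poly_order and <= length/3 (got %d)",
               window)
  half <- window %/% 2L
  t <- trace$t
  y <- trace$y
  ys <- numeric(N)
  for (i in seq_len(N)) {
    lo <- max(1L, i - half)
    hi <- min(N, i + half)
    idx <- lo:hi
    p <- min(poly_order, length(idx) - 1L)
    # center/scale local times for conditioning
    tl <- t[idx] - t[i]
    sc <- max(abs(tl), 1)
    X <- outer(tl / sc, 0:p, `^`)
    fit <- stats::.lm.fit(X, y[idx])
    ys[i] <- fit$coefficients[1]
  }
  out <- trace
  out$y <- ys
  out
}
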