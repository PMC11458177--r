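# Model-independent analysis: the peak of a trace marks the motor's arrival
# at the C-terminal fluorophore, so substrate length vs peak time is a
# position-vs-time plot whose slope is the overall unfolding/translocation
# rate (aa/s) and whose intercept is the pre-translocated distance C (aa).

#' Detect the fluorescence peak of a trace
#'
#' Smooths the trace, takes the global maximum over the interior (the first
#' and last 1% of points are excluded), breaks ties toward the earliest time,
#' and optionally refines the peak time by a local quadratic through the
#' smoothed neighbors (sub-sample interpolation; never moves the estimate by
#' more than one grid interval). The peak height is read from the unsmoothed
#' trace at the detected index. A maximum on the boundary of the interior
#' window is flagged rather than reported.
#'
#' @param trace a normalized [timecourse].
#' @param window,poly_order smoothing parameters (see [smooth_timecourse()]).
#' @param edge_frac fraction of points excluded at each end (default 0.01).
#' @param refine logical; quadratic sub-sample refinement (default `TRUE`).
#' @return list with `has_peak`, `peak_time` (s), `peak_height`, `index`.
#' @export
detect_peak <- function(trace, window = 11L, poly_order = 3L,
                        edge_frac = 0.01, refine = TRUE) {
  stopifnot(is_timecourse(trace))
  sm <- smooth_timecourse(trace, window = window, poly_order = poly_order)
  N <- length(sm$t)
  n_edge <- max(1L, floor(edge_frac * N))
  interior <- (n_edge + 1L):(N - n_edge)
  i <- interior[which.max(sm$y[interior])]
  if (i == interior[1L] || i == interior[length(interior)])
    return(list(has_peak = FALSE, peak_time = NA_real_,
                peak_height = NA_real_, index = NA_integer_))
  pt <- sm$t[i]
  if (refine) {
    t3 <- sm$t[(i - 1L):(i + 1L)]
    y3 <- sm$y[(i - 1L):(i + 1L)]
    # exact parabola through three (possibly unevenly spaced) points
    d1 <- (y3[2] - y3[1]) / (t3[2] - t3[1])
    d2 <- (y3[3] - y3[2]) / (t3[3] - t3[2])
    curv <- (d2 - d1) / (t3[3] - t3[1])
    if (is.finite(curv) && curv < 0) {
      # Newton form: f'(t*) = 0 at t* = (t1 + t2)/2 - d1 / (2 curv)
      vertex <- (t3[1] + t3[2]) / 2 - d1 / (2 * curv)
      pt <- min(max(vertex, t3[1]), t3[3])
    }
  }
  list(has_peak = TRUE, peak_time = pt, peak_height = trace$y[i], index = i)
}

wls_line <- function(x, y, sd = NULL, xname, yname) {
  if (length(x) < 2L)
    stop_usage("need >= 2 points for a %s vs %s line", yname, xname)
  if (stats::var(x) == 0)
    stop_usage("all %s values identical; line fit is degenerate", xname)
  use_w <- !is.null(sd) && all(is.finite(sd)) && all(sd > 0)
  fit <- if (use_w) stats::lm(y ~ x, weights = 1 / sd^2) else stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       slope_sd = unname(cf["x", "Std. Error"]),
       intercept_sd = unname(cf["(Intercept)", "Std. Error"]),
       weighted = use_w,
       points = data.frame(x = x, y = y, sd = if (is.null(sd)) NA_real_ else sd))
}

#' Length vs peak time line (kinematic fit)
#'
#' Weighted least squares of substrate length (response, aa) on peak time
#' (regressor, s), weights `1 / sd^2`; unweighted when uncertainties are
#' absent. The slope is the overall rate in aa/s and the intercept the
#' pre-translocated distance C in aa.
#'
#' @param peak_time peak times (s).
#' @param L substrate lengths (aa).
#' @param sd optional peak-time scatter used as weights.
#' @return object of class `peaktime_fit` with `slope`, `intercept`, their
#'   standard errors, and the points.
#' @export
fit_length_vs_peaktime <- function(peak_time, L, sd = NULL) {
  out <- wls_line(peak_time, L, sd, xname = "peak time", yname = "length")
  names(out$points) <- c("peak_time_s", "L_aa", "sd_s")
  class(out) <- "peaktime_fit"
  out
}

#' @export
print.peaktime_fit <- function(x, ...) {
  cat(sprintf("<peaktime_fit> rate = %.4g +/- %.2g aa/s; C = %.4g +/- %.2g aa (%s)\n",
              x$slope, x$slope_sd, x$intercept, x$intercept_sd,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Pre-translocated distance vs delay time line
#'
#' Same contract as [fit_length_vs_peaktime()] with the delay time `dt1` as
#' regressor: the slope estimates the ATPgS-driven pre-translocation rate
#' (aa/s) and the intercept the excluded length (aa) at `dt1 = 0`.
#'
#' @param dt1 delay times (s).
#' @param C pre-translocated distances (aa), typically per-`dt1` intercepts.
#' @param sd optional uncertainties on `C` used as weights.
#' @return object of class `dt1_fit`.
#' @export
fit_pretranslocation_vs_dt1 <- function(dt1, C, sd = NULL) {
  out <- wls_line(dt1, C, sd, xname = "dt1", yname = "pre-translocated distance")
  names(out$points) <- c("dt1_s", "C_aa", "sd_aa")
  class(out) <- "dt1_fit"
  out
}

#' @export
print.dt1_fit <- function(x, ...) {
  cat(sprintf("<dt1_fit> v_gammaS = %.4g +/- %.2g aa/s; excluded length = %.4g +/- %.2g aa\n",
              x$slope, x$slope_sd, x$intercept, x$intercept_sd))
  invisible(x)
}

#' Full model-independent peak-time pipeline
#'
#' For every (dt1, substrate): normalizes raw replicates, detects the peak of
#' each replicate, and summarizes peak time as mean +/- sd across replicates.
#' Per dt1, fits the length-vs-peak-time line (replicate peak-time scatter as
#' weights); when two or more delay times are present, fits the per-dt1
#' intercepts against dt1 to estimate the ATPgS pre-translocation rate and
#' excluded length.
#'
#' @param dataset an `st_dataset` (raw or already-normalized traces).
#' @param n_baseline baseline points for [relative_enhancement()].
#' @param window,poly_order,edge_frac,refine peak-detection settings.
#' @param verbose log the per-dt1 intercepts (the C values handed to the
#'   model-dependent stage).
#' @return list with `peaks` (tidy per-replicate table), `per_dt1`
#'   (dt1_s, slope_aa_per_s, slope_sd, intercept_aa, intercept_sd), `fits`
#'   (the per-dt1 `peaktime_fit` objects) and `dt1_fit` (or `NULL`).
#' @export
run_peaktime_pipeline <- function(dataset, n_baseline = 10L, window = 11L,
                                  poly_order = 3L, edge_frac = 0.01,
                                  refine = TRUE, verbose = FALSE) {
  stopifnot(inherits(dataset, "st_dataset"))
  peaks <- do.call(rbind, lapply(dataset$traces, function(tc) {
    rel <- if (tc$meta$normalization == "raw")
      relative_enhancement(tc, n_baseline) else tc
    pk <- detect_peak(rel, window = window, poly_order = poly_order,
                      edge_frac = edge_frac, refine = refine)
    data.frame(substrate = tc$meta$substrate, L_aa = tc$meta$L,
               dt1_s = tc$meta$dt1, replicate = tc$meta$replicate,
               peak_time_s = pk$peak_time, peak_height = pk$peak_height,
               has_peak = pk$has_peak)
  }))
  rownames(peaks) <- NULL
  if (any(!peaks$has_peak))
    warning(sprintf("%d trace(s) without an interior peak were dropped",
                    sum(!peaks$has_peak)))
  peaks_ok <- peaks[peaks$has_peak, ]
  fits <- list()
  rows <- list()
  for (d in sort(unique(peaks_ok$dt1_s))) {
    sub <- peaks_ok[peaks_ok$dt1_s == d, ]
    agg <- stats::aggregate(peak_time_s ~ substrate + L_aa, data = sub,
                            FUN = mean)
    agg$sd <- stats::aggregate(peak_time_s ~ substrate + L_aa, data = sub,
                               FUN = function(v)
                                 if (length(v) > 1L) stats::sd(v) else NA_real_
                               )$peak_time_s
    if (nrow(agg) < 2L) {
      warning(sprintf("dt1 = %g s: fewer than 2 substrates with peaks; skipped", d))
      next
    }
    ft <- fit_length_vs_peaktime(agg$peak_time_s, agg$L_aa, sd = agg$sd)
    fits[[as.character(d)]] <- ft
    if (verbose)
      message(sprintf("peaktime: dt1 = %g s -> C = %.3f aa (rate %.4f aa/s)",
                      d, ft$intercept, ft$slope))
    rows[[as.character(d)]] <- data.frame(
      dt1_s = d, slope_aa_per_s = ft$slope, slope_sd = ft$slope_sd,
      intercept_aa = ft$intercept, intercept_sd = ft$intercept_sd)
  }
  per_dt1 <- do.call(rbind, rows)
  rownames(per_dt1) <- NULL
  dt1_fit <- NULL
  if (!is.null(per_dt1) && nrow(per_dt1) >= 2L) {
    sds <- per_dt1$intercept_sd
    dt1_fit <- fit_pretranslocation_vs_dt1(
      per_dt1$dt1_s, per_dt1$intercept_aa,
      sd = if (all(is.finite(sds)) && all(sds > 0)) sds else NULL)
  }
  list(peaks = peaks, per_dt1 = per_dt1, fits = fits, dt1_fit = dt1_fit)
}
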