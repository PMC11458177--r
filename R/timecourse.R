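#' Stopped-flow fluorescence time course
#'
#' Container for one fluorescence trace: a strictly increasing time grid, the
#' signal at each time, and metadata identifying the substrate, the delay time
#' between the first and second mixing events, the replicate, and whether the
#' signal is raw instrument fluorescence or relative fluorescence enhancement.
#'
#' @param t time grid (s), strictly increasing, nonnegative.
#' @param y signal values, same length as `t`; raw fluorescence (arbitrary
#'   units) or relative enhancement depending on `normalization`.
#' @param substrate substrate name (e.g. `"RepA-Titin_3"`).
#' @param L total substrate length in amino acids.
#' @param dt1 delay time between mixing events (s); `NA` for standard mixing.
#' @param replicate replicate index.
#' @param normalization `"raw"` or `"relative"`.
#' @param sd optional per-point standard deviation (from replicate averaging).
#' @param n_averaged number of replicates averaged into this trace.
#' @return an object of class `timecourse`.
#' @export
timecourse <- function(t, y, substrate = NA_character_, L = NA_real_,
                       dt1 = NA_real_, replicate = NA_integer_,
                       normalization = c("raw", "relative"),
                       sd = NULL, n_averaged = 1L) {
  check_time_grid(t)
  normalization <- match.arg(normalization)
  if (!is.numeric(y) || length(y) != length(t) || anyNA(y) || any(!is.finite(y)))
    stop_usage("`y` must be finite numeric of the same length as `t`")
  if (!is.null(sd) && (length(sd) != length(t) || any(sd < 0)))
    stop_usage("`sd` must be nonnegative and match the grid length")
  structure(
    list(t = as.numeric(t), y = as.numeric(y), sd = sd,
         meta = list(substrate = substrate, L = L, dt1 = dt1,
                     replicate = replicate, normalization = normalization,
                     n_averaged = as.integer(n_averaged))),
    class = "timecourse")
}

is_timecourse <- function(x) inherits(x, "timecourse")

#' @export
print.timecourse <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<timecourse> %s (L = %s aa), dt1 = %s s, replicate %s\n",
              m$substrate, format(m$L), format(m$dt1), format(m$replicate)))
  cat(sprintf("  %d points, t in [%.4g, %.4g] s, %s signal",
              length(x$t), min(x$t), max(x$t), m$normalization))
  if (m$n_averaged > 1L) cat(sprintf(" (mean of %d replicates)", m$n_averaged))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.timecourse <- function(x, ...) {
  d <- data.frame(time_s = x$t, y = x$y)
  names(d)[2] <- if (x$meta$normalization == "raw") "fluorescence" else "rel_enhancement"
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}

#' Write a time course to delimited text
#'
#' One trace per file: `#`-prefixed metadata header lines followed by a CSV
#' body with columns `time_s` and `fluorescence` (raw) or `rel_enhancement`
#' (normalized), plus `sd` when present.
#'
#' @param tc a [timecourse].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(is_timecourse(tc))
  m <- tc$meta
  hdr <- c(
    sprintf("# substrate: %s", m$substrate),
    sprintf("# L_aa: %s", format(m$L, digits = 17)),
    sprintf("# dt1_s: %s", format(m$dt1, digits = 17)),
    sprintf("# replicate: %s", format(m$replicate)),
    sprintf("# normalization: %s", m$normalization),
    sprintf("# n_averaged: %d", m$n_averaged))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(as.data.frame(tc), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course from delimited text
#'
#' Parses the CSV trace format written by [write_timecourse()]: optional
#' `# key: value` metadata lines, then a header row naming `time_s` and either
#' `fluorescence` or `rel_enhancement`. Time must be strictly increasing;
#' parse failures report the offending row.
#'
#' @param path file path.
#' @return a [timecourse]; normalization state is taken from the metadata or,
#'   failing that, from the signal column name.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: %s", path)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  body <- lines[!is_meta]
  if (length(body) < 2L) stop_usage("%s: no data rows", path)
  d <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(d))
    stop_usage("%s: missing required column 'time_s'", path)
  ycol <- intersect(c("fluorescence", "rel_enhancement"), names(d))
  if (length(ycol) == 0L)
    stop_usage("%s: need a 'fluorescence' or 'rel_enhancement' column", path)
  ycol <- ycol[1]
  bad <- which(!is.finite(d$time_s) | !is.finite(d[[ycol]]))
  if (length(bad))
    stop_usage("%s: non-numeric or missing value at data row %d", path, bad[1])
  nonmono <- which(diff(d$time_s) <= 0)
  if (length(nonmono))
    stop_usage("%s: time not strictly increasing at data row %d (t = %g)",
               path, nonmono[1] + 1L, d$time_s[nonmono[1] + 1L])
  norm <- meta[["normalization"]]
  if (is.null(norm)) norm <- if (ycol == "fluorescence") "raw" else "relative"
  num_or_na <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  timecourse(
    t = d$time_s, y = d[[ycol]],
    substrate = if (is.null(meta$substrate)) NA_character_ else meta$substrate,
    L = num_or_na(meta$L_aa), dt1 = num_or_na(meta$dt1_s),
    replicate = as.integer(num_or_na(meta$replicate)),
    normalization = norm, sd = d$sd,
    n_averaged = if (is.null(meta$n_averaged)) 1L else as.integer(meta$n_averaged))
}
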