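#' @keywords internal
"_PACKAGE"

# shared argument checks --------------------------------------------------

stop_usage <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_usage("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_usage("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_usage("`%s` must be >= %g (got %g)", name, lower, x)
  if (strict_upper && x >= upper)
    stop_usage("`%s` must be < %g (got %g)", name, upper, x)
  if (!strict_upper && x > upper)
    stop_usage("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

check_time_grid <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || anyNA(t))
    stop_usage("time grid must be numeric and free of NA")
  if (any(t < 0)) stop_usage("time grid must be nonnegative")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_usage("time grid must be strictly increasing")
  invisible(t)
}

#' Default stopped-flow sampling grid
#'
#' Log-spaced time grid matching typical single-turnover stopped-flow
#' acquisition: dense at early times to resolve the lag, extending far enough
#' to capture peak times of a few thousand seconds.
#'
#' @param t_min,t_max first and last sample time (s).
#' @param n number of samples.
#' @return numeric vector of times (s), strictly increasing.
#' @export
default_time_grid <- function(t_min = 1e-2, t_max = 5000, n = 2000L) {
  check_scalar(t_min, "t_min", lower = 0, strict_lower = TRUE)
  check_scalar(t_max, "t_max", lower = t_min, strict_lower = TRUE)
  exp(seq(log(t_min), log(t_max), length.out = n))
}

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
# method; cached since only one size is used internally.
gauss_legendre_01 <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1, ]^2
    ord <- order(x)
    out <- list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
    cache[[key]] <<- out
    out
  }
})

# run code with a private RNG state, restoring the caller's stream
with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  force(code)
}
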