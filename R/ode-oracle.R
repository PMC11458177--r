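#' Linear-chain ODE reference solution (integer n)
#'
#' Integrates the (n + 2)-state master equation of the sequential mechanism
#' directly: `n` forward steps at `k_U`, one terminal step at `k_end`, unit
#' initial occupancy of the first state. This is an implementation-independent
#' reference for [last_intermediate_fraction()] and [product_fraction()]; it
#' is exact only for integer `n` and is intended for verification, not for
#' fitting.
#'
#' @param params a [scheme_params] whose `n` is a nonnegative integer
#'   (<= 10000).
#' @param t time grid (s); 0 is prepended internally for the integrator.
#' @param full if `TRUE`, also return the occupancy of every chain state.
#' @return a data frame with columns `t`, `last_intermediate`, `product`
#'   (and, when `full`, a `states` matrix attribute).
#' @export
ode_oracle <- function(params, t, full = FALSE) {
  stopifnot(inherits(params, "scheme_params"))
  check_time_grid(t)
  n <- params$n
  if (n != round(n) || n < 0 || n > 1e4)
    stop_usage("ode_oracle requires integer n in [0, 10000]; got %g", n)
  n <- as.integer(n)
  k_U <- params$k_U
  k_end <- params$k_end
  # states 1..(n+1) are the chain (state n+1 = last intermediate),
  # state n+2 is the released product
  rates <- c(rep(k_U, n), k_end)
  rhs <- function(tt, y, p) {
    flux <- rates * y[seq_len(n + 1L)]
    dy <- numeric(n + 2L)
    dy[seq_len(n + 1L)] <- -flux
    dy[seq_len(n + 1L) + 1L] <- dy[seq_len(n + 1L) + 1L] + flux
    list(dy)
  }
  y0 <- c(1, rep(0, n + 1L))
  times <- if (t[1] == 0) t else c(0, t)
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  if (attr(sol, "istate")[1] < 0)
    stop_usage("ode_oracle: integrator failed (istate = %d)",
               attr(sol, "istate")[1])
  keep <- if (t[1] == 0) seq_len(nrow(sol)) else -1L
  states <- sol[keep, -1L, drop = FALSE]
  out <- data.frame(t = t,
                    last_intermediate = states[, n + 1L],
                    product = states[, n + 2L])
  if (full) attr(out, "states") <- states
  out
}
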