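# Processivity algebra: the amount of motor that reaches the fluorophore in
# a single-turnover experiment is the amount initially bound times the
# per-step continuation probability raised to the number of steps taken.
# Two equivalent parameterizations of processivity are supported: P, the
# per-step probability of continuing rather than dissociating, and N, the
# mean number of amino acids processed per binding event, with P = exp(-m/N).
# The per-intermediate dissociation rate constant k_d used here is distinct
# from the terminal dissociation k_end of the signal model, which has no
# dissociation from intermediate states.

#' Extent of binding
#'
#' Fraction of total substrate carrying a bound motor hexamer at mixing; the
#' single-turnover amplitude is directly proportional to it.
#'
#' @param bound concentration of motor-substrate complex (same units as
#'   `total`).
#' @param total total substrate concentration (> 0).
#' @return fraction in `[0, 1]`.
#' @export
extent_of_binding <- function(bound, total) {
  check_scalar(total, "total", lower = 0, strict_lower = TRUE)
  check_scalar(bound, "bound", lower = 0)
  if (bound > total)
    stop_usage("bound (%g) exceeds total substrate (%g)", bound, total)
  bound / total
}

#' Per-step processivity from rate constants
#'
#' `P = k_U / (k_U + k_d)`: the probability that an intermediate takes the
#' next unfolding step rather than dissociating, where `k_d` is the
#' dissociation rate constant at each intermediate.
#'
#' @param k_U unfolding rate constant (1/s), > 0.
#' @param k_d per-intermediate dissociation rate constant (1/s), >= 0.
#' @return P in (0, 1].
#' @export
p_from_rates <- function(k_U, k_d) {
  check_scalar(k_U, "k_U", lower = 0, strict_lower = TRUE)
  check_scalar(k_d, "k_d", lower = 0)
  k_U / (k_U + k_d)
}

#' Per-step processivity from step-size and processivity in amino acids
#'
#' `P = exp(-m / N)` with `m` the kinetic step-size (aa) and `N` the
#' processivity expressed as mean amino acids processed per binding event.
#'
#' @param m kinetic step-size (aa), > 0.
#' @param N processivity (aa), > 0.
#' @return P in (0, 1).
#' @export
p_from_step_and_N <- function(m, N) {
  check_scalar(m, "m", lower = 0, strict_lower = TRUE)
  check_scalar(N, "N", lower = 0, strict_lower = TRUE)
  exp(-m / N)
}

#' Processivity in amino acids from P and step-size
#'
#' Inverse of [p_from_step_and_N()]: `N = -m / log(P)`. `P = 1` corresponds
#' to infinite processivity and is rejected rather than returned as a
#' number.
#'
#' @param P per-step continuation probability, strictly inside (0, 1).
#' @param m kinetic step-size (aa), > 0.
#' @return N in amino acids.
#' @export
N_from_p_and_step <- function(P, m) {
  check_scalar(m, "m", lower = 0, strict_lower = TRUE)
  check_scalar(P, "P", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  -m / log(P)
}

#' Expected single-turnover peak amplitude
#'
#' `amplitude = X * P^n * F`: extent of binding times the probability of
#' surviving all `n` steps to the fluorophore times a fluorescence output
#' factor. Strictly decreasing in `n` when `P < 1` and increasing in `X`, so
#' a lower observed peak is consistent with less motor bound, lower
#' processivity, or both.
#'
#' @param X extent of binding in `[0, 1]`.
#' @param P per-step processivity in (0, 1].
#' @param n number of steps (>= 0, real).
#' @param fluor_factor fluorescence output factor (> 0).
#' @return expected amplitude (same units as `fluor_factor`).
#' @export
amplitude_model <- function(X, P, n, fluor_factor = 1) {
  check_scalar(X, "X", lower = 0, upper = 1)
  check_scalar(P, "P", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(n, "n", lower = 0)
  check_scalar(fluor_factor, "fluor_factor", lower = 0, strict_lower = TRUE)
  X * P^n * fluor_factor
}
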