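# Closed-form solutions of the deterministic phase in the three tractable
# parameter regimes, the sweep duration, and the soft-sweep threshold.

.check_regime <- function(ok, regime, violated) {
  if (!ok)
    stop(sprintf("unsupported regime for %s closed forms: requires %s",
                 regime, violated), call. = FALSE)
}

.gate_case1 <- function(params) {
  .check_regime(params$r == 0, "case 1", "r = 0")
  .check_regime(params$mu_A == 0 && params$mu_Abar == 0, "case 1",
                "mu_A = mu_Abar = 0")
  .check_regime(params$s1 == 0, "case 1", "s1 = 0")
}

.gate_case2 <- function(params) {
  .check_regime(params$mu_A == 0 && params$mu_Abar == 0, "case 2",
                "mu_A = mu_Abar = 0")
  .check_regime(params$s1 == 0, "case 2", "s1 = 0")
}

.gate_case3 <- function(params) {
  .check_regime(params$mu_B == 0, "case 3", "mu_B = 0")
  .check_regime(params$mu_A > 0, "case 3", "mu_A > 0")
  .check_regime(params$mu_Abar == 0, "case 3", "mu_Abar = 0")
  .check_regime(params$s1 < 0, "case 3", "s1 < 0 (A deleterious)")
}

#' Integration constant of the mutation-only sweep solution
#'
#' For the regime with recurrent beneficial mutation only (`r = 0`,
#' `mu_A = mu_Abar = 0`, `s1 = 0`) the background difference obeys
#' `p1 - p2 = C (s2 x + mu_B) / x` with
#' `C = x0 / (s2 x0 + mu_B) * (p10 - p20)`.
#'
#' @param params A [sweep_params()] in the case-1 regime.
#' @param init An [initial_conditions()] object.
#' @return The scalar constant `C`.
#' @export
case1_constants <- function(params, init) {
  .gate_case1(params)
  init$x0 / (params$s2 * init$x0 + params$mu_B) * (init$p10 - init$p20)
}

#' Closed-form sweep solution: recurrent mutation, no recombination
#'
#' Exact solution of the deterministic phase when the only forces are strong
#' selection and recurrent mutation at the selected locus
#' (`mu_B >= 0, r = 0, mu_A = mu_Abar = 0, s1 = 0`), parameterized by the
#' frequency `x` of the beneficial allele:
#' `p1 - p2 = C (s2 x + mu_B) / x`, `p2 = p20` (mutation at the selected
#' locus does not touch the `b` background), and the gamete frequencies
#' `x1 = C (s2 x + mu_B) + p20 x`, `x2 = x - x1`. With `p10 = p20` the ratio
#' `x1 / x` stays constant through the whole sweep.
#'
#' @param x Frequency (or vector of frequencies) of `B`, with
#'   `x0 <= x < 1`.
#' @param params A [sweep_params()] in the case-1 regime.
#' @param init An [initial_conditions()] object.
#' @return Data frame with columns `x, p1_minus_p2, p1, p2, x1, x2`.
#' @examples
#' p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
#' ic <- initial_conditions(0.005, p10 = 0, p20 = 0.7)
#' case1_solution(0.5, p, ic)
#' @export
case1_solution <- function(x, params, init) {
  C <- case1_constants(params, init)
  pm <- C * (params$s2 * x + params$mu_B) / x
  x1 <- C * (params$s2 * x + params$mu_B) + init$p20 * x
  data.frame(x = x, p1_minus_p2 = pm, p1 = pm + init$p20, p2 = init$p20,
             x1 = x1, x2 = x - x1)
}

#' Frequency of the beneficial allele under selection plus mutation
#'
#' Exact solution of `dx/dt = (s2 x + mu_B)(1 - x)`: with
#' `gamma = s2 + mu_B` and `K = (s2 x0 + mu_B)/(1 - x0)`,
#' `x(t) = (K e^(gamma t) - mu_B) / (s2 + K e^(gamma t))`. For `mu_B = 0`
#' this is the classical logistic sweep
#' `x0 / (x0 + (1 - x0) e^(-s2 t))`.
#'
#' @param t Time (generations) since the start of the deterministic phase;
#'   may be a vector.
#' @param params A [sweep_params()] in the case-1 regime.
#' @param x0 Initial frequency of `B`.
#' @return Frequency (vector) of `B` at `t`.
#' @examples
#' case1_x_of_t(500, sweep_params(s2 = 0.01, mu_B = 1e-4), x0 = 0.005)
#' @export
case1_x_of_t <- function(t, params, x0) {
  .gate_case1(params)
  if (any(t < 0)) stop("t must be non-negative")
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly inside (0, 1)")
  gam <- params$s2 + params$mu_B
  K <- (params$s2 * x0 + params$mu_B) / (1 - x0)
  E <- K * exp(gam * t)
  (E - params$mu_B) / (params$s2 + E)
}

#' Constants of the mutation-plus-recombination solution
#'
#' `rho = r / (s2 + mu_B)` and the integration constant
#' `C_tilde = x0 / ((1 - x0)^rho (s2 x0 + mu_B)^(1 - rho)) * (p10 - p20)`.
#' The `p2` approximation assumes `rho << 1`; a warning is emitted when
#' `rho > 0.1`.
#'
#' @inheritParams case1_constants
#' @return List with elements `rho` and `C_tilde`.
#' @export
case2_constants <- function(params, init) {
  .gate_case2(params)
  rho <- params$r / (params$s2 + params$mu_B)
  if (rho > 0.1)
    warning("rho = r/(s2 + mu_B) > 0.1: the p2 approximation assumes rho << 1",
            call. = FALSE)
  C_tilde <- init$x0 /
    ((1 - init$x0)^rho * (params$s2 * init$x0 + params$mu_B)^(1 - rho)) *
    (init$p10 - init$p20)
  list(rho = rho, C_tilde = C_tilde)
}

#' Closed-form sweep solution: recurrent mutation plus recombination
#'
#' Regime `mu_B >= 0, r >= 0, s1 = 0, mu_A = mu_Abar = 0`. The background
#' difference
#' `p1 - p2 = C_tilde (1 - x)^rho (s2 x + mu_B)^(1 - rho) / x`
#' is the exact solution of its ODE in `x`; the accompanying
#' `p2 ~ p20 - r C_tilde (log(1 - x) - log(1 - x0))`
#' is a first-order approximation in `rho` (the integration constant is kept
#' so that `p2(x0) = p20` holds exactly; dropping it recovers the small-`x0`
#' form). At `r = 0` everything collapses to the case-1 solution.
#'
#' @inheritParams case1_solution
#' @return Data frame with columns `x, p1_minus_p2, p2_approx` plus
#'   attributes `rho` and `C_tilde`.
#' @examples
#' p <- sweep_params(s2 = 0.01, mu_B = 1e-4, r = 1e-4)
#' ic <- initial_conditions(0.005, p10 = 0, p20 = 0.7)
#' case2_solution(0.9, p, ic)
#' @export
case2_solution <- function(x, params, init) {
  k <- case2_constants(params, init)
  pm <- k$C_tilde * (1 - x)^k$rho *
    (params$s2 * x + params$mu_B)^(1 - k$rho) / x
  p2 <- init$p20 - params$r * k$C_tilde * (log(1 - x) - log(1 - init$x0))
  out <- data.frame(x = x, p1_minus_p2 = pm, p2_approx = p2)
  attr(out, "rho") <- k$rho
  attr(out, "C_tilde") <- k$C_tilde
  out
}

#' Closed-form sweep solution: mutation-selection balance at the linked locus
#'
#' Regime `mu_B = 0, r >= 0, mu_A > 0, s1 < 0`: allele `A` is deleterious and
#' held at the equilibrium frequency `x30 = mu_A / |s1|` before the sweep.
#' Starting from `p10 = 0`, `p20 = x30` (the beneficial mutation arises on an
#' `a` chromosome with high probability), the approximate solutions in
#' `tau = t - t0` are
#' `x = x0 / (x0 + (1 - x0) e^(-s2 tau))`,
#' `p1 - p2 = -p20 e^((s1 - mu_A - r) tau)`, and
#' `p1 = p20 (1 - e^(s1 tau)) + p20 r/(mu_A + r) e^(s1 tau) (1 - e^(-(mu_A + r) tau))`.
#' They assume `|s1|` and `r` are much smaller than `s2`; the relative error
#' shrinks as `|s1|/s2` and `r/s2` decrease.
#'
#' @param tau Time since the start of the deterministic phase (generations);
#'   may be a vector.
#' @param params A [sweep_params()] in the case-3 regime.
#' @param init An [initial_conditions()] object; `p20` should equal the
#'   mutation-selection equilibrium `mu_A / |s1|` and `p10 = 0`.
#' @return Data frame with columns `tau, x, p1_minus_p2, p1, p2`.
#' @examples
#' p <- sweep_params(s1 = -0.001, s2 = 0.05, r = 5e-4, mu_A = 1e-5)
#' ic <- initial_conditions(0.005, p10 = 0, p20 = 0.01)
#' case3_solution(c(0, 100, 200), p, ic)
#' @export
case3_solution <- function(tau, params, init) {
  .gate_case3(params)
  if (any(tau < 0)) stop("tau must be non-negative")
  x <- init$x0 / (init$x0 + (1 - init$x0) * exp(-params$s2 * tau))
  pm <- -init$p20 * exp((params$s1 - params$mu_A - params$r) * tau)
  rterm <- if (params$r == 0) 0 else
    init$p20 * params$r / (params$mu_A + params$r) * exp(params$s1 * tau) *
      (1 - exp(-(params$mu_A + params$r) * tau))
  p1 <- init$p20 * (1 - exp(params$s1 * tau)) + rterm
  data.frame(tau = tau, x = x, p1_minus_p2 = pm, p1 = p1, p2 = p1 - pm)
}

#' Duration of the selective phase
#'
#' Time for the beneficial allele to go from `x0` to `1 - x0` under the
#' logistic sweep. The printed, logistic-symmetry form is
#' `tau_hat = -(2/s2) log(x0)`; the exact logistic expression is
#' `(2/s2) log((1 - x0)/x0)`. The printed form is the default and the two
#' agree to `O(x0)`.
#'
#' @param params A [sweep_params()] object.
#' @param x0 Threshold frequency, `0 < x0 < 0.5`.
#' @param form `"printed"` (default) or `"exact"`.
#' @return Sweep duration in generations.
#' @examples
#' sweep_duration(sweep_params(s2 = 0.01), x0 = 0.005) # ~1059.66
#' @export
sweep_duration <- function(params, x0, form = c("printed", "exact")) {
  form <- match.arg(form)
  if (!is.finite(x0) || x0 <= 0 || x0 >= 0.5)
    stop("x0 must lie in (0, 0.5)")
  if (form == "printed") -(2 / params$s2) * log(x0)
  else (2 / params$s2) * log((1 - x0) / x0)
}

#' Soft-sweep threshold parameter
#'
#' `kappa = mu_B / s2` separates mutation-dominated growth of the beneficial
#' allele (`x < kappa`) from selection-dominated growth (`x > kappa`);
#' larger `kappa` makes multiple-origin soft sweeps more likely. When a
#' deterministic threshold `x0` is supplied the function also reports
#' whether `kappa < x0`, i.e. whether the mutation-dominated range lies
#' entirely inside the stochastic initial phase.
#'
#' @param params A [sweep_params()] object.
#' @param x0 Optional deterministic threshold frequency to compare against.
#' @return List with elements `kappa`, `x0` and `kappa_below_x0` (`NA` when
#'   `x0` is missing).
#' @examples
#' soft_sweep_threshold(sweep_params(s2 = 0.01, mu_B = 1e-6), x0 = 0.025)
#' @export
soft_sweep_threshold <- function(params, x0 = NULL) {
  kappa <- params$mu_B / params$s2
  list(kappa = kappa,
       x0 = if (is.null(x0)) NA_real_ else x0,
       kappa_below_x0 = if (is.null(x0)) NA else kappa < x0)
}
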