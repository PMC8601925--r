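# Diffusion treatment of the stochastic initial phase: moment ODEs, their
# closed-form solutions, the decay law of the A background, the mean time to
# the deterministic threshold, and initial conditions for the deterministic
# phase. All times here are in units of 2N generations.

#' Moment ODEs of the initial-phase diffusions
#'
#' First- and second-moment dynamics of the frequency of the beneficial
#' allele (`which = "x"`) or of the `AB` gamete (`which = "x1"`) during the
#' stochastic initial phase. For `x`:
#' `dm1/dt = theta/2 + alpha m1`, `dm2/dt = (1 + theta) m1 + 2 alpha m2`.
#' For `x1` the mutational input is thinned by the decaying frequency of the
#' `A` background: `theta/2` is replaced by `(theta/2) sigma(t)` and
#' `(1 + theta)` by `(1 + theta sigma(t))`. The moment hierarchy closes
#' because drift and diffusion coefficients are linear in the frequency.
#'
#' @param state Numeric vector `(m1, m2)` (a `moment_state` row works too).
#' @param spec A [diffusion_spec()] object.
#' @param which `"x"` or `"x1"`.
#' @param t Time in units of `2N` generations (needed for `which = "x1"`).
#' @return Named numeric vector `(dm1, dm2)`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' moment_rhs(c(0.001, 5e-7), sp, which = "x")
#' @export
moment_rhs <- function(state, spec, which = c("x", "x1"), t = 0) {
  which <- match.arg(which)
  al <- spec$scale$alpha
  th <- spec$scale$theta
  m1 <- state[[1L]]; m2 <- state[[2L]]
  sg <- if (which == "x") 1 else sigma_decay(t, spec)
  inp <- th / 2 * sg
  fac <- 1 + th * sg
  c(dm1 = inp + al * m1, dm2 = fac * m1 + 2 * al * m2)
}

#' Closed-form moments of the beneficial-allele diffusion
#'
#' Exact solutions of the `x` moment ODEs started from zero mass:
#' `m1(t) = theta/(2 alpha) (e^(alpha t) - 1)`,
#' `m2(t) = (1 + 1/theta) m1(t)^2`, so the variance is `m1(t)^2 / theta`.
#' The coefficient of variation is therefore `1/sqrt(theta)`, typically
#' large: the initial phase is strongly stochastic even though its mean is
#' simple.
#'
#' @param t Time(s) in units of `2N` generations.
#' @param spec A [diffusion_spec()] object.
#' @return Data frame with columns `t, m1, m2, var`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' moments_x_closed(c(0, 0.005, 0.01), sp)
#' @export
moments_x_closed <- function(t, spec) {
  if (any(t < 0)) stop("t must be non-negative")
  al <- spec$scale$alpha
  th <- spec$scale$theta
  m1 <- th / (2 * al) * (exp(al * t) - 1)
  data.frame(t = t, m1 = m1, m2 = (1 + 1 / th) * m1^2, var = m1^2 / th)
}

#' Decay of the A background at the selected locus
#'
#' Frequency of the `Ab` gamete class during the initial phase, relative to
#' the onset of selection: `sigma(t) = x3_star exp(-m1(t))` where `m1(t)` is
#' the closed-form mean of the beneficial-allele diffusion. Equivalently
#' `sigma(t) = x3_star exp(-(theta/(2 alpha)) (e^(alpha t) - 1))`.
#'
#' @inheritParams moments_x_closed
#' @return Numeric vector `sigma(t)`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' sigma_decay(0, sp) # x3_star
#' @export
sigma_decay <- function(t, spec) {
  if (any(t < 0)) stop("t must be non-negative")
  spec$x3_star * exp(-moments_x_closed(t, spec)$m1)
}

#' Closed-form moments of the AB-gamete diffusion
#'
#' Approximate moments of the frequency of gamete `AB` during the initial
#' phase: `m1(t) = (theta/(2 alpha)) x3_star (e^(alpha t) - 1)` and
#' `m2(t) = (1 + 1/(theta x3_star)) m1(t)^2`. They rely on approximating the
#' mutational-input integrand by `e^(-alpha t')`, which is accurate for
#' `t <= 2 tbar0` in the intended range (`alpha > 100`, `theta > 0.005`);
#' beyond that window a warning is attached (attribute
#' `"validity_warning"`). The ratio `m1(x1)/m1(x) = x3_star` for all `t` is
#' what makes `p1(t0) ~ x3_star` at the end of the initial phase.
#'
#' @inheritParams moments_x_closed
#' @param x0 Threshold frequency used to locate the validity window
#'   `t <= 2 tbar0`; defaults to `5/alpha`.
#' @return Data frame with columns `t, m1, m2, var`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' moments_x1_closed(0.01, sp)
#' @export
moments_x1_closed <- function(t, spec, x0 = 5 / spec$scale$alpha) {
  if (any(t < 0)) stop("t must be non-negative")
  al <- spec$scale$alpha
  th <- spec$scale$theta
  xs <- spec$x3_star
  m1 <- th / (2 * al) * xs * (exp(al * t) - 1)
  out <- data.frame(t = t, m1 = m1, m2 = (1 + 1 / (th * xs)) * m1^2,
                    var = (1 + 1 / (th * xs)) * m1^2 - m1^2)
  tmax <- 2 * mean_time_to_threshold(spec, x0)
  if (any(t > tmax)) {
    msg <- sprintf("t exceeds the validity window t <= 2*tbar0 = %.4g (2N units)",
                   tmax)
    warning(msg, call. = FALSE)
    attr(out, "validity_warning") <- msg
  }
  out
}

#' Mean time for the beneficial allele to reach the deterministic threshold
#'
#' Inverts the closed-form mean trajectory at `x0`:
#' `tbar0 = (1/alpha) log(1 + 2 alpha x0 / theta)` in units of `2N`
#' generations, so `m1(tbar0) = x0` exactly. This is the mean of the
#' unconditional diffusion trajectory, not the mean first-hitting time of a
#' finite-population path; the two can differ substantially when `theta` is
#' small (see the package vignette).
#'
#' @param spec A [diffusion_spec()] object.
#' @param x0 Threshold frequency in (0, 1).
#' @return `tbar0` in units of `2N` generations.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.1, 1e-6), 0.9)
#' mean_time_to_threshold(sp, 0.005)
#' @export
mean_time_to_threshold <- function(spec, x0) {
  if (!is.finite(x0) || x0 <= 0 || x0 >= 1)
    stop("x0 must lie strictly inside (0, 1)")
  al <- spec$scale$alpha
  th <- spec$scale$theta
  if (th <= 0) stop("theta must be positive (mu_B > 0) for a finite tbar0")
  log(1 + 2 * al * x0 / th) / al
}

#' Initial conditions for the deterministic phase from the diffusion moments
#'
#' At the end of the stochastic initial phase both haplotype backgrounds of
#' the beneficial allele carry allele `A` at (mean) frequency `x3_star`:
#' `p10 = p20 = x3_star`, with `t0 = 2N tbar0` converted to generations
#' (the single place where the 2N conversion happens). With `p10 = p20` the
#' subsequent deterministic sweep keeps `x1/x` constant, so the competition
#' between mutation and selection is confined to the initial phase. The mean
#' prediction of `p10` is poor in any single population: the coefficient of
#' variation of `x1` at `tbar0`, `sqrt(1/(theta x3_star))`, is attached as
#' attribute `"cv_p10"`.
#'
#' @inheritParams mean_time_to_threshold
#' @return An [initial_conditions()] object with attributes `cv_p10` and
#'   `tbar0_2N`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' deterministic_init(sp, x0 = 0.01)
#' @export
deterministic_init <- function(spec, x0) {
  tbar0 <- mean_time_to_threshold(spec, x0)
  ic <- initial_conditions(x0 = x0, p10 = spec$x3_star, p20 = spec$x3_star,
                           t0 = 2 * spec$scale$N * tbar0)
  attr(ic, "cv_p10") <- sqrt(1 / (spec$scale$theta * spec$x3_star))
  attr(ic, "tbar0_2N") <- tbar0
  ic
}

#' Numerically integrate the moment ODEs
#'
#' Integrates [moment_rhs()] from zero initial moments, mainly as a check on
#' the closed forms.
#'
#' @param spec A [diffusion_spec()] object.
#' @param t_end End time (2N units).
#' @param which `"x"` or `"x1"`.
#' @param n_out Number of output points.
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `t, m1, m2, var`.
#' @examples
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' tail(integrate_moments(sp, t_end = 0.01), 1)
#' @export
integrate_moments <- function(spec, t_end, which = c("x", "x1"),
                              n_out = 201L, rtol = 1e-12, atol = 1e-16) {
  which <- match.arg(which)
  rhs <- function(t, y, parms)
    list(unname(moment_rhs(y, spec, which = which, t = t)))
  sol <- deSolve::ode(y = c(m1 = 0, m2 = 0),
                      times = seq(0, t_end, length.out = n_out),
                      func = rhs, parms = NULL, rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  data.frame(t = sol$time, m1 = sol$m1, m2 = sol$m2,
             var = sol$m2 - sol$m1^2)
}
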