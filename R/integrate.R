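# Numerical integration of the deterministic phase.

#' Integrate the deterministic sweep dynamics
#'
#' Adaptive integration of the transformed-coordinate system from the
#' initial conditions until the beneficial allele reaches `stop_at_x`
#' (located by root finding) or a time cap is hit. The solver is `lsodar`,
#' which switches automatically between non-stiff and stiff methods; with
#' all per-generation rates well below one the dynamics are non-stiff in
#' practice.
#'
#' @param params A [sweep_params()] object.
#' @param init An [initial_conditions()] object.
#' @param stop_at_x Target frequency of `B` in `(x0, 1)`; integration stops
#'   when `x` first reaches it.
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param max_time Cap on integration time past `t0`, in generations.
#'   Defaults to `10 * log(1/(x0 (1 - stop_at_x))) / s2`; the logistic
#'   transit time from `x0` to `stop_at_x` is bounded by one tenth of this
#'   in the admissible regimes, so the cap only bites when the sweep stalls.
#' @param n_out Number of output points on the time grid.
#' @return A [sweep_trajectory()] in generations, ending at the event time.
#'   An attribute `"stop_time"` records the time at which `x = stop_at_x`.
#' @examples
#' p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
#' ic <- initial_conditions(x0 = 0.005, p10 = 0, p20 = 0.7)
#' tr <- integrate_sweep(p, ic, stop_at_x = 0.995)
#' attr(tr, "stop_time")
#' @export
integrate_sweep <- function(params, init, stop_at_x,
                            rtol = 1e-10, atol = 1e-12,
                            max_time = NULL, n_out = 2001L) {
  if (!inherits(params, "sweep_params")) stop("params must be 'sweep_params'")
  if (!inherits(init, "initial_conditions"))
    stop("init must be 'initial_conditions'")
  if (!is.finite(stop_at_x) || stop_at_x <= init$x0 || stop_at_x >= 1)
    stop("stop_at_x must lie in (x0, 1)")
  if (is.null(max_time))
    max_time <- 10 * log(1 / (init$x0 * (1 - stop_at_x))) / params$s2
  times <- seq(init$t0, init$t0 + max_time, length.out = n_out)
  rhs <- function(t, y, parms)
    list(.haplo_rhs(y[1L], y[2L], y[3L], parms))
  root <- function(t, y, parms) y[1L] - stop_at_x
  sol <- deSolve::ode(y = c(x = init$x0, p1 = init$p10, p2 = init$p20),
                      times = times, func = rhs, parms = params,
                      method = "lsodar", rootfunc = root,
                      rtol = rtol, atol = atol)
  troot <- attr(sol, "troot")
  sol <- as.data.frame(sol)
  if (length(troot) == 0 || max(sol$x) < stop_at_x - 1e-8) {
    partial <- sweep_trajectory(sol$time, sol$x, sol$p1, sol$p2)
    stop(errorCondition(
      sprintf("sweep did not complete: x reached only %.6g by t = %.6g",
              max(sol$x), max(sol$time)),
      class = c("sweep_incomplete", "error"),
      trajectory = partial))
  }
  # clamp p1/p2 rounding excursions outside [0,1] at solver tolerance level
  sol$p1 <- pmin(pmax(sol$p1, 0), 1)
  sol$p2 <- pmin(pmax(sol$p2, 0), 1)
  keep <- !duplicated(sol$time)
  traj <- sweep_trajectory(sol$time[keep], sol$x[keep], sol$p1[keep],
                           sol$p2[keep])
  attr(traj, "stop_time") <- troot[1L]
  traj
}
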