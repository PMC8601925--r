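# Semi-deterministic sweep pipeline: stochastic initial phase (diffusion
# moments or a sampled Wright-Fisher path) stitched to the deterministic ODE
# phase at the threshold frequency x0.

#' Semi-deterministic sweep trajectory
#'
#' Composes the two phases of the sweep model. Below the threshold
#' frequency `x0` the beneficial allele is governed by drift, mutation and
#' selection in a finite population; above it the dynamics are
#' deterministic. `mode = "moment_init"` starts the deterministic phase from
#' the diffusion-moment initial conditions
#' (`p10 = p20 = x3_star`, `t0 = 2N tbar0`); `mode = "sampled_init"` draws
#' one Wright-Fisher path (given `seed`) and hands the state at the first
#' generation with `x >= x0` to the ODE integrator (no sub-generation
#' interpolation; the overshoot is recorded).
#'
#' @param params A [sweep_params()] object; must describe the same `s2` and
#'   `mu_B` as `spec`.
#' @param spec A [diffusion_spec()] object (provides `N`, `alpha`, `theta`,
#'   `x3_star`).
#' @param x0 Threshold frequency, or `"auto"` for `5/alpha`.
#' @param mode `"moment_init"` or `"sampled_init"`.
#' @param seed Integer seed, required for `"sampled_init"`.
#' @param epsilon Soft-sweep detection threshold applied to the final state.
#' @param max_generations Cap for the stochastic phase in `"sampled_init"`.
#' @param ... Passed on to [integrate_sweep()] (tolerances, grid size).
#' @return A list of class `"semidet_sweep"`: `trajectory` (deterministic
#'   phase, in generations, starting at the phase boundary `t0`),
#'   `boundary` (`t0` in generations), `init` (the stitched
#'   [initial_conditions()]), `summary` (a `"sweep_summary"`), and for
#'   `"sampled_init"` the sampled boundary state and its overshoot.
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 1e-6)
#' sp <- diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), 0.9)
#' sw <- semideterministic_sweep(p, sp, x0 = 0.01)
#' sw$summary
#' @export
semideterministic_sweep <- function(params, spec, x0 = "auto",
                                    mode = c("moment_init", "sampled_init"),
                                    seed = NULL, epsilon = 0.05,
                                    max_generations = 200000L, ...) {
  mode <- match.arg(mode)
  if (!inherits(params, "sweep_params")) stop("params must be 'sweep_params'")
  if (!inherits(spec, "diffusion_spec")) stop("spec must be 'diffusion_spec'")
  sc <- spec$scale
  if (abs(sc$alpha - 2 * sc$N * params$s2) > 1e-9 * sc$alpha ||
      abs(sc$theta - 4 * sc$N * params$mu_B) > 1e-9 * max(sc$theta, 1e-300))
    stop("params and spec are inconsistent: alpha and theta must equal ",
         "2*N*s2 and 4*N*mu_B for the same s2, mu_B, N")
  if (identical(x0, "auto")) x0 <- 5 / sc$alpha
  overshoot <- NA_real_
  boundary_state <- NULL
  if (mode == "moment_init") {
    init <- deterministic_init(spec, x0)
  } else {
    if (is.null(seed)) stop("sampled_init requires a seed")
    set.seed(seed)
    g0 <- c(0, 0, spec$x3_star, 1 - spec$x3_star)
    res <- .wf_run(params, sc$N, g0, max_generations, x0,
                   stop_at_completion = FALSE, stop_at_hit = TRUE)
    if (is.na(res$hit))
      stop("threshold not reached: beneficial allele did not attain x0 ",
           "within the generation cap")
    # rerun to the hitting generation to obtain the state there
    set.seed(seed)
    res2 <- .wf_run(params, sc$N, g0, res$hit, x0,
                    record_at = res$hit, stop_at_completion = FALSE)
    g_hit <- res2$rec[1L, ]
    x_hit <- g_hit[1L] + g_hit[2L]
    overshoot <- x_hit - x0
    boundary_state <- gamete_freqs(g_hit[1L], g_hit[2L], g_hit[3L], g_hit[4L])
    h <- to_haplo(boundary_state)
    init <- initial_conditions(x0 = h[["x"]], p10 = h[["p1"]],
                               p20 = h[["p2"]], t0 = res$hit)
  }
  traj <- integrate_sweep(params, init, stop_at_x = 1 - x0, ...)
  fin <- traj[nrow(traj), ]
  g_end <- c(fin$x1, fin$x2, fin$x3, fin$x4)
  summary <- .sweep_summary(
    tau_hat = attr(traj, "stop_time"),
    p_end = fin$p_A,
    H_ratio = fin$H / traj$H[1L],
    kappa = params$mu_B / params$s2,
    final = g_end,
    classification = .classify(g_end, epsilon, swept = TRUE),
    mode = mode)
  structure(list(trajectory = traj, boundary = init$t0, init = init,
                 boundary_state = boundary_state, overshoot = overshoot,
                 summary = summary, x0 = x0),
            class = "semidet_sweep")
}

#' @export
print.semidet_sweep <- function(x, ...) {
  cat("Semi-deterministic sweep\n")
  cat(sprintf("  phase boundary t0 : %.6g generations (x0 = %.4g)\n",
              x$boundary, x$x0))
  cat(sprintf("  sweep completes at: %.6g generations\n",
              x$summary$tau_hat))
  cat(sprintf("  classification    : %s\n", x$summary$classification))
  invisible(x)
}
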