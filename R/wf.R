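# Discrete-generation two-locus Wright-Fisher forward simulator: the
# brute-force oracle for the diffusion moments and the engine for soft-sweep
# classification and scanning.
#
# Life cycle per generation: one Euler application of the full deterministic
# right-hand side (selection + mutation + recombination jointly, valid to
# first order because all rates are << 1), then multinomial resampling of
# 2N gametes.

#' Configuration of a Wright-Fisher simulation
#'
#' @param params A [sweep_params()] object.
#' @param N Diploid population size (>= 10); `2N` gametes are resampled each
#'   generation.
#' @param init A [gamete_freqs()] starting state. The canonical sweep setup
#'   is `gamete_freqs(0, 0, x3_star, 1 - x3_star)`: no beneficial copies yet,
#'   allele `A` at frequency `x3_star`.
#' @param max_generations Cap on the number of generations (>= 1).
#' @param seed Integer seed; mandatory, so that `(seed, config)` fully
#'   determines every output.
#' @param record_every Thinning interval for recorded trajectories.
#' @param epsilon Soft-sweep detection threshold: at sweep end, a sweep is
#'   `multiple_origin_soft` if both `x1 > epsilon` and `x2 > epsilon`
#'   (both origin backgrounds carry the beneficial allele in substantial
#'   amounts), `hard` if exactly one does. Default 0.05.
#' @param x0 Threshold frequency: hitting times are measured at `x >= x0`
#'   and a sweep is complete at `x >= 1 - x0`. `"auto"` resolves to
#'   `5 / (2 N s2)`.
#' @return An object of class `"sim_config"`.
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 2.5e-5)
#' sim_config(p, N = 2000, init = gamete_freqs(0, 0, 0.5, 0.5),
#'            max_generations = 5000, seed = 1)
#' @export
sim_config <- function(params, N, init, max_generations, seed,
                       record_every = 1L, epsilon = 0.05, x0 = "auto") {
  if (!inherits(params, "sweep_params")) stop("params must be 'sweep_params'")
  if (!inherits(init, "gamete_freqs"))
    init <- gamete_freqs(init[1L], init[2L], init[3L], init[4L])
  if (!is.finite(N) || N < 10) stop("N must be >= 10")
  if (!is.finite(max_generations) || max_generations < 1)
    stop("max_generations must be >= 1")
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an integer seed is mandatory")
  if (identical(x0, "auto")) x0 <- 5 / (2 * N * params$s2)
  if (!is.finite(x0) || x0 <= 0 || x0 >= 0.5) stop("x0 must lie in (0, 0.5)")
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  structure(list(params = params, N = as.integer(N), init = init,
                 max_generations = as.integer(max_generations),
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 epsilon = epsilon, x0 = x0),
            class = "sim_config")
}

#' One Wright-Fisher generation
#'
#' Applies the deterministic right-hand side as a one-generation Euler step
#' to obtain expected gamete frequencies (clipped to the simplex), then
#' draws the realized frequencies as a multinomial sample of `2N` gametes.
#' Uses the current R RNG state; seed management is the caller's job (see
#' [run_replicate()] / [ensemble_stats()]).
#'
#' @param g Current gamete frequencies (numeric vector of length 4).
#' @param params A [sweep_params()] object.
#' @param N Diploid population size.
#' @return Numeric vector of next-generation gamete frequencies.
#' @examples
#' set.seed(1)
#' wf_step(gamete_freqs(0, 0, 0.9, 0.1), sweep_params(s2 = 0.05, mu_B = 1e-4), 500)
#' @export
wf_step <- function(g, params, N) {
  gp <- unclass(g) + .gamete_rhs(unclass(g), params)
  if (any(gp < -1e-6) || any(gp > 1 + 1e-6))
    stop("expected frequencies left the simplex by more than 1e-6: ",
         "per-generation rates are too large for the Euler life cycle")
  gp[gp < 0] <- 0
  gp <- gp / sum(gp)
  as.vector(stats::rmultinom(1L, 2L * N, gp)) / (2 * N)
}

# inner loop shared by run_replicate / ensemble_stats / softness_scan.
# Returns hitting/completion generations (NA if not reached), final state,
# and optionally the states at `record_at` generations (sorted, may be
# empty). Stops at completion (x >= 1 - x0) unless run_past_completion.
.wf_run <- function(params, N, g, max_gen, x0, record_at = integer(0),
                    stop_at_completion = TRUE, stop_at_hit = FALSE) {
  two_n <- 2L * N
  hit <- NA_integer_
  done <- NA_integer_
  nrec <- length(record_at)
  rec <- if (nrec) matrix(NA_real_, nrow = nrec, ncol = 4L) else NULL
  ri <- 1L
  mu_free <- params$mu_B == 0 && params$mu_A == 0 && params$mu_Abar == 0
  for (gen in seq_len(max_gen)) {
    gp <- g + .gamete_rhs(g, params)
    gp[gp < 0] <- 0
    g <- as.vector(stats::rmultinom(1L, two_n, gp)) / two_n
    x <- g[1L] + g[2L]
    if (is.na(hit) && x >= x0) hit <- gen
    if (is.na(done) && x >= 1 - x0) done <- gen
    while (ri <= nrec && record_at[ri] == gen) {
      rec[ri, ] <- g
      ri <- ri + 1L
    }
    if (!is.na(done) && stop_at_completion) break
    if (!is.na(hit) && stop_at_hit && ri > nrec) break
    if (mu_free && x == 0 && ri > nrec) break  # B lost, cannot re-arise
  }
  # pad unreached recording points with the absorbing/final state
  while (ri <= nrec) { rec[ri, ] <- g; ri <- ri + 1L }
  list(hit = hit, done = done, final = g, rec = rec, last_gen = gen)
}

.classify <- function(g, epsilon, swept) {
  if (!swept) return("no_sweep")
  soft <- g[1L] > epsilon && g[2L] > epsilon
  if (soft) "multiple_origin_soft" else "hard"
}

#' Run a single Wright-Fisher replicate
#'
#' Simulates generations until the sweep completes (`x >= 1 - x0`) or the
#' generation cap is reached, recording the first generation at which
#' `x >= x0` (hitting time) and classifying the outcome at sweep end:
#' `multiple_origin_soft` if both `AB` and `aB` exceed the detection
#' threshold `epsilon`, `hard` if exactly one does, `no_sweep` if the cap
#' was reached first.
#'
#' @param cfg A [sim_config()] object.
#' @return A list of class `"wf_replicate"` with elements `outcome`
#'   (class `"sweep_outcome"`: `swept`, `classification`, `final`,
#'   `hitting_time_x0`, `completion_time`) and `trajectory` (a
#'   [sweep_trajectory()] of the recorded generations; rows where `x` is at
#'   a boundary are recorded in gamete columns only, with `p1`/`p2` set NA).
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 2.5e-4)
#' cfg <- sim_config(p, N = 500, init = gamete_freqs(0, 0, 0.5, 0.5),
#'                   max_generations = 2000, seed = 42)
#' run_replicate(cfg)$outcome
#' @export
run_replicate <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a 'sim_config'")
  set.seed(cfg$seed)
  record_at <- seq(cfg$record_every, cfg$max_generations,
                   by = cfg$record_every)
  res <- .wf_run(cfg$params, cfg$N, unclass(cfg$init), cfg$max_generations,
                 cfg$x0, record_at = record_at, stop_at_completion = TRUE)
  swept <- !is.na(res$done)
  outcome <- structure(
    list(swept = swept,
         classification = .classify(res$final, cfg$epsilon, swept),
         final = gamete_freqs(res$final[1L], res$final[2L], res$final[3L],
                              res$final[4L]),
         hitting_time_x0 = res$hit,
         completion_time = res$done),
    class = "sweep_outcome")
  keep <- record_at <= res$last_gen
  rec <- res$rec[keep, , drop = FALSE]
  times <- record_at[keep]
  x <- rec[, 1L] + rec[, 2L]
  inner <- x > 0 & x < 1
  p1 <- ifelse(inner, rec[, 1L] / x, NA_real_)
  p2 <- ifelse(inner, rec[, 3L] / (1 - x), NA_real_)
  traj <- data.frame(time = times, x1 = rec[, 1L], x2 = rec[, 2L],
                     x3 = rec[, 3L], x4 = rec[, 4L], x = x, p1 = p1, p2 = p2,
                     D = rec[, 1L] * rec[, 4L] - rec[, 2L] * rec[, 3L],
                     p_A = rec[, 1L] + rec[, 3L],
                     H = 2 * (rec[, 1L] + rec[, 3L]) * (1 - rec[, 1L] - rec[, 3L]))
  attr(traj, "time_scale") <- "generations"
  class(traj) <- c("sweep_trajectory", "data.frame")
  structure(list(outcome = outcome, trajectory = traj),
            class = "wf_replicate")
}

#' @export
print.sweep_outcome <- function(x, ...) {
  cat(sprintf("WF sweep outcome: %s (swept = %s)\n", x$classification,
              x$swept))
  cat(sprintf("  hitting time of x0 : %s generations\n",
              ifelse(is.na(x$hitting_time_x0), "not reached",
                     x$hitting_time_x0)))
  cat(sprintf("  completion time    : %s generations\n",
              ifelse(is.na(x$completion_time), "not reached",
                     x$completion_time)))
  invisible(x)
}

# deterministic per-replicate substream seeds derived from (seed, index)
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Ensemble statistics of the Wright-Fisher process
#'
#' Runs independent replicates (with deterministic per-replicate seed
#' substreams derived from `cfg$seed`) and returns per-time-point ensemble
#' means and variances of `x` (beneficial allele) and `x1` (gamete `AB`)
#' with Monte-Carlo standard errors, the mean first-hitting time of `x0`,
#' and classification proportions among completed sweeps. The standard
#' error of the variance estimate uses the fourth central moment, since the
#' frequency distribution in the initial phase is far from normal.
#'
#' @param cfg A [sim_config()] object; `max_generations` is the observation
#'   horizon.
#' @param reps Number of replicates (>= 2).
#' @param record_gens Generations at which moments are recorded; defaults to
#'   `record_every` spacing up to `max_generations`.
#' @return A list of class `"wf_ensemble"`: `times`, `mean_x`, `var_x`,
#'   `se_mean_x`, `se_var_x`, `mean_x1`, `se_mean_x1`, `var_x1`,
#'   `n_hit`, `mean_hitting_time`, `se_hitting_time`, `n_swept`, `n_soft`,
#'   `prop_soft`, `reps`.
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 2.5e-4)
#' cfg <- sim_config(p, N = 200, init = gamete_freqs(0, 0, 0.9, 0.1),
#'                   max_generations = 100, seed = 7, record_every = 50)
#' ensemble_stats(cfg, reps = 20)$mean_x
#' @export
ensemble_stats <- function(cfg, reps, record_gens = NULL) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a 'sim_config'")
  if (reps < 2) stop("reps must be >= 2")
  if (is.null(record_gens))
    record_gens <- seq(cfg$record_every, cfg$max_generations,
                       by = cfg$record_every)
  record_gens <- as.integer(sort(unique(record_gens)))
  seeds <- .substream_seeds(cfg$seed, reps)
  nt <- length(record_gens)
  X <- matrix(NA_real_, nrow = reps, ncol = nt)
  X1 <- matrix(NA_real_, nrow = reps, ncol = nt)
  hits <- rep(NA_integer_, reps)
  dones <- rep(NA_integer_, reps)
  finals <- matrix(NA_real_, nrow = reps, ncol = 4L)
  g0 <- unclass(cfg$init)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    res <- .wf_run(cfg$params, cfg$N, g0, cfg$max_generations, cfg$x0,
                   record_at = record_gens, stop_at_completion = FALSE)
    X[i, ] <- res$rec[, 1L] + res$rec[, 2L]
    X1[i, ] <- res$rec[, 1L]
    hits[i] <- res$hit
    dones[i] <- res$done
    finals[i, ] <- res$final
  }
  n_swept <- sum(!is.na(dones))
  soft <- vapply(seq_len(reps), function(i)
    !is.na(dones[i]) && finals[i, 1L] > cfg$epsilon &&
      finals[i, 2L] > cfg$epsilon, logical(1))
  var_cols <- function(M) apply(M, 2L, stats::var)
  se_var <- function(M) {
    n <- nrow(M)
    apply(M, 2L, function(v) {
      m2 <- mean((v - mean(v))^2)
      m4 <- mean((v - mean(v))^4)
      sqrt(max(m4 - (n - 3) / (n - 1) * m2^2, 0) / n)
    })
  }
  structure(list(
    times = record_gens,
    mean_x = colMeans(X), var_x = var_cols(X),
    se_mean_x = sqrt(var_cols(X) / reps), se_var_x = se_var(X),
    mean_x1 = colMeans(X1), var_x1 = var_cols(X1),
    se_mean_x1 = sqrt(var_cols(X1) / reps),
    n_hit = sum(!is.na(hits)),
    mean_hitting_time = mean(hits, na.rm = TRUE),
    se_hitting_time = stats::sd(hits, na.rm = TRUE) /
      sqrt(max(sum(!is.na(hits)), 1)),
    n_swept = n_swept, n_soft = sum(soft),
    prop_soft = if (n_swept > 0) sum(soft) / n_swept else NA_real_,
    reps = reps), class = "wf_ensemble")
}

#' First-hitting times of the threshold frequency
#'
#' Runs replicates until the beneficial allele first reaches `x0` (or the
#' generation cap) and returns the hitting generation of each, for
#' comparison with the diffusion mean-trajectory time
#' [mean_time_to_threshold()].
#'
#' @param cfg A [sim_config()] object.
#' @param reps Number of replicates.
#' @return Integer vector of length `reps`; `NA` where the cap was reached
#'   first.
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 2.5e-4)
#' cfg <- sim_config(p, N = 200, init = gamete_freqs(0, 0, 0.9, 0.1),
#'                   max_generations = 2000, seed = 5)
#' summary(hitting_times(cfg, reps = 10))
#' @export
hitting_times <- function(cfg, reps) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a 'sim_config'")
  seeds <- .substream_seeds(cfg$seed, reps)
  g0 <- unclass(cfg$init)
  vapply(seq_len(reps), function(i) {
    set.seed(seeds[i])
    .wf_run(cfg$params, cfg$N, g0, cfg$max_generations, cfg$x0,
            stop_at_completion = FALSE, stop_at_hit = TRUE)$hit
  }, integer(1))
}

#' Scan the proportion of multiple-origin soft sweeps
#'
#' Runs seeded Wright-Fisher replicate ensembles across a grid of the
#' soft-sweep threshold parameter `kappa = mu_B / s2` and tabulates the
#' proportion of completed sweeps classified as multiple-origin soft. The
#' default axis varies `mu_B` at fixed `s2` (so `theta = 4 N mu_B` co-varies
#' with `kappa`); `vary = "s2"` instead varies `s2` at fixed `mu_B`, the
#' complementary axis along which stronger selection shortens the sweep and
#' suppresses secondary origins.
#'
#' @param base A [sim_config()] providing everything except the scanned
#'   parameter; its `seed` seeds the whole scan.
#' @param values For `vary = "mu_B"`: the `kappa` grid (achieved as
#'   `mu_B = kappa * s2`). For `vary = "s2"`: the `s2` grid (with `mu_B`
#'   from `base`).
#' @param reps Replicates per grid point.
#' @param vary `"mu_B"` (default) or `"s2"`.
#' @return Data frame with columns
#'   `kappa, theta, n_reps, n_swept, n_soft, prop_soft, se` (binomial SE of
#'   `prop_soft` among swept runs). A warning is emitted when any
#'   `theta > 10` (outside the biologically sensible range).
#' @examples
#' p <- sweep_params(s2 = 0.05, mu_B = 2.5e-5)
#' base <- sim_config(p, N = 500, init = gamete_freqs(0, 0, 0.5, 0.5),
#'                    max_generations = 3000, seed = 3)
#' softness_scan(base, values = c(5e-4, 5e-3), reps = 20)
#' @export
softness_scan <- function(base, values, reps, vary = c("mu_B", "s2")) {
  vary <- match.arg(vary)
  if (!inherits(base, "sim_config")) stop("base must be a 'sim_config'")
  nv <- length(values)
  seeds <- matrix(.substream_seeds(base$seed, nv * reps), nrow = nv)
  out <- data.frame(kappa = numeric(nv), theta = numeric(nv),
                    n_reps = integer(nv), n_swept = integer(nv),
                    n_soft = integer(nv), prop_soft = numeric(nv),
                    se = numeric(nv))
  g0 <- unclass(base$init)
  for (k in seq_len(nv)) {
    p0 <- base$params
    if (vary == "mu_B") {
      kap <- values[k]
      params <- sweep_params(s1 = p0$s1, s2 = p0$s2, r = p0$r,
                             mu_A = p0$mu_A, mu_Abar = p0$mu_Abar,
                             mu_B = kap * p0$s2)
    } else {
      params <- sweep_params(s1 = p0$s1, s2 = values[k], r = p0$r,
                             mu_A = p0$mu_A, mu_Abar = p0$mu_Abar,
                             mu_B = p0$mu_B)
      kap <- p0$mu_B / values[k]
    }
    x0 <- 5 / (2 * base$N * params$s2)
    n_swept <- 0L; n_soft <- 0L
    for (i in seq_len(reps)) {
      set.seed(seeds[k, i])
      res <- .wf_run(params, base$N, g0, base$max_generations, x0)
      if (!is.na(res$done)) {
        n_swept <- n_swept + 1L
        if (res$final[1L] > base$epsilon && res$final[2L] > base$epsilon)
          n_soft <- n_soft + 1L
      }
    }
    ps <- if (n_swept > 0) n_soft / n_swept else NA_real_
    out[k, ] <- list(kap, 4 * base$N * params$mu_B, as.integer(reps),
                     n_swept, n_soft, ps,
                     if (n_swept > 0) sqrt(ps * (1 - ps) / n_swept)
                     else NA_real_)
  }
  if (any(out$theta > 10))
    warning("theta > 10 at some grid points: outside the biologically ",
            "sensible range", call. = FALSE)
  out
}
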