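#' Parameters of the two-locus hitchhiking model
#'
#' Collects all per-generation rates and selection coefficients of the
#' two-locus, two-allele sweep model. Locus 1 carries alleles `A`/`a`
#' (the linked, possibly weakly selected site), locus 2 carries `B`/`b`
#' where `B` is the strongly beneficial allele.
#'
#' @param s1 Signed per-generation selection coefficient at the linked locus;
#'   `s1 < 0` means allele `A` is deleterious (purifying selection). Assumed
#'   small relative to `s2`; a warning is emitted if `|s1| >= s2`.
#' @param s2 Per-generation selection coefficient of the beneficial allele
#'   `B`; must be positive.
#' @param r Recombination fraction between the loci, in `[0, 0.5]`.
#' @param mu_A Mutation rate `a -> A` (per generation), non-negative.
#' @param mu_Abar Mutation rate `A -> a`, non-negative.
#' @param mu_B Mutation rate `b -> B` (recurrent beneficial mutation),
#'   non-negative.
#' @param mu_Bbar Mutation rate `B -> b`; fixed at 0 in this model so that the
#'   beneficial allele fixes at the end of a sweep. Any other value is an
#'   error.
#'
#' @return An object of class `"sweep_params"`: a named list of the seven
#'   rates.
#' @examples
#' sweep_params(s2 = 0.01, mu_B = 1e-4)
#' @export
sweep_params <- function(s1 = 0, s2, r = 0, mu_A = 0, mu_Abar = 0,
                         mu_B = 0, mu_Bbar = 0) {
  vals <- c(s1 = s1, s2 = s2, r = r, mu_A = mu_A, mu_Abar = mu_Abar,
            mu_B = mu_B, mu_Bbar = mu_Bbar)
  if (!all(is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (s2 <= 0)
    stop("s2 must be positive (strong directional selection on B)")
  if (mu_A < 0 || mu_Abar < 0 || mu_B < 0)
    stop("mutation rates must be non-negative")
  if (r < 0 || r > 0.5)
    stop("recombination fraction r must lie in [0, 0.5]")
  if (mu_Bbar != 0)
    stop("mu_Bbar is fixed at 0 in this model (back mutation B -> b is excluded)")
  if (abs(s1) >= s2)
    warning("|s1| >= s2: the model assumes selection at the linked locus is ",
            "(much) weaker than at the selected locus", call. = FALSE)
  structure(list(s1 = s1, s2 = s2, r = r, mu_A = mu_A, mu_Abar = mu_Abar,
                 mu_B = mu_B, mu_Bbar = mu_Bbar),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat("Two-locus sweep model parameters\n")
  cat(sprintf("  selection:     s1 = %g, s2 = %g\n", x$s1, x$s2))
  cat(sprintf("  recombination: r = %g\n", x$r))
  cat(sprintf("  mutation:      mu_A = %g, mu_Abar = %g, mu_B = %g (mu_Bbar = 0)\n",
              x$mu_A, x$mu_Abar, x$mu_B))
  cat(sprintf("  soft-sweep threshold kappa = mu_B/s2 = %g\n", x$mu_B / x$s2))
  invisible(x)
}

#' Gamete frequencies of the two-locus model
#'
#' The four gametes are `AB`, `aB`, `Ab`, `ab` with frequencies
#' `x1`, `x2`, `x3`, `x4` summing to one. If `x4` is omitted it is filled in
#' as `1 - x1 - x2 - x3`, which keeps the simplex constraint exact.
#'
#' @param x1,x2,x3 Frequencies of gametes `AB`, `aB`, `Ab`.
#' @param x4 Frequency of gamete `ab`; defaults to `1 - x1 - x2 - x3`.
#' @return A named numeric vector of class `"gamete_freqs"`.
#' @examples
#' gamete_freqs(0.1, 0.2, 0.3, 0.4)
#' @export
gamete_freqs <- function(x1, x2, x3, x4 = NULL) {
  if (is.null(x4)) x4 <- 1 - x1 - x2 - x3
  g <- c(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  if (!all(is.finite(g)))
    stop("gamete frequencies must be finite")
  if (any(g < -1e-9) || any(g > 1 + 1e-9))
    stop("gamete frequencies must lie in [0, 1]")
  if (abs(sum(g) - 1) > 1e-9)
    stop("gamete frequencies must sum to 1 (tolerance 1e-9)")
  structure(g, class = "gamete_freqs")
}

#' Transformed (haplotype-background) coordinates
#'
#' The coordinates used for the analysis of the deterministic phase:
#' `x` is the frequency of the beneficial allele `B`, `p1` the frequency of
#' `A` among `B`-bearing gametes, and `p2` the frequency of `A` among
#' `b`-bearing gametes. The chart is singular at `x = 0` and `x = 1`, so `x`
#' must lie strictly inside `(0, 1)` (boundary guard `1e-12`).
#'
#' @param x Frequency of `B`, in the open interval (0, 1).
#' @param p1 Frequency of `A` on the `B` background, in `[0, 1]`.
#' @param p2 Frequency of `A` on the `b` background, in `[0, 1]`.
#' @return A named numeric vector of class `"haplo_state"`.
#' @examples
#' haplo_state(0.5, 0.462, 0.7)
#' @export
haplo_state <- function(x, p1, p2) {
  h <- c(x = x, p1 = p1, p2 = p2)
  if (!all(is.finite(h)))
    stop("haplotype-state components must be finite")
  if (x <= .x_eps || x >= 1 - .x_eps)
    stop("x must lie strictly inside (0, 1): the (p1, p2) chart is singular ",
         "at the boundary")
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("p1 and p2 must lie in [0, 1]")
  structure(h, class = "haplo_state")
}

# boundary guard of the transformed chart
.x_eps <- 1e-12

#' Diffusion scaling of the initial phase
#'
#' Population size and the scaled parameters of the diffusion approximation:
#' `alpha = 2 N s2` (scaled selection) and `theta = 4 N mu_B` (scaled
#' beneficial mutation rate). Time in the diffusion module is measured in
#' units of `2N` generations.
#'
#' @param N Diploid population size (positive integer).
#' @param s2 Selection coefficient of the beneficial allele.
#' @param mu_B Beneficial mutation rate `b -> B`.
#' @return An object of class `"diffusion_scale"` with fields `N`, `alpha`,
#'   `theta` (and the generating `s2`, `mu_B`).
#' @examples
#' diffusion_scale(N = 5000, s2 = 0.05, mu_B = 1e-6)
#' @export
diffusion_scale <- function(N, s2, mu_B) {
  if (!is.finite(N) || N <= 0 || N != round(N))
    stop("N must be a positive integer")
  if (!is.finite(s2) || s2 <= 0) stop("s2 must be positive")
  if (!is.finite(mu_B) || mu_B < 0) stop("mu_B must be non-negative")
  structure(list(N = as.integer(N), s2 = s2, mu_B = mu_B,
                 alpha = 2 * N * s2, theta = 4 * N * mu_B),
            class = "diffusion_scale")
}

#' Specification of the initial-phase diffusion
#'
#' Bundles the diffusion scaling with `x3_star`, the frequency of the major
#' allele `A` at the onset of selection. The drift coefficient of the `x`
#' process is `a(z) = alpha z + theta/2`, that of the `x1` (gamete `AB`)
#' process is `a(z) = alpha z + (theta/2) sigma(t)`, and both share the
#' diffusion coefficient `b(z) = z`; only the first two moments of the
#' corresponding density are used, never the density itself.
#'
#' The closed-form moments are derived for strong selection and appreciable
#' mutational input; a `in_range` flag records whether `alpha > 100` and
#' `theta > 0.005` (the biologically relevant range the approximations
#' target), and a warning is emitted outside it.
#'
#' @param scale A [diffusion_scale()] object.
#' @param x3_star Frequency of allele `A` at the onset of selection, in (0,1).
#' @return An object of class `"diffusion_spec"`.
#' @examples
#' diffusion_spec(diffusion_scale(5000, 0.05, 1e-6), x3_star = 0.9)
#' @export
diffusion_spec <- function(scale, x3_star) {
  if (!inherits(scale, "diffusion_scale"))
    stop("scale must be a 'diffusion_scale' object")
  if (!is.finite(x3_star) || x3_star <= 0 || x3_star >= 1)
    stop("x3_star must lie strictly inside (0, 1)")
  in_range <- scale$alpha > 100 && scale$theta > 0.005
  if (!in_range)
    warning("parameters outside the intended range (alpha > 100, theta > 0.005); ",
            "closed-form moment approximations may be inaccurate", call. = FALSE)
  structure(list(scale = scale, x3_star = x3_star, in_range = in_range),
            class = "diffusion_spec")
}

#' Initial conditions of the deterministic phase
#'
#' State of the transformed coordinates at time `t0`, the start of the
#' deterministic phase (the time at which the beneficial allele first reaches
#' the threshold frequency `x0`).
#'
#' @param x0 Initial frequency of `B`, in (0, 1).
#' @param p10 Initial frequency of `A` on the `B` background.
#' @param p20 Initial frequency of `A` on the `b` background.
#' @param t0 Time offset in generations at which the deterministic phase
#'   begins (default 0).
#' @return An object of class `"initial_conditions"`.
#' @examples
#' initial_conditions(x0 = 0.005, p10 = 0, p20 = 0.7)
#' @export
initial_conditions <- function(x0, p10, p20, t0 = 0) {
  if (!all(is.finite(c(x0, p10, p20, t0))))
    stop("initial conditions must be finite")
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly inside (0, 1)")
  if (p10 < 0 || p10 > 1 || p20 < 0 || p20 > 1)
    stop("p10 and p20 must lie in [0, 1]")
  structure(list(x0 = x0, p10 = p10, p20 = p20, t0 = t0),
            class = "initial_conditions")
}
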