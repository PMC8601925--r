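# Core dynamics: the two equivalent ODE right-hand sides, the coordinate
# change between gamete frequencies and haplotype-background coordinates,
# and derived observables (D, allele frequency of A, heterozygosity).

# unchecked scalar versions used in inner loops (WF simulator, ODE solvers)
.gamete_rhs <- function(g, p) {
  pA <- g[1L] + g[3L]
  pB <- g[1L] + g[2L]
  D <- g[1L] * g[4L] - g[2L] * g[3L]
  d1 <- -(p$mu_Abar + p$mu_Bbar) * g[1L] + p$mu_A * g[2L] + p$mu_B * g[3L] +
    p$s1 * g[1L] * (1 - pA) + p$s2 * g[1L] * (1 - pB) - p$r * D
  d2 <- -(p$mu_A + p$mu_Bbar) * g[2L] + p$mu_Abar * g[1L] + p$mu_B * g[4L] -
    p$s1 * g[2L] * pA + p$s2 * g[2L] * (1 - pB) + p$r * D
  d3 <- -(p$mu_Abar + p$mu_B) * g[3L] + p$mu_A * g[4L] + p$mu_Bbar * g[1L] +
    p$s1 * g[3L] * (1 - pA) - p$s2 * g[3L] * pB + p$r * D
  c(d1, d2, d3, -(d1 + d2 + d3))
}

.haplo_rhs <- function(x, p1, p2, p) {
  dlt <- p1 - p2
  dx <- ((p$s1 * dlt + p$s2) * x + p$mu_B) * (1 - x)
  dp1 <- -p$mu_Abar * p1 + p$mu_A * (1 - p1) + p$s1 * p1 * (1 - p1) -
    p$r * (1 - x) * dlt - p$mu_B * (1 - x) / x * dlt
  dp2 <- -p$mu_Abar * p2 + p$mu_A * (1 - p2) + p$s1 * p2 * (1 - p2) +
    p$r * x * dlt
  c(dx, dp1, dp2)
}

#' Rate of change of the gamete frequencies
#'
#' Right-hand side of the selection-mutation-recombination ODE system in
#' gamete coordinates. The per-gamete rates combine two-way mutation at the
#' first locus, one-way mutation `b -> B` at the second (back mutation is
#' excluded), additive selection through the marginal allele frequencies, and
#' recombination acting through the linkage disequilibrium
#' `D = x1 x4 - x2 x3`. The rate of `ab` is defined by conservation,
#' `dx4 = -(dx1 + dx2 + dx3)`, so the simplex constraint is exact.
#'
#' @param state A [gamete_freqs()] object (or a valid numeric vector of
#'   length 4).
#' @param params A [sweep_params()] object.
#' @return Named numeric vector `(dx1, dx2, dx3, dx4)` of per-generation
#'   rates of change.
#' @examples
#' p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
#' gamete_rhs(gamete_freqs(0.001, 0.004, 0.6, 0.395), p)
#' @seealso [haplo_rhs()] for the same dynamics in transformed coordinates.
#' @export
gamete_rhs <- function(state, params) {
  if (!inherits(state, "gamete_freqs"))
    state <- gamete_freqs(state[1L], state[2L], state[3L], state[4L])
  if (!all(is.finite(state)))
    stop("gamete frequencies must be finite")
  d <- .gamete_rhs(unclass(state), params)
  names(d) <- c("dx1", "dx2", "dx3", "dx4")
  d
}

#' Rate of change of the transformed coordinates
#'
#' Right-hand side of the dynamics in the haplotype-background coordinates
#' `(x, p1, p2)`. The beneficial allele obeys
#' `dx = ((s1 (p1 - p2) + s2) x + mu_B) (1 - x)`: it is driven by direct
#' selection, recurrent mutation, and selection at the linked locus acting
#' through linkage disequilibrium `D = x (1 - x) (p1 - p2)`. The system is
#' the exact image of [gamete_rhs()] under the coordinate change and is only
#' defined for `0 < x < 1`.
#'
#' @param state A [haplo_state()] object (or numeric vector `(x, p1, p2)`).
#' @param params A [sweep_params()] object.
#' @return Named numeric vector `(dx, dp1, dp2)`.
#' @examples
#' p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
#' haplo_rhs(haplo_state(0.5, 0.462, 0.7), p)
#' @export
haplo_rhs <- function(state, params) {
  if (!inherits(state, "haplo_state"))
    state <- haplo_state(state[1L], state[2L], state[3L])
  d <- .haplo_rhs(state[[1L]], state[[2L]], state[[3L]], params)
  names(d) <- c("dx", "dp1", "dp2")
  d
}

#' Convert between gamete frequencies and transformed coordinates
#'
#' `to_haplo()` maps gamete frequencies to `(x, p1, p2)` with
#' `x = x1 + x2`, `p1 = x1 / x`, `p2 = x3 / (1 - x)`; `to_gametes()` is its
#' inverse. The maps are mutually inverse on the valid domain `0 < x < 1`
#' and are rejected at the boundary, where the chart is singular.
#'
#' @param g A [gamete_freqs()] object.
#' @param h A [haplo_state()] object.
#' @return `to_haplo()` returns a [haplo_state()]; `to_gametes()` a
#'   [gamete_freqs()].
#' @examples
#' to_haplo(gamete_freqs(0.25, 0.25, 0.25, 0.25))
#' to_gametes(haplo_state(0.5, 0, 1))
#' @export
to_haplo <- function(g) {
  if (!inherits(g, "gamete_freqs"))
    g <- gamete_freqs(g[1L], g[2L], g[3L], g[4L])
  x <- g[[1L]] + g[[2L]]
  if (x <= .x_eps || x >= 1 - .x_eps)
    stop("x1 + x2 at the boundary {0, 1}: transformed coordinates are ",
         "undefined there")
  haplo_state(x, g[[1L]] / x, g[[3L]] / (1 - x))
}

#' @rdname to_haplo
#' @export
to_gametes <- function(h) {
  if (!inherits(h, "haplo_state"))
    h <- haplo_state(h[1L], h[2L], h[3L])
  x <- h[[1L]]; p1 <- h[[2L]]; p2 <- h[[3L]]
  gamete_freqs(p1 * x, (1 - p1) * x, p2 * (1 - x), (1 - p2) * (1 - x))
}

#' Linkage disequilibrium
#'
#' `D = x1 x4 - x2 x3`, the coupling measure through which recombination and
#' indirect selection act. In transformed coordinates
#' `D = x (1 - x) (p1 - p2)`.
#'
#' @param g A [gamete_freqs()] object.
#' @return The scalar `D`.
#' @examples
#' linkage_disequilibrium(gamete_freqs(0.5, 0, 0, 0.5)) # maximal coupling
#' @export
linkage_disequilibrium <- function(g) {
  if (!inherits(g, "gamete_freqs"))
    g <- gamete_freqs(g[1L], g[2L], g[3L], g[4L])
  g[[1L]] * g[[4L]] - g[[2L]] * g[[3L]]
}

#' Allele frequency and heterozygosity at the linked locus
#'
#' The frequency of allele `A` is `p = p1 x + p2 (1 - x)` and its
#' heterozygosity `H = 2 p (1 - p)`; the post-sweep reduction of `H` is the
#' hitchhiking signature of interest.
#'
#' @param h A [haplo_state()] object.
#' @return Named numeric vector `(p, H)`.
#' @examples
#' locus_A_summary(haplo_state(0.9, 0.02, 0.10))
#' @export
locus_A_summary <- function(h) {
  if (!inherits(h, "haplo_state"))
    h <- haplo_state(h[1L], h[2L], h[3L])
  p <- h[[2L]] * h[[1L]] + h[[3L]] * (1 - h[[1L]])
  c(p = p, H = 2 * p * (1 - p))
}
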