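# Random valid states and parameter sets for property-style tests.

random_gametes <- function(x_min = 0.01, x_max = 0.99) {
  repeat {
    v <- stats::runif(4)
    v <- v / sum(v)
    x <- v[1] + v[2]
    if (x > x_min && x < x_max)
      return(gamete_freqs(v[1], v[2], v[3], v[4]))
  }
}

random_params <- function() {
  sweep_params(s1 = stats::runif(1, -0.004, 0.004),
               s2 = stats::runif(1, 0.005, 0.05),
               r = stats::runif(1, 0, 0.01),
               mu_A = stats::runif(1, 0, 1e-4),
               mu_Abar = stats::runif(1, 0, 1e-4),
               mu_B = stats::runif(1, 0, 1e-3))
}

# time-derivative of (x, p1, p2) implied by the gamete-coordinate rates
pushforward_rates <- function(g, dg) {
  x <- g[[1]] + g[[2]]
  p1 <- g[[1]] / x
  p2 <- g[[3]] / (1 - x)
  dx <- dg[[1]] + dg[[2]]
  c(dx = dx,
    dp1 = (dg[[1]] - p1 * dx) / x,
    dp2 = (dg[[3]] + p2 * dx) / (1 - x))
}
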