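# Deterministic phase: numerical integration and closed-form solutions.

test_that("integrate_sweep reproduces the classical logistic sweep", {
  p <- sweep_params(s2 = 0.01)
  ic <- initial_conditions(x0 = 0.005, p10 = 0.3, p20 = 0.3)
  tr <- integrate_sweep(p, ic, stop_at_x = 0.995)
  logistic <- 0.005 / (0.005 + 0.995 * exp(-0.01 * tr$time))
  expect_lt(max(abs(tr$x - logistic)), 1e-8)
  # stopping time ~ tau_hat within 0.5%
  expect_equal(attr(tr, "stop_time"), sweep_duration(p, 0.005),
               tolerance = 0.005)
  # with no mutation/recombination/selection at A, backgrounds are frozen
  expect_lt(max(abs(tr$p1 - 0.3)), 1e-10)
  expect_error(integrate_sweep(p, ic, stop_at_x = 0.001), "stop_at_x")
})

test_that("incomplete sweeps raise a condition carrying the partial trajectory", {
  p <- sweep_params(s2 = 0.01)
  ic <- initial_conditions(x0 = 0.005, p10 = 0, p20 = 0)
  err <- tryCatch(
    integrate_sweep(p, ic, stop_at_x = 0.995, max_time = 50),
    sweep_incomplete = function(e) e)
  expect_s3_class(err, "sweep_incomplete")
  expect_s3_class(err$trajectory, "sweep_trajectory")
  expect_lt(max(err$trajectory$x), 0.995)
})

test_that("mutation-only closed form solves the dynamics exactly", {
  p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
  ic <- initial_conditions(x0 = 0.005, p10 = 0, p20 = 0.7)
  expect_equal(case1_constants(p, ic), 0.005 / 1.5e-4 * (-0.7),
               tolerance = 1e-12)
  cs <- case1_solution(0.5, p, ic)
  expect_equal(cs$p1_minus_p2, -23.33333333 * 0.0051 / 0.5, tolerance = 1e-8)
  expect_equal(cs$p1, 0.462, tolerance = 1e-3)

  # against adaptive integration of the full system
  tr <- integrate_sweep(p, ic, stop_at_x = 0.995, rtol = 1e-12, atol = 1e-14)
  cl <- case1_solution(tr$x, p, ic)
  expect_lt(max(abs(cl$p1_minus_p2 - (tr$p1 - tr$p2))), 1e-8)
  expect_lt(max(abs(cl$x1 - tr$x1)), 1e-8)

  # p10 = p20: constant AB/B ratio through the sweep
  ic_eq <- initial_conditions(x0 = 0.005, p10 = 0.7, p20 = 0.7)
  cs_eq <- case1_solution(c(0.05, 0.5, 0.95), p, ic_eq)
  expect_equal(cs_eq$x1 / cs_eq$x, rep(0.7, 3), tolerance = 1e-12)

  # no decay without mutation at the selected locus
  p_nomu <- sweep_params(s2 = 0.01, mu_B = 0)
  cs0 <- case1_solution(c(0.1, 0.9), p_nomu, ic)
  expect_equal(cs0$p1_minus_p2, rep(-0.7, 2), tolerance = 1e-12)

  expect_error(case1_solution(0.5, sweep_params(s2 = 0.01, r = 0.001), ic),
               "unsupported regime")
})

test_that("explicit x(t) under selection plus mutation matches quadrature", {
  p <- sweep_params(s2 = 0.01, mu_B = 1e-4)
  expect_equal(case1_x_of_t(0, p, 0.005), 0.005)
  # mu_B = 0 limit is the logistic
  p0 <- sweep_params(s2 = 0.01)
  tt <- c(0, 100, 500, 1200)
  expect_equal(case1_x_of_t(tt, p0, 0.005),
               0.005 / (0.005 + 0.995 * exp(-0.01 * tt)), tolerance = 1e-12)
  # against direct quadrature of the scalar ODE
  num <- deSolve::ode(c(x = 0.005), seq(0, 500, length.out = 11),
                      function(t, y, parms)
                        list((0.01 * y[1] + 1e-4) * (1 - y[1])),
                      NULL, rtol = 1e-12, atol = 1e-14)
  expect_lt(max(abs(case1_x_of_t(num[, "time"], p, 0.005) - num[, "x"])),
            1e-10)
  expect_true(all(diff(case1_x_of_t(seq(0, 2000, 10), p, 0.005)) > 0))
})

test_that("mutation-plus-recombination closed form: exact part and p2 approximation", {
  ic <- initial_conditions(x0 = 0.005, p10 = 0, p20 = 0.7)
  # r = 0 collapses to the mutation-only solution
  p_r0 <- sweep_params(s2 = 0.01, mu_B = 1e-4, r = 0)
  k <- case2_constants(p_r0, ic)
  expect_equal(k$rho, 0)
  expect_equal(k$C_tilde, case1_constants(p_r0, ic), tolerance = 1e-12)

  for (rho in c(1e-3, 1e-2)) {
    p <- sweep_params(s2 = 0.01, mu_B = 1e-4, r = rho * (0.01 + 1e-4))
    tr <- integrate_sweep(p, ic, stop_at_x = 0.995, rtol = 1e-12,
                          atol = 1e-14)
    cs <- case2_solution(tr$x, p, ic)
    # the p1 - p2 expression is exact
    expect_lt(max(abs(cs$p1_minus_p2 - (tr$p1 - tr$p2))), 1e-8)
    # p2 is approximate with O(rho) control
    expect_lt(max(abs(cs$p2_approx - tr$p2) / abs(tr$p2)), 5 * rho)
    # the retained constant makes the initial condition exact
    expect_equal(case2_solution(0.005, p, ic)$p2_approx, 0.7,
                 tolerance = 1e-14)
  }

  # identical backgrounds stay identical
  ic_eq <- initial_conditions(0.005, 0.7, 0.7)
  cs_eq <- case2_solution(c(0.1, 0.9), sweep_params(s2 = 0.01, mu_B = 1e-4,
                                                    r = 1e-4), ic_eq)
  expect_equal(cs_eq$p1_minus_p2, c(0, 0))
  expect_equal(cs_eq$p2_approx, c(0.7, 0.7))

  expect_error(case2_solution(0.5, sweep_params(s1 = -0.001, s2 = 0.01,
                                                mu_A = 1e-5, mu_B = 1e-4),
                              ic), "unsupported regime")
})

test_that("mutation-selection-balance closed form behaves at its anchors", {
  p <- sweep_params(s1 = -0.001, s2 = 0.05, r = 5e-4, mu_A = 1e-5)
  ic <- initial_conditions(x0 = 0.005, p10 = 0, p20 = 0.01)
  at0 <- case3_solution(0, p, ic)
  expect_equal(unname(unlist(at0[c("x", "p1_minus_p2", "p1", "p2")])),
               c(0.005, -0.01, 0, 0.01), tolerance = 1e-14)

  # without recombination and with vanishing selection at A, p1 stays ~0
  p_r0 <- sweep_params(s1 = -1e-9, s2 = 0.05, r = 0, mu_A = 1e-11)
  cs <- case3_solution(c(50, 200), p_r0,
                       initial_conditions(0.005, 0, 0.01))
  expect_lt(max(abs(cs$p1)), 1e-6)

  # the small-frequency linearization is the accurate part of the
  # approximation: against the linear ODE driven by the true logistic the
  # closed form's only remaining error is the (1 - x) ~ 1 replacement,
  # which vanishes at r = 0
  p_norec <- sweep_params(s1 = -0.001, s2 = 0.05, r = 0, mu_A = 1e-5)
  tau_hat <- sweep_duration(p_norec, 0.005)
  tr <- deSolve::ode(c(x = 0.005, p1 = 0, p2 = 0.01), c(0, tau_hat),
                     function(t, y, parms)
                       list(unname(haplo_rhs(haplo_state(y[1], y[2], y[3]),
                                             parms))),
                     p_norec, rtol = 1e-12, atol = 1e-14)
  cl <- case3_solution(tau_hat, p_norec, ic)
  expect_equal(cl$p1, unname(tr[2, "p1"]), tolerance = 0.01)
  # the closed-form x drops the small LD-mediated s1 term, so agreement is
  # to O(|s1| p20 / s2), not machine precision
  expect_equal(cl$x, unname(tr[2, "x"]), tolerance = 1e-4)

  expect_error(case3_solution(10, sweep_params(s2 = 0.05, mu_B = 1e-6), ic),
               "unsupported regime")
})

test_that("sweep duration formulas and scaling", {
  p <- sweep_params(s2 = 0.01)
  expect_equal(sweep_duration(p, 0.005), 200 * log(200), tolerance = 1e-12)
  expect_equal(sweep_duration(p, 0.005), 1059.66, tolerance = 1e-4)
  p2 <- sweep_params(s2 = 0.02)
  expect_equal(sweep_duration(p2, 0.005), sweep_duration(p, 0.005) / 2)
  # exact form lands the logistic exactly on 1 - x0
  tau_ex <- sweep_duration(p, 0.005, form = "exact")
  expect_equal(0.005 / (0.005 + 0.995 * exp(-0.01 * tau_ex)), 0.995,
               tolerance = 1e-12)
  # printed form lands within O(x0^2)
  tau_pr <- sweep_duration(p, 0.005)
  expect_equal(0.005 / (0.005 + 0.995 * exp(-0.01 * tau_pr)), 0.995,
               tolerance = 10 * 0.005^2)
  expect_error(sweep_duration(p, 0.6), "x0")
})

test_that("soft-sweep threshold parameter", {
  expect_equal(soft_sweep_threshold(sweep_params(s2 = 0.01, mu_B = 1e-6))$kappa,
               1e-4)
  expect_equal(soft_sweep_threshold(sweep_params(s2 = 0.01))$kappa, 0)
  st <- soft_sweep_threshold(sweep_params(s2 = 0.01, mu_B = 1e-6),
                             x0 = 5 / (2 * 1e4 * 0.01))
  expect_equal(st$x0, 0.025)
  expect_true(st$kappa_below_x0)
})

test_that("post-sweep heterozygosity ratio: closed form, numeric mode, monotonicity", {
  p <- sweep_params(s1 = -0.001, s2 = 0.01, mu_A = 1e-5)
  cf <- het_ratio_after_sweep(p, 0.005, mode = "closed_form")
  expect_equal(cf$H_ratio, 1 - 0.005^0.2, tolerance = 1e-10)
  expect_equal(cf$H_ratio, 0.6534, tolerance = 1e-3)

  nm <- het_ratio_after_sweep(p, 0.005, mode = "numeric")
  expect_equal(cf$H_ratio, nm$H_ratio, tolerance = 0.1)

  # neutral limits of the closed form
  pn <- sweep_params(s1 = 0, s2 = 0.01, r = 0.001)
  expect_equal(het_ratio_after_sweep(pn, 0.005, mode = "closed_form",
                                     p20 = 0.01)$H_ratio,
               1 - 0.005^(2 * 0.001 / 0.01), tolerance = 1e-10)
  pn0 <- sweep_params(s1 = 0, s2 = 0.01, r = 0)
  expect_equal(het_ratio_after_sweep(pn0, 0.005, mode = "closed_form",
                                     p20 = 0.01)$H_ratio, 0)

  # modes agree inside the regime (|s1|, r well below s2)
  for (r in c(0, 1e-4, 5e-4)) {
    pr <- sweep_params(s1 = -0.001, s2 = 0.01, r = r, mu_A = 1e-5)
    a <- het_ratio_after_sweep(pr, 0.005, mode = "closed_form")$H_ratio
    b <- het_ratio_after_sweep(pr, 0.005, mode = "numeric")$H_ratio
    expect_lt(abs(a - b) / b, 0.1)
  }

  # numeric ratio is monotone non-decreasing in r and approaches 1
  rs <- c(0, 1e-4, 1e-3, 3e-3, 1e-2)
  vals <- vapply(rs, function(r) het_ratio_after_sweep(
    sweep_params(s1 = -0.001, s2 = 0.01, r = r, mu_A = 1e-5),
    0.005, mode = "numeric")$H_ratio, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_gt(vals[length(vals)], 1 - 10 * 0.005)
  expect_true(all(vals >= 0 & vals <= 1 + 1e-6))

  expect_error(het_ratio_after_sweep(sweep_params(s2 = 0.01, mu_B = 1e-5),
                                     0.005), "unsupported regime")
  expect_error(het_ratio_after_sweep(pn0, 0.005), "p20")
  expect_warning(het_ratio_after_sweep(
    sweep_params(s1 = -0.001, s2 = 0.01, mu_A = 2e-4), 0.005), "p20")
})
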