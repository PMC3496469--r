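test_that("exponential moments behave as concentration measures", {
  par <- nnlif_params(b = 0.5)
  g <- nnlif_grid(par, vmin = -5, dv = 0.01)
  mu <- 3

  # near-Dirac at the threshold: moment approaches e^(mu VF)
  dirac <- maxwellian_density(g, v0 = par$VF - 0.01, sigma2 = 1e-6)
  expect_equal(exponential_moment(dirac, mu, log = TRUE), mu * par$VF,
               tolerance = 0.05)

  # any density is capped by e^(mu VF); mu -> 0 recovers the mass
  set.seed(3)
  for (i in 1:5) {
    d <- maxwellian_density(g, v0 = runif(1, -2, 1.5), sigma2 = runif(1, 0.02, 0.4))
    expect_lte(exponential_moment(d, mu, log = TRUE), mu * par$VF + 1e-12)
    expect_equal(exponential_moment(d, 1e-9), 1, tolerance = 1e-6)
  }
})

test_that("blow-up certificates match the concentration condition", {
  par05 <- nnlif_params(b = 0.5)
  g <- nnlif_grid(par05, vmin = -5, dv = 0.01)

  # concentrated near threshold: certified for some admissible mu
  c8 <- blowup_certificate(maxwellian_density(g, 1.83, 0.003), par05)
  expect_true(c8$applicable)
  expect_true(c8$certified)
  expect_gt(c8$mu, max(par05$VF / par05$a0, 1 / par05$b))
  expect_gte(c8$log_M, c8$log_lambda)

  # spread-out data: no admissible mu reaches the threshold
  c3 <- blowup_certificate(maxwellian_density(g, 0, 0.25), par05)
  expect_true(c3$applicable)
  expect_false(c3$certified)

  # moderately excitatory, concentrated: certified as well
  par15 <- nnlif_params(b = 1.5)
  g15 <- nnlif_grid(par15, vmin = -5, dv = 0.01)
  c7 <- blowup_certificate(maxwellian_density(g15, 1.5, 0.005), par15)
  expect_true(c7$certified)

  # inhibitory networks are outside the theorem's scope
  cneg <- blowup_certificate(maxwellian_density(g, 0, 0.25), nnlif_params(b = -1))
  expect_false(cneg$applicable)
  expect_false(cneg$certified)
})

test_that("moment threshold has the expected small-exponent expansion", {
  # lambda(mu) = (e^(mu VF) - e^(mu VR)) / (b mu) -> (VF - VR) e^(mu VR) / b
  # as mu (VF - VR) -> 0
  par <- nnlif_params(b = 0.7)
  for (mu in c(1e-3, 1e-4, 1e-5)) {
    lam <- exp(nnlifpd:::log_lambda_thresh(mu, par))
    lead <- (par$VF - par$VR) * exp(mu * par$VR) / par$b
    expect_equal(lam / lead, 1, tolerance = 10 * mu)
  }
})

test_that("a-priori moment bounds hold along coarse runs", {
  # weak coupling: b < VF - VR
  par <- nnlif_params(b = 0.5)
  g <- nnlif_grid(par, dv = 0.04, v0 = 0, sigma2 = 0.25)
  init <- maxwellian_density(g, 0, 0.25)
  res <- run_simulation(init, scheme_config(t_end = 6, steady_tol = 1e-12))
  rep_weak <- moment_bounds_report(res)
  expect_true(all(rep_weak$holds))
  expect_true(any(grepl(">= min", rep_weak$bound)))

  # strong coupling run to (near) steady state: upper bounds applicable
  par2 <- nnlif_params(b = 1.5)
  root <- find_steady_states(par2)$roots$N[1]
  g2 <- nnlif_grid(par2, dv = 0.04)
  init2 <- stationary_density(par2, g2, N = root)
  res2 <- run_simulation(init2, scheme_config(t_end = 4, steady_tol = 1e-12))
  rep_strong <- moment_bounds_report(res2)
  expect_true(all(rep_strong$holds))
  expect_true(any(grepl("<= max", rep_strong$bound)))

  # stationary data: moments essentially constant in time
  m1 <- res2$trace$m1
  expect_lt(max(abs(m1 - m1[1])), 0.02)

  # post-hoc checks refuse abnormal runs
  pre <- nnlif_preset("fig7", dv = 0.02)
  resb <- run_simulation(pre$init, pre$config)
  expect_error(moment_bounds_report(resb), "normal")
})

test_that("relative entropy decays monotonically for the uncoupled model", {
  par <- nnlif_params(b = 0)
  g <- nnlif_grid(par, vmin = -6, dv = 0.04)
  init <- maxwellian_density(g, 0, 0.25)
  # entropy is measured against the exact equilibrium, so the scheme whose
  # discrete equilibrium matches it to high order is the right instrument
  cfg <- scheme_config(scheme = "chang_cooper", t_end = 8, steady_tol = 1e-13)
  res <- run_simulation(init, cfg, track_entropy = TRUE)
  ent <- relative_entropy_trace(res)
  expect_true(ent$monotone_ok)
  expect_gt(ent$fitted_rate, 0)
  expect_lt(ent$trace$H[nrow(ent$trace)], ent$trace$H[1])

  # starting at the equilibrium the entropy is numerically zero throughout
  pinf <- stationary_density(par, g)
  res0 <- run_simulation(pinf, scheme_config(scheme = "chang_cooper",
                                             t_end = 1, steady_tol = 1e-13),
                         track_entropy = TRUE)
  expect_lt(max(res0$trace$entropy), 1e-8)

  # entropy decay is a linear-case statement only
  expect_error(relative_entropy_trace(res, params = nnlif_params(b = 0.5)),
               "uncoupled")
})
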