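test_that("single-integral form of I(N) matches nested double quadrature", {
  set.seed(42)
  for (i in 1:20) {
    par <- nnlif_params(b = runif(1, -2, 2.5), a0 = runif(1, 0.4, 2),
                        a1 = sample(c(0, runif(1, 0, 0.3)), 1),
                        VR = runif(1, 0.2, 1.2), VF = runif(1, 1.6, 2.6))
    N <- runif(1, 0, 3)
    expect_equal(steady_state_integral(N, par), oracle_I_nested(N, par),
                 tolerance = 1e-8)
  }
})

test_that("uncoupled model has an N-independent integral", {
  par <- nnlif_params(b = 0, a0 = 1.3)
  vals <- steady_state_integral(c(0, 0.5, 2, 10), par)
  expect_equal(vals, rep(vals[1], 4), tolerance = 1e-12)
})

test_that("I(N) is monotone: decreasing for excitation, increasing for inhibition", {
  Ns <- c(0, 0.2, 0.5, 1, 2, 5, 10)
  I_exc <- steady_state_integral(Ns, nnlif_params(b = 1.5))
  expect_true(all(diff(I_exc) < 0))
  I_inh <- steady_state_integral(Ns, nnlif_params(b = -1.5), log = TRUE)
  expect_true(all(diff(I_inh) > 0))
  # rate-modulated diffusion keeps I decreasing for b > 0
  I_a1 <- steady_state_integral(Ns, nnlif_params(b = 0.5, a0 = 0.5, a1 = 1 / 8))
  expect_true(all(diff(I_a1) < 0))
  I_a1b <- steady_state_integral(Ns, nnlif_params(b = 1.2, a0 = 0.4, a1 = 0.01))
  expect_true(all(diff(I_a1b) < 0))
})

test_that("N*I(N) approaches (VF-VR)/b for strong rates", {
  for (b in c(0.5, 1.5, 3)) {
    par <- nnlif_params(b = b)
    N <- 200 * (par$VF - par$VR) / b
    NI <- exp(log(N) + steady_state_integral(N, par, log = TRUE))
    expect_equal(NI, (par$VF - par$VR) / b, tolerance = 0.01)
  }
  # same limit with firing-rate-dependent diffusion
  for (ab in list(c(0.5, 0.5, 1 / 8), c(1.2, 0.4, 0.01))) {
    par <- nnlif_params(b = ab[1], a0 = ab[2], a1 = ab[3])
    N <- 500 * (par$VF - par$VR) / par$b
    NI <- exp(log(N) + steady_state_integral(N, par, log = TRUE))
    expect_equal(NI, (par$VF - par$VR) / par$b, tolerance = 0.05)
  }
})

test_that("I(0) respects its closed-form upper bound", {
  for (a0 in c(0.5, 1, 2)) {
    par <- nnlif_params(b = 1, a0 = a0)
    bound <- sqrt(2 * pi) * (par$VF - par$VR) / sqrt(a0) *
      exp(max(par$VR^2, par$VF^2) / (2 * a0))
    expect_lt(steady_state_integral(0, par), bound)
  }
})

test_that("root finder reproduces the published root counts", {
  rs15 <- find_steady_states(nnlif_params(b = 1.5))
  expect_equal(nrow(rs15$roots), 2L)
  expect_true(all(diff(rs15$roots$N) > 0))
  expect_true(all(rs15$roots$N > 0))
  expect_true(all(abs(rs15$roots$residual) < 1e-9))

  rs05 <- suppressWarnings(find_steady_states(nnlif_params(b = 0.5)))
  expect_equal(nrow(rs05$roots), 1L)
  expect_equal(nrow(find_steady_states(nnlif_params(b = 3))$roots), 0L)
  expect_equal(nrow(find_steady_states(nnlif_params(b = -1.5))$roots), 1L)
})

test_that("roots satisfy the stationarity equation against the nested oracle", {
  for (b in c(1.5, -1.5)) {
    rs <- find_steady_states(nnlif_params(b = b))
    for (N in rs$roots$N)
      expect_equal(N * oracle_I_nested(N, nnlif_params(b = b)), 1,
                   tolerance = 1e-7)
  }
})

test_that("stationary density: linear case equals the normalised Dawson form", {
  par <- nnlif_params(b = 0)
  g <- nnlif_grid(par, vmin = -6, dv = 0.02)
  pinf <- stationary_density(par, g)
  expect_equal(grid_trapz(g, pinf$p), 1, tolerance = 1e-3)
  expect_lt(l1_dist(g, pinf$p, oracle_linear_equilibrium(g)), 1e-6)
})

test_that("stationary density at a root has unit mass without renormalisation", {
  par <- nnlif_params(b = 1.5)
  g <- nnlif_grid(par, dv = 0.005)
  roots <- find_steady_states(par)$roots$N
  for (N in roots) {
    d <- stationary_density(par, g, N = N)
    expect_equal(grid_trapz(g, d$p), 1, tolerance = 1e-4)
  }
})

test_that("stationary profile is continuous with slope jump N/a at reset", {
  par <- nnlif_params(b = 1.5)
  g <- nnlif_grid(par, dv = 0.002)
  N <- find_steady_states(par)$roots$N[1]
  d <- stationary_density(par, g, N = N)
  i <- g$iR
  # one-sided slopes around VR (second-order stencils)
  slope_left <- (3 * d$p[i] - 4 * d$p[i - 1] + d$p[i - 2]) / (2 * g$dv)
  slope_right <- (-3 * d$p[i] + 4 * d$p[i + 1] - d$p[i + 2]) / (2 * g$dv)
  a <- par$a0 + par$a1 * N
  expect_equal(slope_left - slope_right, N / a, tolerance = 1e-3)
  # continuity across the reset node
  expect_lt(abs(d$p[i + 1] - d$p[i - 1]), 10 * g$dv)
})

test_that("regime classification follows the sufficient conditions", {
  r05 <- classify_regime(nnlif_params(b = 0.5))
  expect_true(r05$exist_moderate)
  expect_equal(r05$classification, "existence-guaranteed")

  r15 <- classify_regime(nnlif_params(b = 1.5))
  expect_false(r15$exist_moderate)    # b > VF - VR
  expect_false(r15$exist_diffusion)   # 2*1*1.5 = 3 >= (VF-VR)^2 VR = 1
  expect_true(r15$exist_diffusion_refined)  # 3 < sqrt(2 pi) + 1
  expect_true(r15$two_states)
  expect_equal(r15$classification, "two-guaranteed")

  expect_equal(classify_regime(nnlif_params(b = -1))$classification, "unique")
  expect_equal(classify_regime(nnlif_params(b = 0))$classification, "unique")

  # high connectivity: b beyond max(2(VF-VR), 2 VF I(0)) rules steady states out
  I0 <- steady_state_integral(0, nnlif_params(b = 1))
  rhi <- classify_regime(nnlif_params(b = 2 * 2 * I0 * 1.05))
  expect_true(rhi$none_high_conn)
  expect_equal(rhi$classification, "nonexistence-guaranteed")
  expect_equal(nrow(find_steady_states(nnlif_params(b = 2 * 2 * I0 * 1.05),
                                       N_max = 500)$roots), 0L)

  # existence and non-existence are never asserted together
  set.seed(7)
  for (i in 1:20) {
    r <- classify_regime(nnlif_params(b = runif(1, -3, 40),
                                      a0 = runif(1, 0.3, 2)))
    exists_any <- r$exist_moderate || r$exist_diffusion ||
      r$exist_diffusion_refined || r$exist_a1
    expect_false(exists_any && r$none_high_conn)
  }
})
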