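# Unit tests of the explicit solver on deliberately coarse grids; the
# published-resolution checks live in test-acceptance.R.

make_state <- function(par, dv = 0.05, v0 = 0, s2 = 0.25, vmin = NULL) {
  g <- nnlif_grid(par, vmin = vmin, dv = dv, v0 = v0, sigma2 = s2)
  maxwellian_density(g, v0, s2)
}

test_that("firing rate read-off solves the implicit boundary relation", {
  par <- nnlif_params(b = 0.5)
  g <- nnlif_grid(par, vmin = -5, dv = 0.02)
  # no density near threshold -> zero rate
  d0 <- maxwellian_density(g, v0 = -2, sigma2 = 0.1)
  expect_equal(d0$N, 0)

  # linear read-off N = a0 * q for constant diffusion: impose a known slope
  q_target <- 0.35
  p <- pmax((par$VF - g$v) * q_target, 0)
  p <- p * pmin(1, pmax(0, (g$v - g$vmin) / 2))  # taper to 0 at vmin
  p[1] <- 0; p[g$J] <- 0
  st <- list(grid = g, p = p / grid_trapz(g, p), t = 0, N = 0)
  class(st) <- "nnlif_density"
  scale <- 1 / grid_trapz(g, p)
  expect_equal(firing_rate_from_density(st, par), par$a0 * q_target * scale,
               tolerance = 1e-10)

  # a1 > 0: closed form agrees with fixed-point iteration of N = (a0+a1 N) q
  par1 <- nnlif_params(b = 0.5, a0 = 1, a1 = 1)
  q <- par$a0 * q_target * scale  # the slope of st
  N_closed <- firing_rate_from_density(st, par1)
  N_iter <- 0
  for (k in 1:200) N_iter <- (par1$a0 + par1$a1 * N_iter) * q
  expect_equal(N_closed, N_iter, tolerance = 1e-10)

  # loss of the implicit solution raises the breakdown error
  steep <- pmax((par$VF - g$v) * 1.2, 0) * pmin(1, pmax(0, g$v - g$vmin))
  steep[1] <- 0; steep[g$J] <- 0
  st2 <- list(grid = g, p = steep, t = 0, N = 0)
  class(st2) <- "nnlif_density"
  expect_error(firing_rate_from_density(st2, par1),
               class = "nnlifpd_cc_breakdown")
})

test_that("a single step conserves mass to rounding for every scheme", {
  par <- nnlif_params(b = 1.5)
  init <- make_state(par)
  dt <- 1e-4
  for (stepper in list(step_upwind, step_chang_cooper, step_weno5)) {
    for (rk in c(2L, 3L)) {
      nxt <- stepper(init, dt, rk_order = rk)
      expect_equal(grid_trapz(nxt$grid, nxt$p), 1, tolerance = 1e-10)
      expect_equal(nxt$t, dt)
    }
  }
  expect_error(step_upwind(init, dt = 1), "CFL")
})

test_that("Chang-Cooper weight recovers centered and upwind limits", {
  expect_equal(chang_cooper_weight(1e-12), 0.5, tolerance = 1e-9)
  expect_equal(chang_cooper_weight(0.2) + chang_cooper_weight(-0.2), 1,
               tolerance = 1e-12)          # symmetry delta(w) + delta(-w) = 1
  expect_equal(chang_cooper_weight(60), 1 / 60, tolerance = 1e-10)
  expect_equal(chang_cooper_weight(-60), 1 - 1 / 60, tolerance = 1e-10)
})

test_that("stationary profiles are near-fixed points of the discretisation", {
  par <- nnlif_params(b = 0.5)
  root <- suppressWarnings(find_steady_states(par))$roots$N[1]
  g <- nnlif_grid(par, dv = 0.02)
  d0 <- stationary_density(par, g, N = root)
  cfg <- scheme_config(t_end = 1, steady_tol = 1e-12)  # run the full time unit
  for (sch in c("upwind1", "chang_cooper")) {
    cfg$scheme <- sch
    res <- run_simulation(d0, cfg)
    expect_equal(res$status, "reached_t_end")
    expect_lt(l1_dist(g, res$final$p, d0$p), 6e-3)
    expect_equal(res$final$N, root, tolerance = 0.02)
  }
})

test_that("uncoupled dynamics relax monotonically to the Dawson equilibrium", {
  par <- nnlif_params(b = 0)
  g <- nnlif_grid(par, vmin = -6, dv = 0.04)
  init <- maxwellian_density(g, v0 = 0, sigma2 = 0.25)
  pinf <- stationary_density(par, g)
  cfg <- scheme_config(scheme = "chang_cooper", t_end = 6,
                       snapshot_times = c(1, 2, 3, 4, 5), steady_tol = 1e-12)
  res <- run_simulation(init, cfg)
  dists <- vapply(res$snapshots, function(s) l1_dist(g, s$p, pinf$p), numeric(1))
  expect_true(all(diff(dists) < 0))
  expect_lt(l1_dist(g, res$final$p, pinf$p), 0.02)
  # mass stays put throughout
  expect_lt(max(abs(res$trace$mass - 1)), 1e-10)
})

test_that("positivity holds along coarse runs of all schemes", {
  par <- nnlif_params(b = 1.5)
  init <- make_state(par)
  for (sch in c("upwind1", "chang_cooper", "weno5")) {
    cfg <- scheme_config(scheme = sch, t_end = 2, steady_tol = 1e-12)
    res <- run_simulation(init, cfg)
    expect_gte(min(res$final$p), 0)
    expect_true(all(res$trace$N >= 0))
    if (sch != "weno5") expect_equal(res$clipped_mass, 0, tolerance = 1e-13)
  }
})

test_that("strong excitation with concentrated data blows up; statuses propagate", {
  # coarse version of the no-steady-state experiment
  par <- nnlif_params(b = 3)
  init <- make_state(par, dv = 0.04, v0 = -1, s2 = 0.5)
  res <- run_simulation(init, scheme_config(t_end = 10))
  expect_equal(res$status, "blowup")
  expect_lt(res$status_time, 10)
  # the rate reached the scale at which the exit layer is mesh-unresolvable
  expect_gte(max(res$trace$N, na.rm = TRUE),
             0.4 * par$a0 / (par$b * res$grid$dv))
  # mass is conserved right up to the abnormal exit
  expect_lt(max(abs(res$trace$mass - 1)), 1e-8 * max(res$trace$time))
})

test_that("a too-small domain is caught by the lower-cutoff guard", {
  par <- nnlif_params(b = 0)
  g <- suppressWarnings(nnlif_grid(par, vmin = -2.5, dv = 0.04))
  init <- suppressWarnings(maxwellian_density(g, v0 = 0, sigma2 = 0.5))
  res <- run_simulation(init, scheme_config(t_end = 10))
  expect_equal(res$status, "vmin_leak")
})

test_that("rate-modulated diffusion terminates via firing-relation breakdown", {
  par <- nnlif_params(b = 1.5, a0 = 1, a1 = 2)
  g <- nnlif_grid(par, vmin = -4, dv = 0.02)
  init <- maxwellian_density(g, v0 = 1.5, sigma2 = 0.005)
  res <- run_simulation(init, scheme_config(t_end = 10))
  expect_true(res$status %in% c("cc_breakdown", "blowup"))
})

test_that("runs are deterministic", {
  pre <- nnlif_preset("fig3", dv = 0.05)
  r1 <- run_simulation(pre$init, pre$config)
  r2 <- run_simulation(pre$init, pre$config)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$final$p, r2$final$p)
})
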