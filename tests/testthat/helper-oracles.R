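# Independent oracles used across the tests.  These deliberately avoid the
# code paths they check: the nested double quadrature below evaluates the
# steady-state integral from its raw two-variable form, while the package
# uses the reduced single-integral form.

# I(N) by brute-force nested quadrature of
#   int_{-inf}^{wF} e^{-z^2/2} int_{max(z,wR)}^{wF} e^{u^2/2} du dz
oracle_I_nested <- function(N, params) {
  a <- params$a0 + params$a1 * N
  V0 <- params$b * N
  wF <- (params$VF - V0) / sqrt(a)
  wR <- (params$VR - V0) / sqrt(a)
  inner <- function(z) {
    vapply(z, function(zz) {
      lo <- max(zz, wR)
      if (lo >= wF) return(0)
      stats::integrate(function(u) exp(u^2 / 2 - zz^2 / 2), lo, wF,
                       rel.tol = 1e-11, abs.tol = 1e-300)$value
    }, numeric(1))
  }
  # split the outer integral at the kink of the inner lower limit (z = wR)
  stats::integrate(inner, -Inf, wR, rel.tol = 1e-10, abs.tol = 1e-300)$value +
    stats::integrate(inner, wR, wF, rel.tol = 1e-10, abs.tol = 1e-300)$value
}

# linear-case equilibrium by direct pointwise quadrature and normalisation,
# independent of stationary_density()
oracle_linear_equilibrium <- function(grid, a0 = grid$params$a0) {
  VR <- grid$params$VR; VF <- grid$params$VF
  raw <- vapply(grid$v, function(v) {
    lo <- max(v, VR)
    if (lo >= VF) return(0)
    exp(-v^2 / (2 * a0)) *
      stats::integrate(function(w) exp(w^2 / (2 * a0)), lo, VF,
                       rel.tol = 1e-10)$value
  }, numeric(1))
  raw / grid_trapz(grid, raw)
}

# L1 distance between two nodal functions on a common grid
l1_dist <- function(grid, f, g) grid_trapz(grid, abs(f - g))

base_params <- function(b, a0 = 1, a1 = 0) nnlif_params(b = b, a0 = a0, a1 = a1)
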