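# Stationary firing rates: the integral I(N), root finding on N*I(N) = 1,
# stationary density profiles, and the sufficient-condition regime report.

# log of I(N) for a single N, overflow-safe.
#
# I(N) = int_0^inf e^{-s^2/2} (e^{s wF} - e^{s wR}) / s ds, with
# wF = (VF - bN)/sqrt(a), wR = (VR - bN)/sqrt(a), a = a0 + a1 N.
# The integrand has a removable singularity at s = 0 (limit wF - wR) and a
# log-peak of wF^2/2 when wF > 0, which is factored out so the quadrature
# works on an O(1) integrand.
log_I_one <- function(N, params) {
  a <- params$a0 + params$a1 * N
  V0 <- params$b * N
  wF <- (params$VF - V0) / sqrt(a)
  wR <- (params$VR - V0) / sqrt(a)
  if (wF < -0.5) {
    # strongly negative scaled threshold (large b*N): the integrand is a
    # boundary layer of width 1/|wF| at the origin; substitute u = s*|wF|
    # so it becomes O(1)-scaled:  I = int_0^inf e^{-u^2/(2 wF^2)}
    # (e^{-u} - e^{-r u})/u du with r = wR/wF >= 1
    r <- wR / wF
    f <- function(u) {
      out <- numeric(length(u))
      small <- u < 1e-12
      if (any(small)) out[small] <- r - 1
      ub <- u[!small]
      out[!small] <- exp(-ub^2 / (2 * wF^2)) * (exp(-ub) - exp(-r * ub)) / ub
      out
    }
    val <- integrate(f, 0, 60, rel.tol = 1e-12, abs.tol = 1e-300,
                     subdivisions = 400L)$value
    return(log(val))
  }
  m <- if (wF > 0) wF^2 / 2 else 0
  f <- function(s) {
    out <- numeric(length(s))
    small <- s < 1e-12
    if (any(small)) out[small] <- (wF - wR) * exp(-m)
    sb <- s[!small]
    out[!small] <- (exp(-sb^2 / 2 + sb * wF - m) -
                    exp(-sb^2 / 2 + sb * wR - m)) / sb
    out
  }
  # beyond max(wF,0) + 15 the integrand is ~e^{-112} of its peak; split at
  # the peak so the adaptive rule always sees its structure
  upper <- max(wF, 0) + 15
  pts <- sort(unique(pmin(pmax(c(0, wF / 2, wF, upper), 0), upper)))
  val <- 0
  for (i in seq_len(length(pts) - 1L))
    val <- val + integrate(f, pts[i], pts[i + 1], rel.tol = 1e-12,
                           abs.tol = 1e-300, subdivisions = 400L)$value
  m + log(val)
}

#' The steady-state integral I(N)
#'
#' A stationary state of the population-density equation has constant firing
#' rate `N` solving the implicit relation `N * I(N) = 1`, where `I(N)` is a
#' Gaussian-weighted integral of the scaled distance between threshold and
#' reset.  This function evaluates `I(N)` by adaptive quadrature of its
#' single-integral form, with the removable singularity at the origin
#' replaced by its limit and the exponentials fused to avoid overflow.
#'
#' @param N Firing rate(s), non-negative (vectorised).
#' @param params An [nnlif_params()] object.
#' @param log If `TRUE` return `log I(N)` (useful for large arguments where
#'   `I(N)` overflows double precision).
#' @return `I(N)` (or its logarithm), finite and positive.
#' @examples
#' steady_state_integral(0, nnlif_params(b = 0.5))
#' @export
steady_state_integral <- function(N, params, log = FALSE) {
  stopifnot(inherits(params, "nnlif_params"), all(is.finite(N)), all(N >= 0))
  lv <- vapply(N, log_I_one, numeric(1), params = params)
  if (log) lv else exp(lv)
}

# N*I(N) - 1, computed as expm1(log N + log I) so huge I(N) only saturates
# the sign instead of overflowing
steady_residual <- function(N, params) {
  vapply(N, function(n) {
    if (n <= 0) return(-1)
    li <- log_I_one(n, params)
    if (!is.finite(li)) return(if (li > 0) Inf else -1)
    expm1(log(n) + li)
  }, numeric(1))
}

#' Find all stationary firing rates
#'
#' Scans `F(N) = N * I(N) - 1` on a log-spaced grid over `(0, N_max]`,
#' brackets every sign change, and refines each bracket with a bisection
#' root method until `|F| < 1e-9`.  Near-tangent brackets (a local maximum
#' of `F` within `1e-6` of zero without a sign change) are reported as
#' flagged roots.
#'
#' @param params An [nnlif_params()] object.
#' @param N_max Upper scan bound; defaults to `max(50, 20 (VF - VR)/b)` for
#'   excitatory coupling and 50 otherwise.
#' @param n_scan Number of scan points (default 400).
#' @return An object of class `nnlif_rootset` with a tibble of roots, the
#'   scan table, and scan-adequacy flags.  For `b > 0` a warning is issued
#'   when `N_max * I(N_max)` has not approached its large-`N` limit
#'   `(VF - VR)/b` within 5%.
#' @examples
#' find_steady_states(nnlif_params(b = 1.5))
#' @export
find_steady_states <- function(params, N_max = NULL, n_scan = 400L) {
  stopifnot(inherits(params, "nnlif_params"))
  b <- params$b; VF <- params$VF; VR <- params$VR
  if (is.null(N_max))
    N_max <- if (b > 0) max(50, 20 * (VF - VR) / b) else 50
  if (N_max <= 0) stop("`N_max` must be positive", call. = FALSE)

  Ns <- exp(seq(log(1e-4), log(N_max), length.out = n_scan))
  Fv <- steady_residual(Ns, params)

  roots <- numeric(0); resid <- numeric(0); flagged <- logical(0)
  sgn <- sign(Fv)
  for (i in seq_len(n_scan - 1L)) {
    if (is.na(sgn[i]) || is.na(sgn[i + 1])) next
    if (sgn[i] == 0) { roots <- c(roots, Ns[i]); resid <- c(resid, 0)
                       flagged <- c(flagged, FALSE); next }
    if (sgn[i] * sgn[i + 1] < 0) {
      r <- uniroot(function(n) steady_residual(n, params),
                   lower = Ns[i], upper = Ns[i + 1], tol = 1e-14)
      roots <- c(roots, r$root)
      resid <- c(resid, steady_residual(r$root, params))
      flagged <- c(flagged, FALSE)
    }
  }
  # near-tangent double roots: interior local maxima of F within 1e-6 of 0
  for (i in 2:(n_scan - 1L)) {
    if (Fv[i] < 0 && Fv[i] > -1e-6 && Fv[i] >= Fv[i - 1] && Fv[i] >= Fv[i + 1] &&
        (length(roots) == 0 || min(abs(roots - Ns[i])) > 1e-6)) {
      op <- optimize(function(n) steady_residual(n, params),
                     c(Ns[i - 1], Ns[i + 1]), maximum = TRUE, tol = 1e-12)
      if (op$objective > -1e-6 && op$objective < 0) {
        roots <- c(roots, op$maximum)
        resid <- c(resid, op$objective)
        flagged <- c(flagged, TRUE)
      }
    }
  }
  ord <- order(roots)
  roots <- roots[ord]; resid <- resid[ord]; flagged <- flagged[ord]

  asympt_ok <- TRUE
  if (b > 0) {
    lim <- (VF - VR) / b
    tail_val <- exp(log(N_max) + log_I_one(N_max, params))
    asympt_ok <- is.finite(tail_val) && abs(tail_val / lim - 1) < 0.05
    if (!asympt_ok)
      warning(sprintf(paste0("N_max * I(N_max) = %.4g is not within 5%% of its ",
                             "limit (VF-VR)/b = %.4g; the scan bound may be ",
                             "too small"), tail_val, lim), call. = FALSE)
  }
  structure(list(
    roots = tibble::tibble(N = roots, residual = resid, flagged = flagged),
    scan = tibble::tibble(N = Ns, F = Fv),
    params = params, N_max = N_max,
    F_positive_at_Nmax = is.finite(Fv[n_scan]) && Fv[n_scan] > 0,
    asympt_ok = asympt_ok), class = "nnlif_rootset")
}

#' @export
print.nnlif_rootset <- function(x, ...) {
  cat(sprintf("<nnlif_rootset> b = %g: %d stationary firing rate(s)\n",
              x$params$b, nrow(x$roots)))
  if (nrow(x$roots)) print(x$roots)
  invisible(x)
}

#' @export
tidy.nnlif_rootset <- function(x, ...) x$roots

#' @export
glance.nnlif_rootset <- function(x, ...) {
  tibble::tibble(b = x$params$b, n_roots = nrow(x$roots),
                 n_flagged = sum(x$roots$flagged), N_max = x$N_max,
                 asympt_ok = x$asympt_ok,
                 F_positive_at_Nmax = x$F_positive_at_Nmax)
}

#' Tabulate stationary firing rates over a connectivity range
#'
#' Runs [find_steady_states()] for each connectivity value and stacks the
#' roots into one table — the numerical bifurcation diagram of the model in
#' its single free parameter.
#'
#' @param b_values Connectivity values to scan.
#' @param a0,a1,VR,VF Remaining model parameters, as in [nnlif_params()].
#' @param ... Passed on to [find_steady_states()].
#' @return A tibble with columns `b`, `N`, `residual`, `flagged` (zero rows
#'   for values of `b` without steady states).
#' @examples
#' bifurcation_table(c(-1, 0.5, 1.5, 3))
#' @export
bifurcation_table <- function(b_values, a0 = 1, a1 = 0, VR = 1, VF = 2, ...) {
  out <- lapply(b_values, function(b) {
    rs <- suppressWarnings(
      find_steady_states(nnlif_params(b = b, a0 = a0, a1 = a1,
                                      VR = VR, VF = VF), ...))
    if (nrow(rs$roots) == 0) return(NULL)
    tibble::tibble(b = b, rs$roots)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- tibble::tibble(b = numeric(0), N = numeric(0),
                          residual = numeric(0), flagged = logical(0))
  out
}

#' Stationary density profile for a given firing rate
#'
#' Evaluates the closed-form stationary profile
#' `p(v) = N/a * exp(-(v - V0)^2 / (2a)) * int_{max(v, VR)}^{VF}
#' exp((w - V0)^2 / (2a)) dw` with `V0 = b N`, on the grid nodes.  The two
#' exponentials are fused inside the quadrature so the integrand never
#' overflows.  When `N` solves `N I(N) = 1` the profile has unit mass
#' without renormalisation; the profile is continuous with a derivative jump
#' of `N/a` at the reset voltage.
#'
#' For the uncoupled model (`b = 0`, `a1 = 0`) `N` may be omitted: the unique
#' equilibrium is returned with `N = 1/I(0)` as normalising constant (the
#' Dawson-type equilibrium of the linear equation).
#'
#' @param params An [nnlif_params()] object.
#' @param grid An [nnlif_grid()].
#' @param N Stationary firing rate, strictly positive (omit for `b = 0`).
#' @return An `nnlif_density` (not renormalised).
#' @examples
#' par <- nnlif_params(b = 0)
#' g <- nnlif_grid(par, vmin = -5, dv = 0.02)
#' pinf <- stationary_density(par, g)
#' @export
stationary_density <- function(params, grid, N = NULL) {
  stopifnot(inherits(params, "nnlif_params"), inherits(grid, "nnlif_grid"))
  if (is.null(N)) {
    if (params$b != 0)
      stop("`N` may only be omitted in the uncoupled case b = 0", call. = FALSE)
    N <- 1 / exp(log_I_one(0, params))
  }
  if (!is.numeric(N) || length(N) != 1L || N <= 0)
    stop("`N` must be a single positive firing rate", call. = FALSE)
  a <- params$a0 + params$a1 * N
  V0 <- params$b * N
  VR <- params$VR; VF <- params$VF
  p <- vapply(grid$v, function(v) {
    lo <- max(v, VR)
    if (lo >= VF) return(0)
    val <- integrate(function(w) exp(((w - V0)^2 - (v - V0)^2) / (2 * a)),
                     lo, VF, rel.tol = 1e-10, abs.tol = 1e-300,
                     subdivisions = 400L)$value
    N / a * val
  }, numeric(1))
  p[grid$J] <- 0
  p[1] <- 0    # decay condition at the numerical lower cutoff
  density_state(grid, p, t = 0)
}

#' Classify the steady-state regime from the sufficient conditions
#'
#' Evaluates each sufficient condition on the parameters: existence for
#' moderate excitation (`0 < b < VF - VR`), existence via the diffusion bound
#' (`2 a0 b < (VF - VR)^2 VR`) and its refined variant
#' (`2 a0 b < VR (VF - VR) (sqrt(2 pi a0) + VF - VR)`), guaranteed
#' coexistence of two states when a diffusion-bound condition holds together
#' with `b > VF - VR`, and guaranteed non-existence under high connectivity
#' (`b > max(2 (VF - VR), 2 VF I(0))`), with `I(0)` computed by quadrature.
#' For `a1 > 0` the analogous conditions with the extra `2 a1 VR` term are
#' evaluated.  For `b <= 0` the steady state is unique.
#'
#' These conditions are sufficient only: parameters may support steady
#' states (found numerically by [find_steady_states()]) while every flag is
#' inconclusive.
#'
#' @param params An [nnlif_params()] object.
#' @return An object of class `nnlif_regime` with the individual flags, the
#'   value `I(0)`, and a `classification` string, one of `"unique"`,
#'   `"existence-guaranteed"`, `"two-guaranteed"`,
#'   `"nonexistence-guaranteed"`, `"inconclusive"`.
#' @examples
#' classify_regime(nnlif_params(b = 1.5))
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "nnlif_params"))
  b <- params$b; a0 <- params$a0; a1 <- params$a1
  VR <- params$VR; VF <- params$VF
  I0 <- exp(log_I_one(0, params))
  gap <- VF - VR

  exist_moderate <- b > 0 && b < gap
  exist_diffusion <- b > 0 && 2 * a0 * b < gap^2 * VR
  exist_diffusion_refined <- b > 0 &&
    2 * a0 * b < VR * gap * (sqrt(2 * pi * a0) + gap)
  none_high_conn <- b > max(2 * gap, 2 * VF * I0)
  two_states <- (exist_diffusion || exist_diffusion_refined) && b > gap

  # analogues for firing-rate-dependent diffusion
  exist_a1 <- a1 > 0 && b > 0 &&
    (b < gap || 2 * a0 * b + 2 * a1 * VR < gap^2 * VR)
  two_a1 <- a1 > 0 && 2 * a0 * b + 2 * a1 * VR < gap^2 * VR && b > gap

  classification <-
    if (b <= 0) "unique"
    else if (none_high_conn) "nonexistence-guaranteed"
    else if (two_states || two_a1) "two-guaranteed"
    else if (exist_moderate || exist_diffusion || exist_diffusion_refined ||
             exist_a1) "existence-guaranteed"
    else "inconclusive"

  structure(list(
    params = params, I0 = I0,
    exist_moderate = exist_moderate,
    exist_diffusion = exist_diffusion,
    exist_diffusion_refined = exist_diffusion_refined,
    two_states = two_states,
    none_high_conn = none_high_conn,
    exist_a1 = exist_a1, two_a1 = two_a1,
    classification = classification), class = "nnlif_regime")
}

#' @export
print.nnlif_regime <- function(x, ...) {
  cat(sprintf("<nnlif_regime> b = %g, a0 = %g, a1 = %g: %s\n",
              x$params$b, x$params$a0, x$params$a1, x$classification))
  cat(sprintf("  I(0) = %.6g\n", x$I0))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.nnlif_regime <- function(x, ...) {
  tibble::tibble(
    condition = c("0 < b < VF-VR", "2 a0 b < (VF-VR)^2 VR",
                  "2 a0 b < VR (VF-VR)(sqrt(2 pi a0)+VF-VR)",
                  "two states (diffusion bound & b > VF-VR)",
                  "b > max(2(VF-VR), 2 VF I(0))",
                  "a1 > 0 existence analogue", "a1 > 0 two-state analogue"),
    implies = c("existence", "existence", "existence", "two states",
                "non-existence", "existence", "two states"),
    holds = c(x$exist_moderate, x$exist_diffusion, x$exist_diffusion_refined,
              x$two_states, x$none_high_conn, x$exist_a1, x$two_a1))
}
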