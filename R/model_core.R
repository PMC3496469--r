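# Model parameters, voltage grids, coefficient functions and initial densities.

#' Model parameters of the NNLIF population-density equation
#'
#' The membrane-voltage density `p(v, t)` of a recurrently coupled
#' integrate-and-fire population obeys a Fokker-Planck equation with drift
#' `h(v, N) = b N - v` and diffusion `a(N) = a0 + a1 N`, where `N(t)` is the
#' network's mean firing rate, defined as the probability flux through the
#' firing threshold `VF`.  Neurons that fire are reset to `VR`, which enters
#' the equation as a point source.
#'
#' @param b Connectivity parameter (dimensionless voltage units).  `b > 0`
#'   describes an average-excitatory network, `b < 0` average-inhibitory,
#'   `b = 0` the uncoupled (linear) model.
#' @param a0 Baseline diffusion coefficient, strictly positive.
#' @param a1 Firing-rate gain of the diffusion coefficient, non-negative.
#' @param VR Reset voltage.
#' @param VF Firing (threshold) voltage; must exceed `VR`.
#'
#' @return An object of class `nnlif_params`.
#' @examples
#' nnlif_params(b = 1.5)
#' @export
nnlif_params <- function(b = 0, a0 = 1, a1 = 0, VR = 1, VF = 2) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(a0), length(a0) == 1L, is.finite(a0),
            is.numeric(a1), length(a1) == 1L, is.finite(a1),
            is.numeric(VR), length(VR) == 1L, is.finite(VR),
            is.numeric(VF), length(VF) == 1L, is.finite(VF))
  if (a0 <= 0) stop("`a0` must be strictly positive", call. = FALSE)
  if (a1 < 0) stop("`a1` must be non-negative", call. = FALSE)
  if (VR >= VF) stop("`VR` must be strictly below `VF`", call. = FALSE)
  structure(list(b = b, a0 = a0, a1 = a1, VR = VR, VF = VF),
            class = "nnlif_params")
}

#' @export
print.nnlif_params <- function(x, ...) {
  cat("<nnlif_params>  h(v,N) = b*N - v,  a(N) = a0 + a1*N\n")
  cat(sprintf("  b = %g, a0 = %g, a1 = %g, VR = %g, VF = %g\n",
              x$b, x$a0, x$a1, x$VR, x$VF))
  invisible(x)
}

#' Drift and diffusion coefficients
#'
#' `drift_coef()` evaluates the drift `h(v, N) = b N - v` (leak towards zero
#' plus recurrent input proportional to the firing rate); `diffusion_coef()`
#' evaluates `a(N) = a0 + a1 N`.
#'
#' @param v Voltage (vectorised).
#' @param N Firing rate, non-negative.
#' @param params An [nnlif_params()] object.
#' @return Numeric vector of drift velocities / the diffusion coefficient.
#' @examples
#' p <- nnlif_params(b = 1.5)
#' drift_coef(1, 2, p)
#' @export
drift_coef <- function(v, N, params) {
  stopifnot(inherits(params, "nnlif_params"), all(N >= 0))
  params$b * N - v
}

#' @rdname drift_coef
#' @export
diffusion_coef <- function(N, params) {
  stopifnot(inherits(params, "nnlif_params"), all(N >= 0))
  params$a0 + params$a1 * N
}

#' Uniform voltage grid with the reset and threshold voltages on nodes
#'
#' Builds a uniform mesh on `[vmin, VF]`.  The reset voltage must fall exactly
#' on a node for the reset source to be deposited conservatively, so the
#' spacing is taken as `(VF - VR) / k` for the integer `k` closest from above
#' to the requested resolution, and the lower end is extended downwards (by
#' less than one spacing) until it covers the requested `vmin`.
#'
#' @param params An [nnlif_params()] object.
#' @param vmin Requested lower cutoff of the computational domain (the model
#'   lives on `(-Inf, VF]`; the cutoff must be low enough that the density is
#'   negligible there).  If `NULL`, a default of
#'   `min(v0 - 6*sqrt(sigma2), VR - 8*sqrt(a0))` is used, dropping the first
#'   term when `v0`/`sigma2` are not given.  (Eight standard deviations below
#'   the reset: equilibria are centred near `b*N`, typically below `VR`, so
#'   six deviations below `VR` can leave an equilibrium tail above the
#'   `vmin_leak` guard of [run_simulation()].)
#' @param J Requested number of nodes (at least 16).  Ignored when `dv` is
#'   given.
#' @param dv Requested node spacing (alternative to `J`).
#' @param v0,sigma2 Optional centre and variance of the initial density, used
#'   only for the default `vmin` rule.
#'
#' @return An object of class `nnlif_grid` with fields `v` (nodes), `dv`,
#'   `J`, `vmin`, `iR` (index of the reset node), and the parameters.
#' @examples
#' g <- nnlif_grid(nnlif_params(b = 0.5), vmin = -4, J = 601)
#' g$dv
#' @export
nnlif_grid <- function(params, vmin = NULL, J = NULL, dv = NULL,
                       v0 = NULL, sigma2 = NULL) {
  stopifnot(inherits(params, "nnlif_params"))
  VF <- params$VF; VR <- params$VR
  if (is.null(vmin)) {
    vmin <- VR - 8 * sqrt(params$a0)
    if (!is.null(v0) && !is.null(sigma2))
      vmin <- min(vmin, v0 - 6 * sqrt(sigma2))
  }
  if (vmin >= VR) stop("`vmin` must be strictly below `VR`", call. = FALSE)
  if (is.null(dv)) {
    if (is.null(J)) J <- 601L
    if (J < 16) stop("`J` must be at least 16 nodes", call. = FALSE)
    dv_req <- (VF - vmin) / (J - 1)
  } else {
    if (dv <= 0) stop("`dv` must be positive", call. = FALSE)
    dv_req <- dv
  }
  k <- max(1L, as.integer(ceiling((VF - VR) / dv_req - 1e-9)))
  dv_act <- (VF - VR) / k
  n <- as.integer(ceiling((VF - vmin) / dv_act - 1e-9))
  J_act <- n + 1L
  if (J_act < 16) stop("grid degenerate: fewer than 16 nodes", call. = FALSE)
  vmin_act <- VF - n * dv_act
  shifted <- abs(vmin_act - vmin) > 1e-12
  if (shifted)
    message(sprintf("grid lower end shifted from %g to %g to place VR on a node",
                    vmin, vmin_act))
  v <- vmin_act + dv_act * (0:n)
  v[J_act] <- VF                       # guard rounding on the last node
  structure(list(params = params, vmin = vmin_act, VF = VF, J = J_act,
                 dv = dv_act, v = v, iR = J_act - k, shifted = shifted),
            class = "nnlif_grid")
}

#' @export
print.nnlif_grid <- function(x, ...) {
  cat(sprintf("<nnlif_grid> [%g, %g], J = %d nodes, dv = %g, VR at node %d\n",
              x$vmin, x$VF, x$J, x$dv, x$iR))
  invisible(x)
}

#' Trapezoidal integral of a nodal function over the grid
#'
#' @param grid An [nnlif_grid()].
#' @param f Nodal values (length `grid$J`).
#' @return The trapezoidal quadrature of `f` over `[vmin, VF]`.
#' @export
grid_trapz <- function(grid, f) {
  stopifnot(inherits(grid, "nnlif_grid"), length(f) == grid$J)
  grid$dv * (sum(f) - 0.5 * (f[1] + f[grid$J]))
}

#' Density state on a voltage grid
#'
#' Wraps nodal density values into a validated state: non-negative, zero at
#' the threshold (absorbing boundary) and of unit trapezoidal mass.  The
#' current firing rate is read off the one-sided derivative at `VF` via
#' [firing_rate_from_density()].
#'
#' @param grid An [nnlif_grid()].
#' @param p Nodal density values.
#' @param t Time attached to the state.
#' @param normalize If `TRUE`, rescale `p` to unit trapezoidal mass.
#' @return An object of class `nnlif_density` with fields `grid`, `p`, `t`, `N`.
#' @export
density_state <- function(grid, p, t = 0, normalize = FALSE) {
  stopifnot(inherits(grid, "nnlif_grid"), length(p) == grid$J)
  if (any(p < 0)) stop("density values must be non-negative", call. = FALSE)
  if (p[grid$J] != 0)
    stop("density must vanish at the threshold node VF", call. = FALSE)
  if (normalize) {
    m <- grid_trapz(grid, p)
    if (m <= 0) stop("cannot normalise a zero density", call. = FALSE)
    p <- p / m
  }
  state <- structure(list(grid = grid, p = p, t = t, N = NA_real_),
                     class = "nnlif_density")
  state$N <- firing_rate_from_density(state)
  state
}

#' Gaussian (Maxwellian) initial density
#'
#' Evaluates a Gaussian profile with mean `v0` and variance `sigma2` on the
#' grid, forces the absorbing boundary value `p(VF) = 0`, and renormalises to
#' unit trapezoidal mass.  A warning is issued when more than 1% of the
#' untruncated Gaussian mass lies outside the computational domain.
#'
#' @param grid An [nnlif_grid()].
#' @param v0 Mean voltage of the profile.
#' @param sigma2 Variance, strictly positive.
#' @return An `nnlif_density`.
#' @examples
#' g <- nnlif_grid(nnlif_params(b = 0.5), vmin = -5, dv = 0.02)
#' d <- maxwellian_density(g, v0 = 0, sigma2 = 0.25)
#' grid_trapz(g, d$p)
#' @export
maxwellian_density <- function(grid, v0, sigma2) {
  stopifnot(inherits(grid, "nnlif_grid"))
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("`sigma2` must be strictly positive", call. = FALSE)
  sd0 <- sqrt(sigma2)
  outside <- pnorm(grid$vmin, v0, sd0) + pnorm(grid$VF, v0, sd0, lower.tail = FALSE)
  if (outside > 0.01)
    warning(sprintf(paste0("%.2f%% of the Gaussian mass lies outside ",
                           "[%g, %g]; enlarge the grid"),
                    100 * outside, grid$vmin, grid$VF), call. = FALSE)
  p <- dnorm(grid$v, v0, sd0)
  p[1] <- 0
  p[grid$J] <- 0
  density_state(grid, p, t = 0, normalize = TRUE)
}

#' @export
print.nnlif_density <- function(x, ...) {
  cat(sprintf("<nnlif_density> t = %g, N = %.6g, mass = %.12g, J = %d\n",
              x$t, x$N, grid_trapz(x$grid, x$p), x$grid$J))
  invisible(x)
}

#' @export
tidy.nnlif_density <- function(x, ...) {
  tibble::tibble(v = x$grid$v, p = x$p)
}
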