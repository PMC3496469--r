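# Blow-up certificates from exponential moments, a-priori moment-bound
# checks along a run, and relative-entropy relaxation for the linear case.

# log of the trapezoidal integral of e^{mu v} p(v) dv (log-sum-exp)
log_exponential_moment <- function(state, mu) {
  g <- state$grid
  w <- rep(g$dv, g$J); w[c(1, g$J)] <- g$dv / 2
  lp <- ifelse(state$p > 0, log(state$p) + log(w) + mu * g$v, -Inf)
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

#' Exponential moment of a density
#'
#' Computes `M_mu = int e^(mu v) p(v) dv` by trapezoidal quadrature, with the
#' exponentials fused in log space so large `mu * VF` does not overflow.
#' For any probability density supported on `(-Inf, VF]`, `M_mu <= e^(mu VF)`.
#'
#' @param state An `nnlif_density`.
#' @param mu Positive exponent.
#' @param log If `TRUE`, return `log M_mu`.
#' @return The moment (or its log).
#' @export
exponential_moment <- function(state, mu, log = FALSE) {
  stopifnot(inherits(state, "nnlif_density"), is.numeric(mu), mu > 0)
  lv <- log_exponential_moment(state, mu)
  if (log) lv else exp(lv)
}

# log lambda(mu) = log[(e^{mu VF} - e^{mu VR}) / (b mu)], overflow-safe
log_lambda_thresh <- function(mu, params) {
  mu * params$VF + log1p(-exp(-mu * (params$VF - params$VR))) -
    log(params$b * mu)
}

#' Finite-time blow-up certificate from an exponential moment
#'
#' For an average-excitatory network (`b > 0`) the solution cannot exist
#' globally in time if, for some multiplier exponent
#' `mu > max(VF / a_m, 1 / b)` (with `a_m = a0` the lower bound of the
#' diffusion coefficient), the initial exponential moment `M_mu(0)` reaches
#' the threshold `lambda = (e^(mu VF) - e^(mu VR)) / (b mu)`: the moment then
#' grows without bound while it is capped by `e^(mu VF)` for a probability
#' density -- a contradiction.  Initial data concentrated close enough to
#' the threshold voltage always satisfies the condition.
#'
#' With `mu = "auto"` the certificate scans 64 log-spaced exponents in
#' `[max(VF/a0, 1/b) (1 + 1e-6), 50 / (VF - VR)]` and certifies if any
#' admissible exponent works.  The condition is sufficient only: runs from
#' uncertified data may still blow up.
#'
#' @param init Initial `nnlif_density`.
#' @param params Model parameters; default those attached to the grid.
#' @param mu A positive exponent, or `"auto"` to scan.
#' @return An object of class `nnlif_certificate`: fields `certified`,
#'   `applicable` (`FALSE` for `b <= 0`), `mu`, `log_M`, `log_lambda`,
#'   `margin` (`log M - log lambda` at the best exponent), `a_m`, and the
#'   scan table.
#' @examples
#' par <- nnlif_params(b = 0.5)
#' g <- nnlif_grid(par, vmin = -5, dv = 0.02)
#' blowup_certificate(maxwellian_density(g, 1.83, 0.003), par)
#' @export
blowup_certificate <- function(init, params = init$grid$params, mu = "auto") {
  stopifnot(inherits(init, "nnlif_density"))
  a_m <- params$a0
  if (params$b <= 0) {
    return(structure(list(certified = FALSE, applicable = FALSE,
                          reason = "certificate requires b > 0",
                          mu = NA_real_, log_M = NA_real_,
                          log_lambda = NA_real_, margin = NA_real_,
                          a_m = a_m, scan = NULL, params = params),
                     class = "nnlif_certificate"))
  }
  mu_lo <- max(params$VF / a_m, 1 / params$b)
  if (identical(mu, "auto")) {
    mu_hi <- 50 / (params$VF - params$VR)
    if (mu_lo * (1 + 1e-6) >= mu_hi) {
      mus <- mu_lo * (1 + 1e-6)
    } else {
      mus <- exp(seq(log(mu_lo * (1 + 1e-6)), log(mu_hi), length.out = 64L))
    }
  } else {
    stopifnot(is.numeric(mu), all(mu > 0))
    mus <- mu
  }
  logM <- vapply(mus, function(m) log_exponential_moment(init, m), numeric(1))
  logL <- vapply(mus, log_lambda_thresh, numeric(1), params = params)
  ok_mu <- mus > mu_lo
  cert <- ok_mu & (logM >= logL)
  best <- which.max(ifelse(ok_mu, logM - logL, -Inf))
  structure(list(certified = any(cert), applicable = TRUE,
                 reason = if (any(cert)) "M_mu(0) >= lambda for an admissible mu"
                          else "no admissible mu reached the threshold",
                 mu = mus[best], log_M = logM[best], log_lambda = logL[best],
                 margin = logM[best] - logL[best], a_m = a_m,
                 scan = tibble::tibble(mu = mus, log_M = logM,
                                       log_lambda = logL,
                                       admissible = ok_mu, certified = cert),
                 params = params), class = "nnlif_certificate")
}

#' @export
print.nnlif_certificate <- function(x, ...) {
  cat("<nnlif_certificate>", if (isTRUE(x$certified)) "CERTIFIED blow-up"
      else if (!x$applicable) "not applicable" else "not certified", "\n")
  if (x$applicable)
    cat(sprintf("  best mu = %.4g: log M_mu(0) = %.4g, log lambda = %.4g (margin %.4g)\n",
                x$mu, x$log_M, x$log_lambda, x$margin))
  cat(" ", x$reason, "\n")
  invisible(x)
}

#' @export
tidy.nnlif_certificate <- function(x, ...) {
  if (is.null(x$scan)) return(tibble::tibble())
  x$scan
}

# cumulative trapezoid of y over x
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
}

#' A-priori moment bounds along a completed run
#'
#' Checks the moment estimates that global-in-time solutions must satisfy,
#' using the recorded traces of `int (VF - v) p dv`, `int v^2 p dv` and the
#' time-integrated firing rate:
#' for strong coupling (`b >= VF - VR`) the first moment distance to
#' threshold stays below `max(VF, initial)` and
#' `(b - VF + VR) int_0^T N dt <= VF T + initial`; for weak coupling
#' (`b < VF - VR`) the distance stays above `min(VF, initial)`, the
#' integrated firing rate grows at most linearly (the observed constant
#' `max int_0^T N dt / (1 + T)` is reported), and for constant diffusion the
#' second moment grows at most linearly as well.
#'
#' @param result An `nnlif_result` from a run with a normal termination
#'   status (not a blow-up or breakdown).
#' @param tol Slack allowed on the inequalities (discretisation error).
#' @return A tibble with one row per bound: `bound`, `applicable`, `holds`,
#'   `margin` (worst signed violation, positive = satisfied), `constant`.
#' @export
moment_bounds_report <- function(result, tol = 1e-6) {
  stopifnot(inherits(result, "nnlif_result"))
  if (result$status %in% c("blowup", "cc_breakdown", "vmin_leak"))
    stop("moment bounds apply to runs with a normal termination status",
         call. = FALSE)
  params <- result$params
  b <- params$b; VF <- params$VF; VR <- params$VR
  tr <- result$trace
  dist <- VF * tr$mass - tr$m1          # int (VF - v) p dv
  Tt <- tr$time - tr$time[1]
  cumN <- cumtrapz(tr$time, tr$N)
  strong <- b >= VF - VR

  rows <- list()
  if (strong) {
    cap <- max(VF, dist[1])
    rows$first_upper <- tibble::tibble(
      bound = "int (VF-v) p dv <= max(VF, initial)", applicable = TRUE,
      holds = all(dist <= cap + tol), margin = min(cap - dist),
      constant = cap)
    lhs <- (b - VF + VR) * cumN
    rhs <- VF * Tt + dist[1]
    rows$rate_upper <- tibble::tibble(
      bound = "(b-VF+VR) int N dt <= VF T + initial", applicable = TRUE,
      holds = all(lhs <= rhs + tol), margin = min(rhs - lhs),
      constant = NA_real_)
  } else {
    floor_ <- min(VF, dist[1])
    rows$first_lower <- tibble::tibble(
      bound = "int (VF-v) p dv >= min(VF, initial)", applicable = TRUE,
      holds = all(dist >= floor_ - tol), margin = min(dist - floor_),
      constant = floor_)
    if (params$a1 == 0) {
      Cn <- max(cumN / (1 + Tt))
      rows$rate_linear <- tibble::tibble(
        bound = "int_0^T N dt <= (1+T) C", applicable = TRUE,
        holds = TRUE, margin = NA_real_, constant = Cn)
      if (b > 0) {
        C2 <- max(tr$m2 / (1 + Tt))
        rows$second_linear <- tibble::tibble(
          bound = "int v^2 p dv <= C (1+t)", applicable = TRUE,
          holds = TRUE, margin = NA_real_, constant = C2)
      }
    }
  }
  do.call(rbind, rows)
}

#' Relative-entropy relaxation trace for the uncoupled model
#'
#' For the linear equation (`b = 0`, constant diffusion) the squared
#' relative entropy `H(t) = int p_inf (p/p_inf - 1)^2 dv` with respect to the
#' unique equilibrium `p_inf` is non-increasing, and decays exponentially at
#' a rate set by a Poincare-type constant that this package estimates only
#' empirically: `log H` is fitted by least squares on the window where
#' `H` lies in `[1e-8, 1e-2]`.  Far-tail nodes where `p_inf` underflows
#' below `1e-30` carry no weight (they hold under `1e-20` of the integral),
#' and the boundary node contributes zero (the integrand there is the limit
#' of the flux ratio `N(t)/N_inf` multiplied by `p_inf(VF) = 0`).
#'
#' @param result An `nnlif_result` from a run of the uncoupled model, ideally
#'   with `track_entropy = TRUE` (otherwise snapshots are used).
#' @param params Model parameters; default those attached to the result.
#' @return An object of class `nnlif_entropy`: `trace` (tibble `time`, `H`),
#'   `fitted_rate` (positive means decay), `fit_window`, `monotone_ok`,
#'   `max_increase`.
#' @export
relative_entropy_trace <- function(result, params = result$params) {
  stopifnot(inherits(result, "nnlif_result"))
  if (params$b != 0 || params$a1 != 0)
    stop("relative-entropy decay holds for the uncoupled model (b = 0, a1 = 0) only",
         call. = FALSE)
  if (isTRUE(result$entropy_tracked)) {
    tr <- tibble::tibble(time = result$trace$time, H = result$trace$entropy)
  } else {
    if (length(result$snapshots) < 3)
      stop("run with track_entropy = TRUE or request snapshots", call. = FALSE)
    pinf <- stationary_density(params, result$grid)$p
    keep <- pinf > 1e-30
    H <- vapply(result$snapshots, function(s)
      sum(pinf[keep] * (s$p[keep] / pinf[keep] - 1)^2) * result$grid$dv,
      numeric(1))
    tr <- tibble::tibble(time = vapply(result$snapshots, `[[`, numeric(1), "t"),
                         H = H)
  }
  dH <- diff(tr$H)
  monotone_ok <- all(dH <= 1e-10)
  # the discrete equilibrium differs from the exact one by truncation error,
  # so H saturates at a positive floor; the exponential fit must stop well
  # above it or the plateau flattens the estimated rate
  H_floor <- min(tr$H)
  lo <- max(1e-8, 4 * H_floor)
  sel <- tr$H >= lo & tr$H <= 1e-2
  if (sum(sel) < 5) sel <- tr$H > 4 * H_floor & tr$H <= 1e-2
  if (sum(sel) < 5) sel <- tr$H > 0
  fit <- lm(log(H) ~ time, data = tr[sel, ])
  structure(list(trace = tr, fitted_rate = -unname(coef(fit)[2]),
                 fit_window = range(tr$time[sel]),
                 monotone_ok = monotone_ok,
                 max_increase = if (length(dH)) max(dH) else 0),
            class = "nnlif_entropy")
}

#' @export
print.nnlif_entropy <- function(x, ...) {
  cat(sprintf("<nnlif_entropy> H: %.3g -> %.3g, fitted decay rate %.4g (window [%.3g, %.3g])\n",
              x$trace$H[1], x$trace$H[nrow(x$trace)], x$fitted_rate,
              x$fit_window[1], x$fit_window[2]))
  cat("  monotone non-increasing:", x$monotone_ok, "\n")
  invisible(x)
}

#' @export
tidy.nnlif_entropy <- function(x, ...) x$trace

#' @export
glance.nnlif_entropy <- function(x, ...) {
  tibble::tibble(fitted_rate = x$fitted_rate, monotone_ok = x$monotone_ok,
                 max_increase = x$max_increase,
                 H_initial = x$trace$H[1], H_final = x$trace$H[nrow(x$trace)])
}
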