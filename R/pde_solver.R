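# Explicit time stepping of the density equation: scheme configuration,
# firing-rate read-off, single steps and full runs (compiled core).

.scheme_codes <- c(upwind1 = 0L, weno5 = 1L, chang_cooper = 2L)
.status_names <- c("reached_t_end", "steady", "blowup", "cc_breakdown",
                   "vmin_leak", "max_steps")

#' Scheme configuration for the explicit solver
#'
#' @param scheme One of `"upwind1"` (first-order upwind advection, the
#'   default), `"weno5"` (fifth-order WENO reconstruction with global
#'   Lax-Friedrichs splitting), or `"chang_cooper"` (exponential-fitting flux
#'   discretisation that is exact on local Maxwellians).  Diffusion is always
#'   second-order centered.
#' @param cfl Courant fraction in `(0, 1]`; the time step is
#'   `cfl * min(dv / max|h|, dv^2 / (2 a))`, recomputed every step.  The
#'   default 0.5 guarantees positivity for the upwind and Chang-Cooper
#'   fluxes under forward-Euler stages (and hence under the SSP combinations).
#' @param rk_order Order of the TVD (SSP) Runge-Kutta stepper, 2 or 3.
#' @param t_end Final time.
#' @param snapshot_times Times at which full density snapshots are stored
#'   (the stepper lands on them exactly).
#' @param N_blowup Firing-rate threshold above which the run is declared to
#'   blow up (together with time-step collapse below `1e-12 * t_end`).
#'   Independently of this threshold, a run with `b > 0` is declared
#'   divergent as soon as `N b dv >= a(N)/2`: the exit boundary layer of
#'   width `a/(b N)` is then thinner than two mesh cells, past which the
#'   discretisation saturates at a spurious mesh-dependent plateau instead
#'   of diverging further.
#' @param steady_tol The run is declared steady when the L1 change of the
#'   density per unit time stays below this threshold ...
#' @param steady_window ... continuously for this many time units.
#' @param vmin_tol Guard on the density next to the lower cutoff; if exceeded
#'   the domain was too small and the run aborts with status `"vmin_leak"`.
#' @param max_steps Hard cap on the number of time steps.
#' @return An object of class `nnlif_config`.
#' @export
scheme_config <- function(scheme = c("upwind1", "weno5", "chang_cooper"),
                          cfl = 0.5, rk_order = 2L, t_end = 10,
                          snapshot_times = numeric(0), N_blowup = 1e3,
                          steady_tol = 1e-5, steady_window = 0.5,
                          vmin_tol = 1e-6, max_steps = 2e7) {
  scheme <- match.arg(scheme)
  stopifnot(cfl > 0, cfl <= 1, rk_order %in% c(2L, 3L), t_end > 0,
            N_blowup > 0, steady_tol > 0, steady_window > 0, vmin_tol > 0)
  structure(list(scheme = scheme, cfl = cfl, rk_order = as.integer(rk_order),
                 t_end = t_end, snapshot_times = sort(unique(snapshot_times)),
                 N_blowup = N_blowup, steady_tol = steady_tol,
                 steady_window = steady_window, vmin_tol = vmin_tol,
                 max_steps = max_steps), class = "nnlif_config")
}

#' Firing rate from the boundary flux of a density
#'
#' The mean firing rate is the probability flux through the threshold:
#' `N = a(N) * q` with `q = -dp/dv` at `VF`, evaluated with the second-order
#' one-sided stencil `q = (4 p_(J-1) - p_(J-2)) / (2 dv)` (the threshold node
#' itself is zero).  For `a(N) = a0 + a1 N` the implicit relation has the
#' unique closed-form solution `N = a0 q / (1 - a1 q)` as long as
#' `a1 q < 1`; when `a1 q >= 1` the relation loses its solution, which is the
#' blow-up mechanism of the rate-modulated-diffusion model, and an error of
#' class `nnlifpd_cc_breakdown` is raised.
#'
#' @param state An `nnlif_density`.
#' @param params Model parameters; defaults to those attached to the grid.
#' @return The firing rate, a non-negative scalar.
#' @export
firing_rate_from_density <- function(state, params = state$grid$params) {
  stopifnot(inherits(state, "nnlif_density") || is.list(state))
  g <- state$grid; p <- state$p
  if (p[g$J] != 0) stop("state must satisfy p(VF) = 0", call. = FALSE)
  q <- (4 * p[g$J - 1L] - p[g$J - 2L]) / (2 * g$dv)
  q <- max(q, 0)
  if (params$a1 > 0 && params$a1 * q >= 1)
    stop(structure(class = c("nnlifpd_cc_breakdown", "error", "condition"),
                   list(message = sprintf(
                     "implicit firing-rate relation has no solution: a1*q = %.4g >= 1",
                     params$a1 * q), call = sys.call(-1))))
  params$a0 * q / (1 - params$a1 * q)
}

# largest admissible explicit step for the current state
cfl_step <- function(state, params, cfl = 1) {
  g <- state$grid
  N <- state$N
  a <- params$a0 + params$a1 * N
  maxh <- max(abs(params$b * N - g$vmin), abs(params$b * N - g$VF))
  cfl * min(if (maxh > 0) g$dv / maxh else Inf, g$dv^2 / (2 * a))
}

step_one <- function(state, dt, scheme, rk_order = 2L,
                     params = state$grid$params) {
  stopifnot(inherits(state, "nnlif_density"), dt > 0)
  if (dt > cfl_step(state, params, cfl = 1) * (1 + 1e-12))
    stop("`dt` violates the explicit stability (CFL) bound", call. = FALSE)
  g <- state$grid
  out <- fp_step_cpp(state$p, g$vmin, g$dv, g$iR - 1L, params$b, params$a0,
                     params$a1, .scheme_codes[[scheme]], as.integer(rk_order),
                     dt)
  if (!out$ok)
    stop(structure(class = c("nnlifpd_cc_breakdown", "error", "condition"),
                   list(message = "scheme breakdown within the step",
                        call = sys.call(-1))))
  structure(list(grid = g, p = out$p, t = state$t + dt, N = out$N),
            class = "nnlif_density")
}

#' Advance a density by one explicit step
#'
#' One SSP Runge-Kutta step of the semi-discretisation
#' `dp/dt = -d_v[h p] + a d_vv p + N delta_(VR)`: advection by first-order
#' upwinding (`step_upwind()`) or by the Chang-Cooper exponential-fitting
#' flux (`step_chang_cooper()`), diffusion by centered differences, the
#' discrete threshold outflux re-deposited in full on the reset node (which
#' makes the step exactly mass-conservative), boundary values pinned to zero
#' after every stage, and the firing rate re-evaluated from each stage
#' density.  The step size must satisfy the explicit stability bound
#' `dt <= min(dv / max|h|, dv^2 / (2a))`.
#'
#' @param state An `nnlif_density`.
#' @param dt Time step.
#' @param rk_order SSP Runge-Kutta order (2 or 3).
#' @param params Model parameters; default those attached to the grid.
#' @return The advanced `nnlif_density`.
#' @export
step_upwind <- function(state, dt, rk_order = 2L, params = state$grid$params) {
  step_one(state, dt, "upwind1", rk_order, params)
}

#' @rdname step_upwind
#' @export
step_chang_cooper <- function(state, dt, rk_order = 2L,
                              params = state$grid$params) {
  step_one(state, dt, "chang_cooper", rk_order, params)
}

#' @rdname step_upwind
#' @export
step_weno5 <- function(state, dt, rk_order = 2L, params = state$grid$params) {
  step_one(state, dt, "weno5", rk_order, params)
}

#' Run a full simulation
#'
#' Advances the density from `init` with the configured scheme, recomputing
#' the admissible step every iteration, until the final time is reached or a
#' terminal condition fires: relaxation to a steady state (L1 change per
#' unit time below `steady_tol` for `steady_window` time units), firing-rate
#' blow-up (`N >= N_blowup` or time-step collapse), loss of the implicit
#' firing-rate solution / positivity failure of the Chang-Cooper flux
#' (`cc_breakdown`), or density leaking through the lower cutoff
#' (`vmin_leak`).
#'
#' @param init Initial `nnlif_density`.
#' @param config An [scheme_config()].
#' @param track_entropy If `TRUE` (only for the uncoupled model `b = 0`,
#'   `a1 = 0`), the squared relative entropy towards the equilibrium
#'   [stationary_density()] is recorded along the trace.
#' @return An object of class `nnlif_result` with fields `trace` (a tibble
#'   with columns `time`, `N`, `mass`, `m1`, `m2`, and `entropy` if tracked),
#'   `snapshots` (list of `nnlif_density`), `final`, `status`,
#'   `status_time`, `steps`, `clipped_mass`, plus the grid, parameters and
#'   configuration used.
#' @examples
#' par <- nnlif_params(b = 0.5)
#' g <- nnlif_grid(par, vmin = -5, dv = 0.05)
#' init <- maxwellian_density(g, 0, 0.25)
#' res <- run_simulation(init, scheme_config(t_end = 2))
#' glance(res)
#' @export
run_simulation <- function(init, config, track_entropy = FALSE) {
  stopifnot(inherits(init, "nnlif_density"), inherits(config, "nnlif_config"))
  g <- init$grid
  params <- g$params
  pinf <- NULL
  if (track_entropy) {
    if (params$b != 0 || params$a1 != 0)
      stop("entropy tracking applies to the uncoupled model (b = 0, a1 = 0) only",
           call. = FALSE)
    pinf <- stationary_density(params, g)$p
  }
  out <- fp_run_cpp(init$p, init$t, g$vmin, g$dv, g$iR - 1L,
                    params$b, params$a0, params$a1,
                    .scheme_codes[[config$scheme]], config$rk_order,
                    config$cfl, config$t_end, config$snapshot_times,
                    config$N_blowup, config$steady_tol, config$steady_window,
                    config$vmin_tol, pinf, config$max_steps)
  trace <- tibble::tibble(time = out$trace$time, N = out$trace$N,
                          mass = out$trace$mass, m1 = out$trace$m1,
                          m2 = out$trace$m2)
  if (track_entropy) trace$entropy <- out$entropy
  snaps <- lapply(seq_along(out$snapshot_times), function(i) {
    structure(list(grid = g, p = out$snapshots[, i],
                   t = out$snapshot_times[i], N = NA_real_),
              class = "nnlif_density")
  })
  final <- structure(list(grid = g, p = out$p_final, t = out$t_final,
                          N = trace$N[nrow(trace)]), class = "nnlif_density")
  if (config$scheme == "chang_cooper" && params$a1 == 0 && params$b > 0 &&
      any(trace$N * params$b > params$VF, na.rm = TRUE))
    warning(paste("Chang-Cooper flux with constant diffusion and b*N beyond",
                  "the threshold: the local Maxwellian is nearly flat on the",
                  "domain and the scheme is outside its reliable regime"),
            call. = FALSE)
  structure(list(trace = trace, snapshots = snaps, final = final,
                 status = .status_names[out$status],
                 status_time = out$status_time, steps = out$steps,
                 clipped_mass = out$clipped_mass, grid = g, params = params,
                 config = config, entropy_tracked = track_entropy),
            class = "nnlif_result")
}

#' @export
print.nnlif_result <- function(x, ...) {
  cat(sprintf("<nnlif_result> %s at t = %.4g (%d trace rows, %g steps)\n",
              x$status, x$status_time, nrow(x$trace), x$steps))
  cat(sprintf("  terminal N = %.6g, terminal mass = %.10g\n",
              x$final$N, x$trace$mass[nrow(x$trace)]))
  invisible(x)
}

#' @export
tidy.nnlif_result <- function(x, ...) x$trace

#' @export
glance.nnlif_result <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(status = x$status, status_time = x$status_time,
                 steps = x$steps, N_final = x$trace$N[n],
                 mass_final = x$trace$mass[n],
                 mass_drift = max(abs(x$trace$mass - x$trace$mass[1])),
                 clipped_mass = x$clipped_mass)
}
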