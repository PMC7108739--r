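#' Explicit stability bound on the time step
#'
#' Minimum over (a) the diffusive bound `h^2 / (4 max(D_n, D_Bmax nu_max,
#' D_P))`, (b) the advective CFL bound `h / max |u|` for the chemotactic
#' drift velocity, and (c) optionally a reaction bound `1 / max local
#' linearized rate` (dominated by the adsorption loss, which reaches
#' `eta K_b ~ 8e3 h^-1` at default parameters), all multiplied by
#' `safety`.
#'
#' The production solver treats the stiff reaction terms with an adaptive
#' exponential per-cell integrator, so [run_simulation()] uses the
#' transport-only bound (`include_reaction = FALSE`); the reaction bound
#' is what a fully explicit scheme would require.
#'
#' @param p a [model_params()] object.
#' @param grid a [plate_grid()].
#' @param state a [field_state()].
#' @param safety multiplicative safety factor.
#' @param include_reaction include the explicit reaction-rate bound.
#' @return time step bound in hours.
#' @export
stable_dt <- function(p, grid, state, safety = 0.8,
                      include_reaction = TRUE) {
  q <- internal_params(p)
  msk <- grid$mask
  nu_max <- max(motility_factor(state$n, p)[msk], 0)
  Dmax <- max(q$D_n, q$D_Bmax * nu_max, q$D_P)
  bound <- if (Dmax > 0) grid$h^2 / (4 * Dmax) else Inf

  u_max <- drift_speed_max(state$n, p, grid)
  if (u_max > 0) bound <- min(bound, grid$h / u_max)

  if (include_reaction) {
    B <- state$B[msk]; L <- state$L[msk]; P <- state$P[msk]
    n <- state$n[msk]
    af <- if (p$ablate_density_inhibition) 1 else p$K_b / (B + L + p$K_b)
    eta2 <- eta_areal(p)
    rates <- c(eta2 * af * P,                  # B adsorption loss
               eta2 * af * (B + L),           # P multi-adsorption loss
               monod_growth(n, p),            # B growth
               if (p$ablate_nutrient_gating) p$k_l * p$n0 else p$k_l * n,
               p$lam * p$g_max * (B + L) / (n + p$K_n))  # n consumption
    rmax <- max(rates, 0)
    if (rmax > 0) bound <- min(bound, 1 / rmax)
  }
  safety * bound
}

drift_speed_max <- function(n, p, grid) {
  q <- internal_params(p)
  cnu <- q$D_Bmax * q$alpha_c * motility_factor(n, p) * q$K_c / (n + q$K_c)^2
  h <- grid$h; msk <- grid$mask
  nx <- grid$nx; ny <- grid$ny
  ux <- abs(0.5 * (cnu[-nx, ] + cnu[-1, ]) * (n[-1, ] - n[-nx, ]) / h)
  ux[!(msk[-nx, ] & msk[-1, ])] <- 0
  uy <- abs(0.5 * (cnu[, -ny] + cnu[, -1]) * (n[, -1] - n[, -ny]) / h)
  uy[!(msk[, -ny] & msk[, -1])] <- 0
  max(ux, uy, 0)
}

#' Advance a field state by one operator-split step
#'
#' One Strang step (transport half-step, adaptive reaction step,
#' transport half-step) of size `dt`. Negative values produced by
#' round-off are clamped at zero and the clamped mass is reported.
#'
#' @param state a [field_state()].
#' @param p a [model_params()] object.
#' @param grid the grid of `state`.
#' @param dt time step (h); must respect the transport stability bound.
#' @param rxn_rtol reaction-integrator relative tolerance.
#' @param rho_cut discreteness cutoff in particles per grid cell (see
#'   [simulation_config()]); 0 disables it.
#' @return a [field_state()] at `state$t + dt`, with attribute
#'   `clamped_mass`.
#' @export
step_state <- function(state, p, grid, dt, rxn_rtol = 1e-6, rho_cut = 1) {
  stopifnot(inherits(state, "field_state"), dt > 0)
  res <- .step_core(state$B, state$L, state$P, state$n, grid$mask, grid$h,
                    internal_params(p), dt, rxn_rtol,
                    rho_cut / (grid$h^2 * UM2_PER_CM2))
  out <- field_state(state$t + dt, res$B, res$L, res$P, res$n, grid)
  attr(out, "clamped_mass") <- res$clamped_mass
  out
}

#' Run a simulation to its end time
#'
#' Integrates the model from the inoculation initial condition to
#' `config$T`, with the time step capped by the transport stability
#' bound, `config$dt_max`, and exact landing on snapshot times. The run
#' is fully deterministic. If `config$stop_depletion_frac` is set, the
#' run halts at the first step where the probe-point nutrient falls below
#' that fraction of its initial value (used to capture the phage
#' initiation zone).
#'
#' @param config a [simulation_config()].
#' @param n_init_mult multiplier on the initial nutrient level; defaults
#'   to the config's `n_init_mult`.
#' @return object of class `phage_trajectory`: list with `times`,
#'   `snapshots` (list of [field_state()]), `config`, `grid`, and
#'   `diagnostics` (dt history summary, clamped mass, probe series,
#'   depletion flag).
#' @export
run_simulation <- function(config, n_init_mult = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(n_init_mult))
    n_init_mult <- if (is.null(config$n_init_mult)) 1 else config$n_init_mult
  p <- config$params
  grid <- plate_grid(config$h, p$R_plate)
  s0 <- build_initial_state(grid, config$inoculations, p,
                            n_init = p$n0 * n_init_mult)
  probe <- integer(0)
  if (!is.null(config$probe))
    probe <- grid_cell_at(grid, config$probe[1], config$probe[2])
  stop_frac <- if (is.null(config$stop_depletion_frac)) -1
               else config$stop_depletion_frac
  t_start <- Sys.time()
  if (config$T <= 0) {
    traj <- list(times = 0, snapshots = list(s0), config = config,
                 grid = grid,
                 diagnostics = list(n_steps = 0L, dt = numeric(0),
                                    clamped_mass = 0,
                                    probe_t = numeric(0),
                                    probe_n = numeric(0),
                                    stopped_depleted = FALSE,
                                    wall_time_s = 0))
    class(traj) <- "phage_trajectory"
    return(traj)
  }
  res <- .run_core(s0$B, s0$L, s0$P, s0$n, grid$mask, grid$h,
                   internal_params(p), 0, config$T,
                   config$snapshot_times, config$safety, config$dt_max,
                   config$rxn_rtol,
                   config$rho_cut / (config$h^2 * UM2_PER_CM2),
                   probe, stop_frac, max_steps = 2000000L)
  snaps <- Map(function(f, t) field_state(t, f$B, f$L, f$P, f$n, grid),
               res$fields, res$times)
  traj <- list(times = unlist(res$times), snapshots = snaps,
               config = config, grid = grid,
               diagnostics = list(
                 n_steps = res$n_steps,
                 dt = res$dt_history,
                 clamped_mass = res$clamped_mass,
                 probe_t = res$probe_t, probe_n = res$probe_n,
                 stopped_depleted = res$stopped_depleted,
                 wall_time_s = as.numeric(difftime(Sys.time(), t_start,
                                                   units = "secs"))))
  class(traj) <- "phage_trajectory"
  traj
}

#' @export
print.phage_trajectory <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<phage_trajectory> %d snapshots over t = [%g, %g] h (%d steps, %.1f s)\n",
              length(x$snapshots), min(x$times), max(x$times), d$n_steps,
              d$wall_time_s))
  if (isTRUE(d$stopped_depleted))
    cat(sprintf("  stopped on probe nutrient depletion at t = %.3f h\n",
                max(x$times)))
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param traj a `phage_trajectory`.
#' @return the last [field_state()].
#' @export
final_state <- function(traj) traj$snapshots[[length(traj$snapshots)]]
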