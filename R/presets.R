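#' Standard drop-assay configuration
#'
#' Builds the canonical scenario: bacteria inoculated at the plate centre
#' and (optionally) phages at distance `d` on the +x axis, both as disks
#' of radius `r_inoc`, on a uniform nutrient field.
#'
#' @param params a [model_params()] object.
#' @param d phage inoculation distance from the centre (cm); `NULL` or
#'   `NA` for a phage-free control; 0 for the concentric control.
#' @param h grid spacing (cm).
#' @param T end time (h).
#' @param P0 phage count override (defaults to `params$P0`).
#' @param B0 bacterial count override.
#' @param rod_length if not `NULL`, the phages are inoculated with a rod
#'   (capillary) of this length (cm) and `rod_width`, centred at `(d, 0)`
#'   with its axis along y.
#' @param rod_width rod width (cm).
#' @param snapshot_by snapshot spacing (h).
#' @param ... passed on to [simulation_config()].
#' @return a [simulation_config()].
#' @export
drop_assay_config <- function(params = model_params(), d = 1, h = 0.1,
                              T = 14, P0 = NULL, B0 = NULL,
                              rod_length = NULL, rod_width = 0.1,
                              snapshot_by = 0.5, ...) {
  if (is.null(B0)) B0 <- params$B0
  if (is.null(P0)) P0 <- params$P0
  inocs <- list(inoculation_spec("bacteria", B0, center = c(0, 0),
                                 radius = params$r_inoc))
  if (!is.null(d) && !is.na(d)) {
    ph <- if (!is.null(rod_length))
      inoculation_spec("phage", P0, shape = "rod", center = c(d, 0),
                       length = rod_length, width = rod_width)
    else
      inoculation_spec("phage", P0, center = c(d, 0),
                       radius = params$r_inoc)
    inocs <- c(inocs, list(ph))
  }
  simulation_config(params = params, h = h, T = T, inoculations = inocs,
                    snapshot_times = seq(0, T, by = snapshot_by), ...)
}

# multiply one model parameter by a factor
scale_param <- function(params, name, factor) {
  stopifnot(name %in% param_names())
  pl <- unclass(params)
  pl[[name]] <- pl[[name]] * factor
  do.call(model_params, pl)
}

#' Figure-style scenario presets
#'
#' Returns the configuration(s) reproducing each in-silico figure panel:
#' either a single [simulation_config()] or a [sweep_spec()] of runs.
#' Sweep grids are reduced relative to the figure panels by default
#' (`full = TRUE` restores the full axes where the source lists them);
#' parameter axes use multiplicative factors 1/2, 1, 2 around the
#' defaults (2/3, 1, 3/2 for the division rate, whose effects saturate
#' sooner). Cells with slower swim rings run longer, mirroring the
#' protocol of incubating until the ring reaches the plate edge.
#'
#' Available presets: `"fig1"` (default scenario, d = 1 cm),
#' `"fig2a"` (inoculation distances), `"fig2b"` (rod inoculations),
#' `"fig2c"` (initial nutrient levels), `"fig2d"` (initial phage
#' numbers), `"fig3a"`/`"fig3b"`/`"fig3c"` (division rate vs adsorption
#' rate / burst size / lysis rate), `"fig4a"` (bacterial diffusion vs
#' chemotactic efficiency), `"fig5a"` (diffusion vs adsorption
#' co-propagation corners), `"s1_ablation_i"` (no nutrient gating),
#' `"s1_ablation_ii"` (no density inhibition), `"s3_b0"` (inoculated
#' bacteria number), `"s6_proportional"` (proportional bacterial and
#' nutrient diffusion), `"s9_nutrient"` (nutrient level vs adsorption
#' rate), `"concentric"` (phages co-inoculated at the centre) and
#' `"no_phage"`.
#'
#' @param name preset name.
#' @param h grid spacing (cm).
#' @param full use the full figure axes instead of the reduced ones.
#' @param params base parameter set.
#' @return a [simulation_config()] or a [sweep_spec()].
#' @export
preset <- function(name, h = 0.1, full = FALSE, params = model_params()) {
  base <- function(...) drop_assay_config(params = params, h = h, ...)
  switch(name,
    fig1 = ,
    default = base(),
    concentric = base(d = 0),
    no_phage = base(d = NULL),
    fig2a = sweep_spec(
      base(), axis(d = if (full) c(0.5, 1, 1.5, 2, 2.5) else c(0.5, 1, 2)),
      name = "fig2a"),
    fig2b = sweep_spec(
      base(d = 0.5), axis(rod_length = if (full) c(0.5, 1, 1.5, 2)
                          else c(0.5, 1.5)),
      name = "fig2b"),
    fig2c = sweep_spec(
      base(), axis(n_init_mult = if (full) c(0.05, 0.1, 0.5, 0.75, 1, 2)
                   else c(0.5, 1, 2)),
      name = "fig2c",
      T_for = function(row) if (row$n_init_mult < 1) 20 else 14),
    fig2d = sweep_spec(
      base(), axis(P0_total = if (full) 1.5 * 10^(2:8)
                   else c(1.5e2, 1.5e5, 1.5e8)),
      name = "fig2d"),
    fig3a = sweep_spec(
      base(), axis(g_max_factor = c(2 / 3, 1, 1.5),
                   eta_factor = c(0.5, 1, 2)),
      name = "fig3a", T_for = slow_ring_T),
    fig3b = sweep_spec(
      base(), axis(g_max_factor = c(2 / 3, 1, 1.5),
                   beta_factor = c(0.5, 1, 2)),
      name = "fig3b", T_for = slow_ring_T),
    fig3c = sweep_spec(
      base(), axis(g_max_factor = c(2 / 3, 1, 1.5),
                   k_l_factor = c(0.5, 1, 2)),
      name = "fig3c", T_for = slow_ring_T),
    fig4a = sweep_spec(
      base(), axis(D_Bmax_factor = c(0.5, 1, 2, 4),
                   alpha_c_factor = c(0.5, 1, 2, 4)),
      name = "fig4a", T_for = slow_ring_T),
    fig5a = sweep_spec(
      base(), axis(corner = c("low", "mid", "high")),
      name = "fig5a"),
    s1_ablation_i = {
      cfg <- base()
      cfg$params$ablate_nutrient_gating <- TRUE
      cfg
    },
    s1_ablation_ii = {
      cfg <- base()
      cfg$params$ablate_density_inhibition <- TRUE
      cfg
    },
    s3_b0 = sweep_spec(
      base(), axis(B0_total = c(1e6, 1e7, 1e8)), name = "s3_b0"),
    s6_proportional = sweep_spec(
      base(), axis(diffusion_factor = c(0.5, 1, 2)),
      name = "s6_proportional",
      T_for = function(row) if (row$diffusion_factor < 1) 20 else 14),
    s9_nutrient = sweep_spec(
      base(), axis(n_init_mult = c(0.5, 1, 2),
                   eta_factor = c(0.5, 1, 2)),
      name = "s9_nutrient",
      T_for = function(row) if (row$n_init_mult < 1) 20 else 14),
    stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  )
}

slow_ring_T <- function(row) {
  f <- 1
  if (!is.null(row$g_max_factor)) f <- f * row$g_max_factor
  if (!is.null(row$D_Bmax_factor)) f <- f * row$D_Bmax_factor
  if (f < 1) 24 else 14
}

axis <- function(...) list(...)

#' Sweep specification
#'
#' A base configuration plus one or two axes of values; the run grid is
#' the Cartesian product. Axis names are either model parameter names
#' suffixed `_factor` (multiplied onto the default), the scenario knobs
#' `d`, `rod_length`, `P0_total`, `B0_total`, `n_init_mult`, the
#' combined `diffusion_factor` (scales `D_Bmax` and `D_n` together), or
#' `corner` (the co-propagation phase-diagram corners scaling `D_Bmax`
#' and `eta` jointly by 1/4, 1, 4).
#'
#' @param base a [simulation_config()].
#' @param axes named list mapping axis names to value vectors.
#' @param name label for outputs.
#' @param T_for optional function of a grid row returning the end time
#'   (h) for that cell.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, axes, name = "sweep", T_for = NULL) {
  stopifnot(inherits(base, "simulation_config"),
            is.list(axes), length(axes) >= 1, length(axes) <= 2,
            !is.null(names(axes)))
  known <- c(paste0(param_names(), "_factor"), "d", "rod_length",
             "P0_total", "B0_total", "n_init_mult", "diffusion_factor",
             "corner")
  bad <- setdiff(names(axes), known)
  if (length(bad))
    stop(sprintf("unknown sweep axis: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  sp <- list(base = base, axes = axes, name = name, T_for = T_for)
  class(sp) <- "sweep_spec"
  sp
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec> %s: %s (%d runs)\n", x$name,
              paste(sprintf("%s[%d]", names(x$axes),
                            lengths(x$axes)), collapse = " x "),
              prod(lengths(x$axes))))
  invisible(x)
}

# build the simulation_config for one grid row of a sweep
config_for_row <- function(spec, row) {
  base <- spec$base
  p <- base$params
  d <- 1
  P0 <- NULL; B0 <- NULL; rod <- NULL
  nmult <- base$n_init_mult
  for (nm in names(row)) {
    v <- row[[nm]]
    if (nm == "d") d <- v
    else if (nm == "rod_length") { rod <- v; d <- 0.5 }
    else if (nm == "P0_total") P0 <- v
    else if (nm == "B0_total") B0 <- v
    else if (nm == "n_init_mult") nmult <- v
    else if (nm == "diffusion_factor") {
      p <- scale_param(p, "D_Bmax", v)
      p <- scale_param(p, "D_n", v)
    } else if (nm == "corner") {
      f <- c(low = 0.25, mid = 1, high = 4)[[v]]
      p <- scale_param(p, "D_Bmax", f)
      p <- scale_param(p, "eta", f)
    } else if (grepl("_factor$", nm)) {
      p <- scale_param(p, sub("_factor$", "", nm), v)
    }
  }
  T <- base$T
  if (!is.null(spec$T_for)) T <- spec$T_for(row)
  if (!is.null(row$corner) && row$corner == "low") T <- 24
  drop_assay_config(params = p, d = d, h = base$h, T = T, P0 = P0,
                    B0 = B0, rod_length = rod,
                    n_init_mult = nmult, safety = base$safety,
                    dt_max = base$dt_max, rxn_rtol = base$rxn_rtol,
                    rho_cut = base$rho_cut, seed = base$seed)
}

#' Run a parameter sweep
#'
#' Executes every cell of the sweep grid and summarises each run into
#' one row: the axis values, final-profile slope and class, outcome,
#' arrival time, initiation-zone radius and depletion time, the sector
#' angle at r = 2 cm, and the run wall time. Individual run failures are
#' recorded in the `error` column and the sweep continues. Results are
#' deterministic given the spec.
#'
#' @param spec a [sweep_spec()].
#' @param verbose print one line per completed run.
#' @return data.frame with one row per grid cell, in `expand.grid` order.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid_df <- do.call(expand.grid,
                     c(spec$axes, list(stringsAsFactors = FALSE)))
  rows <- lapply(seq_len(nrow(grid_df)), function(k) {
    row <- as.list(grid_df[k, , drop = FALSE])
    out <- row
    res <- tryCatch({
      cfg <- config_for_row(spec, row)
      traj <- run_simulation(cfg)
      prof <- sector_angle_profile(final_state(traj))
      cls <- classify_pattern(prof, slope_tol = 0.2, slope_center = 0.4)
      oc <- copropagation_outcome(traj)
      iz <- if (!is.null(phage_center_of(cfg)))
        initiation_zone(traj) else NULL
      list(slope = as.numeric(attr(cls, "slope")),
           class = as.character(cls),
           outcome = as.character(oc),
           arrival_h = as.numeric(ring_arrival_time(traj)),
           initiation_radius_cm =
             if (is.null(iz)) NA_real_ else iz$equiv_radius,
           t_star_h = if (is.null(iz)) NA_real_ else iz$t_star,
           theta_2cm = prof$theta[prof$r == 2],
           wall_s = traj$diagnostics$wall_time_s,
           error = NA_character_)
    }, error = function(e) {
      list(slope = NA_real_, class = NA_character_,
           outcome = NA_character_, arrival_h = NA_real_,
           initiation_radius_cm = NA_real_, t_star_h = NA_real_,
           theta_2cm = NA_real_, wall_s = NA_real_,
           error = conditionMessage(e))
    })
    if (verbose)
      cat(sprintf("[%s] %s -> %s / %s\n", spec$name,
                  paste(names(row), unlist(row), sep = "=",
                        collapse = ", "),
                  res$class, res$outcome))
    as.data.frame(c(out, res), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
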