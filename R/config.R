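#' Simulation configuration
#'
#' Bundles the model parameters, grid spec, inoculations and solver
#' controls of one run. The simulation is fully deterministic; the `seed`
#' slot is carried through for provenance only.
#'
#' @param params a [model_params()] object.
#' @param h grid spacing, cm.
#' @param T end time, h.
#' @param inoculations list of [inoculation_spec()]; defaults to the
#'   standard drop assay built by [preset()] callers. At least one
#'   bacterial inoculum is required.
#' @param snapshot_times times (h) at which field snapshots are stored;
#'   must lie in `[0, T]`. Snapshot times are hit exactly by capping the
#'   time step.
#' @param safety multiplicative safety factor on the stability bound.
#' @param dt_max hard cap on the time step (h), limiting operator-splitting
#'   error where the stability bound is loose.
#' @param rxn_rtol relative tolerance of the per-cell adaptive reaction
#'   integrator.
#' @param rho_cut discreteness cutoff in particles per grid cell: reaction
#'   source terms act only where the participating densities exceed
#'   `rho_cut / (h^2 * 1e8)` um^-2. This suppresses unphysical
#'   amplification of sub-particle density tails by the phage infection
#'   loop (see the methods vignette); set to 0 to integrate the literal
#'   continuum equations.
#' @param stop_depletion_frac if not `NULL`, stop the run at the first
#'   step where the nutrient at the probe point falls below this fraction
#'   of its initial value (the phage-initiation-zone rule uses 0.05).
#' @param probe length-2 numeric (cm) or `NULL`; point whose nutrient
#'   level is recorded every step. Defaults to the first phage inoculum
#'   centre, if any.
#' @param n_init_mult multiplier on the initial nutrient level (nutrient
#'   sweep scenarios).
#' @param seed integer, echoed into outputs (no randomness is consumed).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(params = model_params(), h = 0.1, T = 14,
                              inoculations = list(),
                              snapshot_times = NULL, safety = 0.8,
                              dt_max = 0.02, rxn_rtol = 1e-6,
                              rho_cut = 1, stop_depletion_frac = NULL,
                              probe = NULL, n_init_mult = 1, seed = 1L) {
  validate_params(params)
  stopifnot(h > 0, T >= 0, safety > 0, safety <= 1, dt_max > 0,
            rxn_rtol > 0, rho_cut >= 0)
  if (is.null(snapshot_times)) snapshot_times <- unique(c(0, T))
  snapshot_times <- sort(unique(as.numeric(snapshot_times)))
  if (any(snapshot_times < 0) || any(snapshot_times > T))
    stop("snapshot_times must lie within [0, T]", call. = FALSE)
  if (!any(vapply(inoculations, function(s) s$species == "bacteria",
                  logical(1))))
    stop("at least one bacterial inoculum is required", call. = FALSE)
  if (is.null(probe)) {
    ph <- Filter(function(s) s$species == "phage", inoculations)
    if (length(ph)) probe <- ph[[1]]$center
  }
  cfg <- list(params = params, h = h, T = T, inoculations = inoculations,
              snapshot_times = snapshot_times, safety = safety,
              dt_max = dt_max, rxn_rtol = rxn_rtol, rho_cut = rho_cut,
              stop_depletion_frac = stop_depletion_frac,
              probe = probe, n_init_mult = n_init_mult,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> h = %g cm, T = %g h, %d inocula, %d snapshots\n",
              x$h, x$T, length(x$inoculations), length(x$snapshot_times)))
  invisible(x)
}

#' Write a simulation configuration to a JSON file
#'
#' The on-disk dialect is flat JSON: one `params` object keyed by the
#' model symbols (`D_Bmax`, `K_v`, ...), solver scalars at top level, and
#' an `inoculations` array. Numbers are written at full precision, so
#' save/load round-trips are lossless.
#'
#' @param config a [simulation_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  il <- lapply(config$inoculations, function(s)
    Filter(Negate(is.null),
           s[c("species", "shape", "total", "center", "radius",
               "length", "width")]))
  obj <- list(params = unclass(config$params),
              h = config$h, T = config$T,
              snapshot_times = config$snapshot_times,
              safety = config$safety, dt_max = config$dt_max,
              rxn_rtol = config$rxn_rtol, rho_cut = config$rho_cut,
              stop_depletion_frac = config$stop_depletion_frac,
              probe = config$probe, n_init_mult = config$n_init_mult,
              seed = config$seed, inoculations = il)
  obj <- Filter(Negate(is.null), obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load and validate a simulation configuration
#'
#' Unspecified model parameters take their default values; unknown keys
#' are an error. Validation failures name the offending key.
#'
#' @param path path to a JSON config written by [save_config()] (or by
#'   hand in the same dialect).
#' @return a [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("params", "h", "T", "snapshot_times", "safety", "dt_max",
                 "rxn_rtol", "rho_cut", "stop_depletion_frac", "probe",
                 "n_init_mult", "seed", "inoculations")
  bad <- setdiff(names(obj), known_top)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  pl <- if (is.null(obj$params)) list() else as.list(obj$params)
  # JSON readers return whole numbers as integers; the model works in
  # doubles throughout, so coerce for lossless round-trips
  pl <- lapply(pl, function(v) if (is.numeric(v)) as.numeric(v) else v)
  badp <- setdiff(names(pl), param_names())
  if (length(badp))
    stop(sprintf("unknown model parameter key(s): %s",
                 paste(badp, collapse = ", ")), call. = FALSE)
  params <- do.call(model_params, pl)
  # absent inoculations: the standard drop assay (bacteria at the centre,
  # phages 1 cm away), so an empty config is the default scenario
  inocs <- list(
    inoculation_spec("bacteria", params$B0, center = c(0, 0),
                     radius = params$r_inoc),
    inoculation_spec("phage", params$P0, center = c(1, 0),
                     radius = params$r_inoc))
  if (!is.null(obj$inoculations)) {
    raw <- obj$inoculations
    # read_json with simplifyVector may give a data.frame or a list
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    inocs <- lapply(raw, function(s) {
      s <- as.list(s)
      arg <- function(k) {
        v <- s[[k]]
        if (is.null(v) || (length(v) && all(is.na(v)))) return(NULL)
        v <- unlist(v)
        if (is.numeric(v)) as.numeric(v) else v
      }
      inoculation_spec(species = arg("species"), total = arg("total"),
                       shape = if (is.null(arg("shape"))) "disk" else arg("shape"),
                       center = arg("center"), radius = arg("radius"),
                       length = arg("length"), width = arg("width"))
    })
    names(inocs) <- NULL
  }
  take <- function(k, default) {
    v <- obj[[k]]
    if (is.null(v)) default else if (is.numeric(v)) as.numeric(v) else v
  }
  simulation_config(params = params,
                    h = take("h", 0.1), T = take("T", 14),
                    inoculations = inocs,
                    snapshot_times =
                      if (is.null(obj$snapshot_times)) NULL
                      else as.numeric(obj$snapshot_times),
                    safety = take("safety", 0.8),
                    dt_max = take("dt_max", 0.02),
                    rxn_rtol = take("rxn_rtol", 1e-6),
                    rho_cut = take("rho_cut", 1),
                    stop_depletion_frac =
                      if (is.null(obj$stop_depletion_frac)) NULL
                      else as.numeric(obj$stop_depletion_frac),
                    probe = if (is.null(obj$probe)) NULL
                            else as.numeric(obj$probe),
                    n_init_mult = take("n_init_mult", 1),
                    seed = take("seed", 1L))
}
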