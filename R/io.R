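#' Write a trajectory to a portable on-disk container
#'
#' Persists every snapshot as plain-text CSV matrices (one file per
#' field per time) plus a JSON manifest carrying the configuration echo,
#' grid specification, snapshot inventory, time-step history summary and
#' clamp diagnostics — enough to replay any analysis without rerunning
#' the solver, and inspectable without special libraries.
#'
#' @param traj a `phage_trajectory`.
#' @param dir output directory (created if needed).
#' @return the manifest (invisibly). Files: `manifest.json`,
#'   `config.json`, `fields/<field>_<k>.csv`, `summary.csv`.
#' @export
write_snapshots <- function(traj, dir) {
  stopifnot(inherits(traj, "phage_trajectory"))
  dir.create(file.path(dir, "fields"), recursive = TRUE,
             showWarnings = FALSE)
  files <- character(0)
  for (k in seq_along(traj$snapshots)) {
    s <- traj$snapshots[[k]]
    for (f in c("B", "L", "P", "n")) {
      fn <- file.path("fields", sprintf("%s_%03d.csv", f, k))
      utils::write.table(s[[f]], file.path(dir, fn), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, fn)
    }
  }
  save_config(traj$config, file.path(dir, "config.json"))
  d <- traj$diagnostics
  manifest <- list(
    package_version = as.character(utils::packageVersion("phagesector")),
    times = traj$times,
    grid = list(h = traj$grid$h, nx = traj$grid$nx, ny = traj$grid$ny,
                R_plate = traj$grid$R_plate),
    n_steps = d$n_steps,
    dt = list(min = if (length(d$dt)) min(d$dt) else NA,
              max = if (length(d$dt)) max(d$dt) else NA,
              mean = if (length(d$dt)) mean(d$dt) else NA),
    clamped_mass = d$clamped_mass,
    stopped_depleted = isTRUE(d$stopped_depleted),
    wall_time_s = d$wall_time_s,
    probe = list(t = d$probe_t, n = d$probe_n),
    files = c("config.json", files))
  # atomic write: temp file then rename
  tmp <- file.path(dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Read a trajectory written by [write_snapshots()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `phage_trajectory` (diagnostics restored from the manifest).
#' @export
read_snapshots <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("no manifest.json under %s", dir), call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  config <- load_config(file.path(dir, "config.json"))
  grid <- plate_grid(manifest$grid$h, manifest$grid$R_plate)
  times <- as.numeric(manifest$times)
  read_field <- function(f, k) {
    fn <- file.path(dir, "fields", sprintf("%s_%03d.csv", f, k))
    as.matrix(utils::read.table(fn, sep = ",", header = FALSE))
  }
  snaps <- lapply(seq_along(times), function(k) {
    field_state(times[k],
                B = unname(read_field("B", k)),
                L = unname(read_field("L", k)),
                P = unname(read_field("P", k)),
                n = unname(read_field("n", k)), grid)
  })
  traj <- list(times = times, snapshots = snaps, config = config,
               grid = grid,
               diagnostics = list(
                 n_steps = manifest$n_steps, dt = numeric(0),
                 clamped_mass = manifest$clamped_mass,
                 probe_t = as.numeric(manifest$probe$t),
                 probe_n = as.numeric(manifest$probe$n),
                 stopped_depleted = isTRUE(manifest$stopped_depleted),
                 wall_time_s = manifest$wall_time_s))
  class(traj) <- "phage_trajectory"
  traj
}

#' Write a pattern summary as CSV plus JSON sidecar
#'
#' The CSV holds the theta(r) profile; the JSON sidecar carries the
#' scalar observables and every threshold used.
#'
#' @param ps a [pattern_summary()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(ps, path) {
  stopifnot(inherits(ps, "pattern_summary"))
  utils::write.csv(ps$profile, path, row.names = FALSE)
  side <- list(arrival_time_h = ps$arrival_time,
               slope_rad_per_cm = ps$slope,
               class = ps$class, outcome = ps$outcome,
               initiation = if (is.null(ps$initiation)) NULL else
                 list(t_star_h = ps$initiation$t_star,
                      equiv_radius_cm = ps$initiation$equiv_radius,
                      flags = ps$initiation$flags),
               thresholds = ps$thresholds,
               front_radius = ps$front_radius)
  jsonlite::write_json(Filter(Negate(is.null), side),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
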