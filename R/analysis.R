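#' Swim-ring front radius
#'
#' Along `n_rays` equally spaced rays from the bacterial inoculation
#' centre, finds the largest radius at which total bacterial density
#' `B + L` is at least `frac_threshold` times its current global maximum,
#' and returns the median over rays. If `phage_center` is given, only
#' rays on the opposite (phage-free) half-plane are used, so the lysis
#' sector does not bias the ring radius.
#'
#' @param state a [field_state()].
#' @param frac_threshold front detection threshold (fraction of the
#'   global maximum of `B + L`).
#' @param center bacterial inoculation centre (cm).
#' @param phage_center phage inoculation centre (cm) or `NULL`.
#' @param n_rays number of rays.
#' @return front radius (cm); `NA` with attribute `flag = "empty"` if the
#'   field is all zero.
#' @export
front_radius <- function(state, frac_threshold = 0.1, center = c(0, 0),
                         phage_center = NULL, n_rays = 360) {
  g <- state$grid
  tot <- state$B + state$L
  mx <- max(tot)
  if (mx <= 0) {
    out <- NA_real_
    attr(out, "flag") <- "empty"
    return(out)
  }
  thr <- frac_threshold * mx
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  if (!is.null(phage_center)) {
    pa <- atan2(phage_center[2] - center[2], phage_center[1] - center[1])
    keep <- cos(ang - pa) < 0  # mirror half
    ang <- ang[keep]
  }
  rr <- seq(g$h / 2, g$R_plate, by = g$h / 2)
  radii <- vapply(ang, function(a) {
    x <- center[1] + rr * cos(a)
    y <- center[2] + rr * sin(a)
    i <- pmin(pmax(1L, as.integer(floor((x + g$nx * g$h / 2) / g$h)) + 1L),
              g$nx)
    j <- pmin(pmax(1L, as.integer(floor((y + g$ny * g$h / 2) / g$h)) + 1L),
              g$ny)
    hit <- which(tot[cbind(i, j)] >= thr)
    if (length(hit)) rr[max(hit)] else 0
  }, numeric(1))
  stats::median(radii)
}

#' Time at which the swim ring reaches the plate wall
#'
#' First time the front radius reaches `0.95 * R_plate`, linearly
#' interpolated between the bracketing snapshots.
#'
#' @param traj a `phage_trajectory`.
#' @param frac_threshold passed to [front_radius()].
#' @return arrival time (h); `Inf` with attribute `flag = "not_reached"`
#'   if the ring never arrives within the trajectory.
#' @export
ring_arrival_time <- function(traj, frac_threshold = 0.1) {
  cfg <- traj$config
  pc <- phage_center_of(cfg)
  target <- 0.95 * traj$grid$R_plate
  fr <- vapply(traj$snapshots, front_radius, numeric(1),
               frac_threshold = frac_threshold, phage_center = pc)
  idx <- which(fr >= target)
  if (!length(idx)) {
    out <- Inf
    attr(out, "flag") <- "not_reached"
    attr(out, "front_radii") <- data.frame(t = traj$times, r = fr)
    return(out)
  }
  k <- idx[1]
  t_arr <- if (k == 1) traj$times[1] else {
    t0 <- traj$times[k - 1]; t1 <- traj$times[k]
    r0 <- fr[k - 1]; r1 <- fr[k]
    t0 + (target - r0) / (r1 - r0) * (t1 - t0)
  }
  attr(t_arr, "front_radii") <- data.frame(t = traj$times, r = fr)
  t_arr
}

phage_center_of <- function(cfg) {
  ph <- Filter(function(s) s$species == "phage", cfg$inoculations)
  if (length(ph)) ph[[1]]$center else NULL
}

#' Phage initiation zone
#'
#' Finds the depletion time `t*` at which the nutrient at the phage
#' inoculation centre first falls below `depletion_frac` of its initial
#' level (the 5 percent rule), and measures the phage-occupied region at
#' that moment: the connected component (4-neighbourhood) of cells with
#' `P >= phage_density_floor` containing the phage centre. The reported
#' equivalent radius is `sqrt(area / pi)`.
#'
#' `t*` is read from the per-step probe series when available (exact to
#' one time step), otherwise from the snapshot sequence; the region is
#' evaluated on the snapshot closest to `t*`.
#'
#' @param traj a `phage_trajectory` from a run with a phage inoculum.
#' @param depletion_frac depletion threshold as a fraction of the initial
#'   nutrient level.
#' @param phage_density_floor minimum density (um^-2) counting as
#'   "occupied by phages"; default one particle per grid cell,
#'   `1 / (h^2 * 1e8)`.
#' @return list with `t_star`, `equiv_radius` (cm), `area` (cm^2),
#'   `region` (logical matrix), `snapshot_time`, `thresholds`, `flags`
#'   (character vector; empty when everything was measurable).
#' @export
initiation_zone <- function(traj, depletion_frac = 0.05,
                            phage_density_floor = NULL) {
  cfg <- traj$config
  pc <- phage_center_of(cfg)
  if (is.null(pc))
    stop("initiation_zone requires a run with a phage inoculum",
         call. = FALSE)
  g <- traj$grid
  if (is.null(phage_density_floor))
    phage_density_floor <- 1 / (g$h^2 * UM2_PER_CM2)
  flags <- character(0)

  n_init <- cfg$params$n0
  d <- traj$diagnostics
  t_star <- NA_real_
  if (length(d$probe_t)) {
    thr <- depletion_frac * n_init
    below <- which(d$probe_n < thr)
    if (length(below)) {
      k <- below[1]
      t_star <- if (k == 1) d$probe_t[1] else {
        t0 <- d$probe_t[k - 1]; t1 <- d$probe_t[k]
        v0 <- d$probe_n[k - 1]; v1 <- d$probe_n[k]
        t0 + (v0 - thr) / (v0 - v1) * (t1 - t0)
      }
    }
  } else {
    ij <- grid_cell_at(g, pc[1], pc[2])
    nn <- vapply(traj$snapshots, function(s) s$n[ij[1], ij[2]], numeric(1))
    k <- which(nn < depletion_frac * n_init)
    if (length(k)) t_star <- traj$times[k[1]]
  }
  if (is.na(t_star)) {
    flags <- c(flags, "depletion_not_reached")
    return(list(t_star = NA_real_, equiv_radius = NA_real_,
                area = NA_real_, region = NULL, snapshot_time = NA_real_,
                thresholds = list(depletion_frac = depletion_frac,
                                  phage_density_floor = phage_density_floor),
                flags = flags))
  }
  k <- which.min(abs(traj$times - t_star))
  s <- traj$snapshots[[k]]
  if (abs(traj$times[k] - t_star) > 0.5)
    flags <- c(flags, "coarse_snapshot_spacing")
  ij <- grid_cell_at(g, pc[1], pc[2])
  occ <- s$P >= phage_density_floor & g$mask
  region <- flood_fill(occ, ij[1], ij[2])
  if (!occ[ij[1], ij[2]]) flags <- c(flags, "phage_center_below_floor")
  area <- sum(region) * g$h^2
  list(t_star = t_star, equiv_radius = sqrt(area / pi), area = area,
       region = region, snapshot_time = traj$times[k],
       thresholds = list(depletion_frac = depletion_frac,
                         phage_density_floor = phage_density_floor),
       flags = flags)
}

# 4-neighbour connected component of `occ` containing (i0, j0);
# empty if the seed itself is FALSE.
flood_fill <- function(occ, i0, j0) {
  out <- occ & FALSE
  if (!occ[i0, j0]) return(out)
  nx <- nrow(occ); ny <- ncol(occ)
  stack <- integer(length(occ))
  top <- 1L
  stack[1] <- (j0 - 1L) * nx + i0
  out[i0, j0] <- TRUE
  while (top > 0L) {
    k <- stack[top]; top <- top - 1L
    i <- (k - 1L) %% nx + 1L
    j <- (k - 1L) %/% nx + 1L
    for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
      ii <- nb[1]; jj <- nb[2]
      if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
      if (occ[ii, jj] && !out[ii, jj]) {
        out[ii, jj] <- TRUE
        top <- top + 1L
        stack[top] <- (jj - 1L) * nx + ii
      }
    }
  }
  out
}

#' Lysis-sector angle profile
#'
#' For each requested radius, bins the annulus of width `2 h` into
#' angular sectors about the bacterial inoculation centre and measures
#' the total angular extent over which susceptible-bacteria density falls
#' below `lysis_frac` times the reference level, the median over the
#' non-lysed bins of the same annulus (determined iteratively; a small
#' global floor handles fully lysed annuli, e.g. concentric-inoculation
#' controls). Annuli that the swim ring has not yet colonised are flagged
#' invalid.
#'
#' @param state a [field_state()] with an established ring.
#' @param radii radii (cm) at which to evaluate the profile.
#' @param lysis_frac lysis detection threshold.
#' @param center bacterial inoculation centre (cm).
#' @param n_bins number of angular bins.
#' @return data.frame with columns `r`, `theta` (radians in `[0, 2*pi]`)
#'   and `valid`; invalid radii have `theta = NA`.
#' @export
sector_angle_profile <- function(state, radii = seq(1.5, 4.5, by = 0.5),
                                 lysis_frac = 0.1, center = c(0, 0),
                                 n_bins = 360) {
  g <- state$grid
  dx <- g$xc - center[1]; dy <- g$yc - center[2]
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  bin <- pmin(n_bins, floor((ang + pi) / (2 * pi) * n_bins) + 1)
  Bmax <- max(state$B)
  res <- lapply(radii, function(r) {
    sel <- g$mask & abs(rad - r) <= g$h
    if (!any(sel)) return(c(NA_real_, 0))
    bmean <- tapply(state$B[sel], bin[sel], mean)
    tmean <- tapply((state$B + state$L)[sel], bin[sel], mean)
    # ring not established at this radius: essentially no bacteria at all
    if (stats::median(tmean) < 1e-4 * max(Bmax, 1e-12))
      return(c(NA_real_, 0))
    floor_ref <- 0.05 * Bmax
    ref <- max(stats::median(bmean), floor_ref)
    for (it in 1:10) {
      lysed <- bmean < lysis_frac * ref
      if (all(lysed)) return(c(2 * pi, 1))
      ref_new <- max(stats::median(bmean[!lysed]), floor_ref)
      if (abs(ref_new - ref) <= 1e-12) break
      ref <- ref_new
    }
    c(2 * pi * sum(lysed) / length(bmean), 1)
  })
  out <- data.frame(r = radii,
                    theta = vapply(res, `[`, numeric(1), 1),
                    valid = vapply(res, `[`, numeric(1), 2) == 1)
  out
}

#' Classify a lysis pattern from its sector-angle profile
#'
#' Least-squares slope of `theta(r)` over the valid radii, compared
#' against the band `slope_center +/- slope_tol`: `flared_out` above the
#' band, `closed_up` below it, `straight` inside.
#'
#' `slope_center` exists because finite-resolution solutions of this
#' model carry a positive baseline slope even for patterns that are
#' straight in the converged limit (the under-resolved infection front
#' travels slightly too fast on a lattice, and the sector needs a finite
#' radial distance to open up to its projected angle). The operation
#' defaults read the raw slope (`slope_center = 0`); the analysis
#' pipeline ([pattern_summary()], [run_sweep()]) applies the frozen
#' package calibration against the default-run phenotype at desk
#' resolutions (h = 0.05-0.1 cm): `slope_center = 0.4`,
#' `slope_tol = 0.2` rad/cm, recorded in every summary. See the methods
#' vignette. Profiles that are zero at every valid radius (no lysed arc
#' anywhere) are `straight` with attribute `note = "no_sector"`.
#'
#' @param profile data.frame from [sector_angle_profile()].
#' @param slope_tol half-width of the straight band, rad/cm.
#' @param slope_center centre of the straight band, rad/cm.
#' @return character class, with attributes `slope` (rad/cm) and
#'   `n_radii`; `"unclassified"` if fewer than 5 valid radii.
#' @export
classify_pattern <- function(profile, slope_tol = 0.05, slope_center = 0) {
  ok <- profile$valid & !is.na(profile$theta)
  if (sum(ok) < 5) {
    out <- "unclassified"
    attr(out, "slope") <- NA_real_
    attr(out, "n_radii") <- sum(ok)
    return(out)
  }
  if (all(profile$theta[ok] == 0)) {
    # no lysed arc at any radius: nothing to classify as flared or closed
    out <- "straight"
    attr(out, "slope") <- 0
    attr(out, "n_radii") <- sum(ok)
    attr(out, "note") <- "no_sector"
    return(out)
  }
  fit <- stats::lm(theta ~ r, data = profile[ok, ])
  s <- unname(coef(fit)[2])
  out <- if (s > slope_center + slope_tol) "flared_out"
         else if (s < slope_center - slope_tol) "closed_up"
         else "straight"
  attr(out, "slope") <- s
  attr(out, "n_radii") <- sum(ok)
  out
}

#' Co-propagation outcome of a run
#'
#' Diagnoses whether phages and bacteria keep expanding together, from
#' the maximal radius of the phage-occupied region (`P` above the
#' density floor) versus the bacterial front radius:
#' \itemize{
#'   \item `phage_encircles` - the phage region spans the plate
#'     (max radius >= 0.9 R) while the bacterial front is blocked well
#'     inside (<= 0.8 R), or, mid-expansion, the front stalls over the
#'     last quarter of the run while the phage region keeps growing;
#'   \item `bacteria_encircles` - the mirror image: the ring reaches
#'     the wall while the phage region is enclosed behind it, or the
#'     phage region stalls while the front keeps growing;
#'   \item `co_propagation` - otherwise (both fronts advance or both
#'     arrive).
#' }
#'
#' @param traj a `phage_trajectory`.
#' @param phage_density_floor density (um^-2) counting as phage-occupied;
#'   default one particle per grid cell.
#' @param frac_threshold front-detection threshold for [front_radius()].
#' @return outcome string with attributes `rf_end`, `rp_end`,
#'   `front_growth`, `phage_growth` (cm, last quarter of the run) and
#'   `thresholds`; `"no_phage"` for a phage-free run.
#' @export
copropagation_outcome <- function(traj, phage_density_floor = NULL,
                                  frac_threshold = 0.1) {
  cfg <- traj$config
  pc <- phage_center_of(cfg)
  if (is.null(pc)) return("no_phage")
  g <- traj$grid
  if (is.null(phage_density_floor))
    phage_density_floor <- 1 / (g$h^2 * UM2_PER_CM2)
  R <- g$R_plate
  rad <- g$r
  p_max_radius <- function(s) {
    occ <- s$P >= phage_density_floor & g$mask
    if (!any(occ)) 0 else max(rad[occ])
  }
  s_end <- final_state(traj)
  rf_end <- front_radius(s_end, frac_threshold, phage_center = pc)
  rp_end <- p_max_radius(s_end)
  t_end <- max(traj$times)
  kq <- which.min(abs(traj$times -
                        (t_end - 0.25 * (t_end - min(traj$times)))))
  rf_q <- front_radius(traj$snapshots[[kq]], frac_threshold,
                       phage_center = pc)
  rp_q <- p_max_radius(traj$snapshots[[kq]])
  front_growth <- rf_end - rf_q
  phage_growth <- rp_end - rp_q
  grow <- 2 * g$h  # minimal growth that counts as advancing

  out <- if (rp_end >= 0.9 * R && rf_end <= 0.8 * R) "phage_encircles"
    else if (rf_end >= 0.9 * R && rp_end <= 0.8 * R) "bacteria_encircles"
    else if (rf_end < 0.9 * R && rp_end < 0.9 * R &&
             front_growth > grow && phage_growth <= grow / 2)
      "bacteria_encircles"
    else if (rf_end < 0.9 * R && rp_end < 0.9 * R &&
             phage_growth > grow && front_growth <= grow / 2)
      "phage_encircles"
    else "co_propagation"
  attr(out, "rf_end") <- rf_end
  attr(out, "rp_end") <- rp_end
  attr(out, "front_growth") <- front_growth
  attr(out, "phage_growth") <- phage_growth
  attr(out, "thresholds") <- list(phage_density_floor = phage_density_floor,
                                  frac_threshold = frac_threshold)
  out
}

#' Plug-style region sampling of bacterial and phage densities
#'
#' Mimics the agar-plug quantification: mean total-bacteria (`B + L`) and
#' phage densities over a disk of `plug_radius` at each centre, reported
#' as area densities in cm^-2 (um^-2 times 1e8) for direct comparison
#' with plate counts converted by the agar depth.
#'
#' @param state a [field_state()].
#' @param centers list of length-2 numeric centres (cm), or a 2-column
#'   matrix; names become region ids.
#' @param plug_radius sampling disk radius (cm).
#' @return data.frame with `region`, `x`, `y`, `bacteria` and `phage`
#'   (cm^-2).
#' @export
sample_regions <- function(state, centers, plug_radius = 0.25) {
  g <- state$grid
  if (is.matrix(centers))
    centers <- split(centers, seq_len(nrow(centers)))
  ids <- if (!is.null(names(centers))) names(centers)
         else as.character(seq_along(centers))
  rows <- Map(function(ctr, id) {
    if (sqrt(sum(ctr^2)) > g$R_plate)
      stop(sprintf("region centre (%g, %g) lies outside the plate",
                   ctr[1], ctr[2]), call. = FALSE)
    sel <- (g$xc - ctr[1])^2 + (g$yc - ctr[2])^2 <= plug_radius^2 & g$mask
    data.frame(region = id, x = ctr[1], y = ctr[2],
               bacteria = mean(state$B[sel] + state$L[sel]) * UM2_PER_CM2,
               phage = mean(state$P[sel]) * UM2_PER_CM2)
  }, centers, ids)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Standard region layout for the six-plug density comparison
#'
#' Sampling centres mirroring the plug layout used for the density bar
#' comparison: the bacterial inoculation point (4), the middle of the
#' lysis sector (2), the outer edge of the sector (6), a point on a
#' radial sector boundary (5), and two points outside the sector (1, 3).
#' The phage inoculum is assumed on the +x axis.
#'
#' @param r_mid mid-ring sampling radius (cm).
#' @param boundary_angle angular position of the sector boundary (rad).
#' @param r_edge radius of the sector outer-edge sample (cm).
#' @return named list of centres, in region order 1..6.
#' @export
fig_region_centers <- function(r_mid = 2.75, boundary_angle = 50 * pi / 180,
                               r_edge = 4.9) {
  polar <- function(r, a) c(r * cos(a), r * sin(a))
  list(`1` = polar(r_mid, 2.0),
       `2` = polar(r_mid, 0),
       `3` = polar(r_mid, -2.0),
       `4` = c(0, 0),
       `5` = polar(r_mid, boundary_angle),
       `6` = polar(r_edge, 0))
}

#' Pattern summary of a trajectory
#'
#' Bundles the derived observables of a run: front kinematics, ring
#' arrival time, phage initiation zone, final sector-angle profile,
#' boundary-shape class and co-propagation outcome, together with every
#' threshold used (the summary is self-describing).
#'
#' @param traj a `phage_trajectory`.
#' @param radii radii for the sector-angle profile.
#' @param frac_threshold front-detection threshold.
#' @param lysis_frac lysis detection threshold.
#' @param slope_tol,slope_center classification band (rad/cm), see
#'   [classify_pattern()].
#' @param depletion_frac initiation-zone depletion rule.
#' @param phage_density_floor phage occupancy floor (um^-2); default one
#'   particle per cell.
#' @return object of class `pattern_summary`.
#' @export
pattern_summary <- function(traj, radii = seq(1.5, 4.5, by = 0.5),
                            frac_threshold = 0.1, lysis_frac = 0.1,
                            slope_tol = 0.2, slope_center = 0.4,
                            depletion_frac = 0.05,
                            phage_density_floor = NULL) {
  g <- traj$grid
  if (is.null(phage_density_floor))
    phage_density_floor <- 1 / (g$h^2 * UM2_PER_CM2)
  pc <- phage_center_of(traj$config)
  fr <- vapply(traj$snapshots, front_radius, numeric(1),
               frac_threshold = frac_threshold, phage_center = pc)
  arrival <- ring_arrival_time(traj, frac_threshold)
  iz <- if (!is.null(pc))
    tryCatch(initiation_zone(traj, depletion_frac, phage_density_floor),
             error = function(e) NULL) else NULL
  prof <- sector_angle_profile(final_state(traj), radii, lysis_frac)
  cls <- classify_pattern(prof, slope_tol, slope_center)
  outcome <- copropagation_outcome(traj, phage_density_floor)
  out <- list(front_radius = data.frame(t = traj$times, r = fr),
              arrival_time = as.numeric(arrival),
              initiation = iz,
              profile = prof,
              slope = attr(cls, "slope"),
              class = as.character(cls),
              outcome = as.character(outcome),
              outcome_detail = attributes(outcome),
              thresholds = list(frac_threshold = frac_threshold,
                                lysis_frac = lysis_frac,
                                slope_tol = slope_tol,
                                slope_center = slope_center,
                                depletion_frac = depletion_frac,
                                phage_density_floor = phage_density_floor))
  class(out) <- "pattern_summary"
  out
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("<pattern_summary>\n")
  cat(sprintf("  ring arrival: %.2f h | class: %s (slope %.3f rad/cm) | outcome: %s\n",
              x$arrival_time, x$class,
              ifelse(is.na(x$slope), NA, x$slope), x$outcome))
  if (!is.null(x$initiation))
    cat(sprintf("  initiation zone: t* = %.2f h, equivalent radius %.2f cm\n",
                x$initiation$t_star, x$initiation$equiv_radius))
  th <- vapply(x$profile$theta, function(v) sprintf("%.2f", v), "")
  cat("  theta(r): ", paste(sprintf("%g:%s", x$profile$r, th),
                            collapse = " "), "\n")
  invisible(x)
}
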