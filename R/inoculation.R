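#' Inoculum geometry and load
#'
#' Describes one inoculation: a disk (pipette drop) or a rod (phage-soaked
#' capillary pressed onto the agar) of a given species and total
#' particle/cell count. The inoculum density is the total count divided by
#' the analytic footprint area.
#'
#' @param species `"bacteria"` or `"phage"`.
#' @param total total number of cells / phage particles.
#' @param shape `"disk"` or `"rod"`.
#' @param center length-2 numeric, footprint centre (cm) relative to the
#'   plate centre.
#' @param radius disk radius (cm); required for `shape = "disk"`.
#' @param length,width rod dimensions (cm); required for `shape = "rod"`.
#'   The rod axis runs along y, i.e. perpendicular to an x-axis offset
#'   from the bacterial inoculation point.
#' @return object of class `inoculation_spec`.
#' @export
inoculation_spec <- function(species, total, shape = "disk",
                             center = c(0, 0), radius = NULL,
                             length = NULL, width = NULL) {
  species <- match.arg(species, c("bacteria", "phage"))
  shape <- match.arg(shape, c("disk", "rod"))
  stopifnot(is.numeric(total), length(total) == 1L, total >= 0,
            is.numeric(center), length(center) == 2L)
  if (shape == "disk") {
    if (is.null(radius) || radius <= 0)
      stop("disk inoculum requires a positive 'radius'", call. = FALSE)
    area <- pi * radius^2
  } else {
    if (is.null(length) || is.null(width) || length <= 0 || width <= 0)
      stop("rod inoculum requires positive 'length' and 'width'",
           call. = FALSE)
    area <- length * width
  }
  s <- list(species = species, shape = shape, total = total,
            center = as.numeric(center), radius = radius,
            length = length, width = width, area = area)
  class(s) <- "inoculation_spec"
  s
}

# Outermost distance of the footprint from the plate centre, for the
# inside-the-plate check.
inoc_extent <- function(spec) {
  d <- sqrt(sum(spec$center^2))
  if (spec$shape == "disk") d + spec$radius
  else d + sqrt((spec$length / 2)^2 + (spec$width / 2)^2)
}

# Fractional cell coverage of the footprint, estimated on a 4x4 subgrid
# per cell, so inoculated totals match the nominal count to well under a
# percent even on coarse grids.
inoc_coverage <- function(spec, grid, nsub = 4L) {
  cx <- spec$center[1]; cy <- spec$center[2]
  cov <- matrix(0, grid$nx, grid$ny)
  off <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * grid$h
  inside <- function(x, y) {
    if (spec$shape == "disk") (x - cx)^2 + (y - cy)^2 <= spec$radius^2
    else abs(x - cx) <= spec$width / 2 & abs(y - cy) <= spec$length / 2
  }
  for (ox in off) for (oy in off)
    cov <- cov + inside(grid$xc + ox, grid$yc + oy)
  cov / nsub^2
}

#' Initial field state from inoculation specs
#'
#' Nutrient is uniform at `n0` on the plate; each inoculum adds
#' `total / footprint area` to its species' density, weighted by the
#' fractional coverage of each cell by the footprint shape. Overlapping
#' inocula add. Infected bacteria start at zero.
#'
#' @param grid a [plate_grid()].
#' @param inoculations list of [inoculation_spec()] objects.
#' @param p a [model_params()] object.
#' @param n_init initial nutrient density (um^-2); defaults to `p$n0`.
#' @return a [field_state()] at `t = 0`.
#' @export
build_initial_state <- function(grid, inoculations, p, n_init = p$n0) {
  zero <- matrix(0, grid$nx, grid$ny)
  B <- zero; L <- zero; P <- zero
  n <- zero; n[grid$mask] <- n_init
  for (spec in inoculations) {
    if (!inherits(spec, "inoculation_spec"))
      stop("inoculations must be inoculation_spec objects", call. = FALSE)
    if (inoc_extent(spec) > grid$R_plate)
      stop(sprintf("%s inoculum extends outside the plate (extent %.3g cm > R = %g cm)",
                   spec$species, inoc_extent(spec), grid$R_plate),
           call. = FALSE)
    cov <- inoc_coverage(spec, grid)
    cov[!grid$mask] <- 0
    if (!any(cov > 0))
      stop("inoculum footprint does not cover any grid cell; refine the grid",
           call. = FALSE)
    dens <- spec$total / (spec$area * UM2_PER_CM2)  # um^-2
    if (spec$species == "bacteria") B <- B + dens * cov
    else P <- P + dens * cov
  }
  field_state(0, B, L, P, n, grid)
}
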