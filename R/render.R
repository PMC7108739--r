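#' Render density maps of a field state
#'
#' Writes PNG density maps: total bacteria in grey, phages in red,
#' infected bacteria and nutrient with matching styles, with the plate
#' wall outlined and (optionally) the lysed-region contour overlaid on
#' the bacterial map.
#'
#' @param state a [field_state()].
#' @param dir output directory.
#' @param what fields to render, subset of
#'   `c("bacteria", "infected", "phage", "nutrient")`.
#' @param overlay_lysis draw the lysed-region outline (total bacteria
#'   below 10 percent of its maximum inside the colonised area).
#' @param width,height image size in pixels.
#' @return character vector of files written, invisibly.
#' @export
render_state <- function(state, dir,
                         what = c("bacteria", "infected", "phage",
                                  "nutrient"),
                         overlay_lysis = TRUE,
                         width = 600, height = 600) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- state$grid
  files <- character(0)
  panels <- list(
    bacteria = list(z = state$B + state$L,
                    col = grDevices::gray(seq(1, 0, length.out = 64))),
    infected = list(z = state$L,
                    col = grDevices::gray(seq(1, 0, length.out = 64))),
    phage = list(z = state$P,
                 col = grDevices::colorRampPalette(
                   c("white", "red3"))(64)),
    nutrient = list(z = state$n,
                    col = grDevices::colorRampPalette(
                      c("white", "darkgreen"))(64)))
  for (w in intersect(what, names(panels))) {
    fn <- file.path(dir, sprintf("%s_t%05.2f.png", w, state$t))
    ok <- tryCatch({
      grDevices::png(fn, width, height)
      on.exit(grDevices::dev.off(), add = TRUE)
      z <- panels[[w]]$z
      z[!g$mask] <- NA
      graphics::image(g$x, g$y, z, col = panels[[w]]$col, asp = 1,
                      xlab = "x (cm)", ylab = "y (cm)",
                      main = sprintf("%s, t = %.2f h", w, state$t),
                      useRaster = TRUE)
      tt <- seq(0, 2 * pi, length.out = 256)
      graphics::lines(g$R_plate * cos(tt), g$R_plate * sin(tt))
      if (overlay_lysis && w == "bacteria") {
        tot <- state$B + state$L
        graphics::contour(g$x, g$y, tot, levels = 0.1 * max(tot),
                          add = TRUE, drawlabels = FALSE,
                          col = "green3")
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("rendering %s failed: %s", w,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (ok) files <- c(files, fn)
  }
  invisible(files)
}

#' Render bacterial spatial-flux quiver maps
#'
#' Arrow maps of the combined diffusive + chemotactic flux of total and
#' of infected bacteria, on a subsampled grid; in the default scenario
#' the arrows are non-negligible only at the outer edge of the swim ring
#' (total) and of the lysis area (infected).
#'
#' @param state a [field_state()].
#' @param p a [model_params()] object.
#' @param dir output directory.
#' @param every subsampling stride for arrows.
#' @return files written, invisibly.
#' @export
render_fluxes <- function(state, p, dir, every = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- state$grid
  files <- character(0)
  for (w in c("total", "infected")) {
    X <- if (w == "total") state$B + state$L else state$L
    fl <- bacterial_flux(X, state$n, p, g)
    # face fluxes -> cell-centred vectors
    Jx <- matrix(0, g$nx, g$ny)
    Jx[2:(g$nx - 1), ] <- 0.5 * (fl$Jx[-(g$nx - 1), ] + fl$Jx[-1, ])
    Jy <- matrix(0, g$nx, g$ny)
    Jy[, 2:(g$ny - 1)] <- 0.5 * (fl$Jy[, -(g$ny - 1)] + fl$Jy[, -1])
    ii <- seq(1, g$nx, by = every)
    jj <- seq(1, g$ny, by = every)
    mag <- sqrt(Jx^2 + Jy^2)
    sc <- max(mag)
    fn <- file.path(dir, sprintf("flux_%s_t%05.2f.png", w, state$t))
    ok <- tryCatch({
      grDevices::png(fn, 600, 600)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::plot(NA, xlim = range(g$x), ylim = range(g$y), asp = 1,
                     xlab = "x (cm)", ylab = "y (cm)",
                     main = sprintf("%s bacterial flux, t = %.2f h",
                                    w, state$t))
      tt <- seq(0, 2 * pi, length.out = 256)
      graphics::lines(g$R_plate * cos(tt), g$R_plate * sin(tt))
      if (sc > 0) {
        for (i in ii) for (j in jj) {
          if (!g$mask[i, j] || mag[i, j] < 0.02 * sc) next
          graphics::arrows(g$x[i], g$y[j],
                           g$x[i] + 0.4 * Jx[i, j] / sc,
                           g$y[j] + 0.4 * Jy[i, j] / sc,
                           length = 0.03, col = "blue3")
        }
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("rendering flux %s failed: %s", w,
                      conditionMessage(e)), call. = FALSE)
      FALSE
    })
    if (ok) files <- c(files, fn)
  }
  invisible(files)
}

#' Nutrient profile along the symmetry axis
#'
#' Line plot of the nutrient density along the x axis (the symmetry axis
#' of the standard drop assay).
#'
#' @param state a [field_state()].
#' @param file PNG path.
#' @return `file`, invisibly.
#' @export
render_nutrient_profile <- function(state, file) {
  g <- state$grid
  j <- which.min(abs(g$y))
  ok <- tryCatch({
    grDevices::png(file, 700, 400)
    on.exit(grDevices::dev.off(), add = TRUE)
    sel <- g$mask[, j]
    graphics::plot(g$x[sel], state$n[sel, j], type = "l", col = "orange3",
                   lwd = 2, xlab = "x (cm)",
                   ylab = "nutrient (um^-2)",
                   main = sprintf("nutrient along symmetry axis, t = %.2f h",
                                  state$t))
    TRUE
  }, error = function(e) FALSE)
  invisible(file)
}
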