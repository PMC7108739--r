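#' Model parameters for the phage-bacteria swim-plate model
#'
#' Constructs the full parameter set of the mean-field model: four fields
#' (susceptible bacteria B, infected bacteria L, free phages P, nutrient n)
#' coupled through Keller-Segel motility, Monod growth, density-inhibited
#' phage adsorption, nutrient-gated lysis and nutrient consumption.
#'
#' Units follow the conventions of the source measurements: diffusion
#' coefficients and the lysis rate constant `k_l` are in um^2 h^-1, area
#' densities (`K_v`, `K_c`, `K_n`, `K_b`, `n0`) in um^-2, lengths
#' (`r_inoc`, `R_plate`, `agar_depth`) in cm, and first-order rates in
#' h^-1. Because `n0 = 1 um^-2`, densities expressed in units of `n0`
#' coincide numerically with um^-2; the solver works in those density
#' units and in cm / h for space and time, converting the diffusivities
#' once (see [internal_params()]).
#'
#' The adsorption rate constant `eta` is a volumetric second-order
#' constant in um^3 h^-1 (its default, 8e4 um^3 h^-1, equals the
#' classical measured phage adsorption constant of about 1.3e-9 ml/min).
#' The model's fields are area densities in the agar layer, so every rate
#' law uses the depth-converted two-dimensional constant
#' `eta / agar_depth` (16 um^2 h^-1 at defaults), the same volume-to-area
#' conversion applied to the experimental plug counts. See the methods
#' vignette for why the literal two-dimensional reading is untenable.
#'
#' @param D_Bmax maximum bacterial diffusion coefficient, um^2 h^-1.
#' @param K_v nutrient level for half-maximum motility, um^-2.
#' @param K_c nutrient level for half-maximum chemotactic efficiency, um^-2.
#' @param alpha_c chemotactic efficiency (dimensionless).
#' @param D_P phage diffusion coefficient, um^2 h^-1.
#' @param D_n nutrient diffusion coefficient, um^2 h^-1.
#' @param eta phage adsorption rate constant, um^3 h^-1 (volumetric; the
#'   rate laws use `eta / agar_depth`).
#' @param beta phage burst size (progeny per lysed cell).
#' @param k_l lysis rate constant of infected bacteria, um^2 h^-1 (the
#'   effective lysis rate is `k_l * n`, about the inverse latent period at
#'   full nutrient).
#' @param g_max maximum bacterial division rate, h^-1.
#' @param K_n Monod half-saturation nutrient level, um^-2.
#' @param lam growth yield factor multiplying nutrient consumption
#'   (dimensionless).
#' @param K_b bacterial density for half-maximum phage adsorption, um^-2.
#' @param B0 number of inoculated bacteria.
#' @param P0 number of inoculated phage particles.
#' @param n0 initial nutrient area density, um^-2.
#' @param r_inoc radius of the inoculation disks, cm.
#' @param R_plate plate radius, cm.
#' @param agar_depth agar layer thickness, cm; converts volumetric
#'   quantities to areal ones.
#' @param ablate_nutrient_gating if `TRUE`, disable the nutrient dependence
#'   of motility and lysis: the motility factor becomes 1 and the lysis rate
#'   uses the constant `n0` in place of the local nutrient level.
#' @param ablate_density_inhibition if `TRUE`, disable the bacterial-density
#'   inhibition of phage adsorption: the factor `K_b/(B+L+K_b)` becomes 1.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' monod_growth(p$K_n, p)  # half-saturation: g_max / 2
#' @export
model_params <- function(D_Bmax = 5.25e5, K_v = 0.001, K_c = 0.02,
                         alpha_c = 2, D_P = 1, D_n = 4.5e6, eta = 8e4,
                         beta = 80, k_l = 2, g_max = 6, K_n = 0.1,
                         lam = 0.2, K_b = 0.1, B0 = 1e7, P0 = 1.5e8,
                         n0 = 1, r_inoc = 0.25, R_plate = 5.5,
                         agar_depth = 0.5,
                         ablate_nutrient_gating = FALSE,
                         ablate_density_inhibition = FALSE) {
  p <- list(D_Bmax = D_Bmax, K_v = K_v, K_c = K_c, alpha_c = alpha_c,
            D_P = D_P, D_n = D_n, eta = eta, beta = beta, k_l = k_l,
            g_max = g_max, K_n = K_n, lam = lam, K_b = K_b,
            B0 = B0, P0 = P0, n0 = n0, r_inoc = r_inoc, R_plate = R_plate,
            agar_depth = agar_depth,
            ablate_nutrient_gating = isTRUE(ablate_nutrient_gating),
            ablate_density_inhibition = isTRUE(ablate_density_inhibition))
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  for (k in num) cat(sprintf("  %-10s %g\n", k, x[[k]]))
  cat(sprintf("  ablations: nutrient_gating=%s density_inhibition=%s\n",
              x$ablate_nutrient_gating, x$ablate_density_inhibition))
  invisible(x)
}

param_names <- function() {
  c("D_Bmax", "K_v", "K_c", "alpha_c", "D_P", "D_n", "eta", "beta", "k_l",
    "g_max", "K_n", "lam", "K_b", "B0", "P0", "n0", "r_inoc", "R_plate",
    "agar_depth", "ablate_nutrient_gating", "ablate_density_inhibition")
}

validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  pos <- c("D_Bmax", "K_v", "K_c", "alpha_c", "D_P", "D_n", "eta", "beta",
           "k_l", "g_max", "K_n", "lam", "K_b", "B0", "P0", "n0", "r_inoc",
           "R_plate", "agar_depth")
  for (k in pos) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive finite number (got %s)",
                   k, format(p[[k]])), call. = FALSE)
  }
  if (p$beta < 1) stop("burst size 'beta' must be >= 1", call. = FALSE)
  if (p$r_inoc >= p$R_plate)
    stop("inoculation radius 'r_inoc' must be smaller than 'R_plate'",
         call. = FALSE)
  invisible(p)
}

# Conversion between the um-based measurement units and the cm/h solver
# units. Reaction terms are closed in (um^-2, h) units, so only the
# diffusivities need rescaling: 1 um^2 = 1e-8 cm^2. Densities in um^-2
# convert to cm^-2 with the factor 1e8.
UM2_PER_CM2 <- 1e8

#' Solver-unit view of a parameter set
#'
#' Returns the parameters with all diffusivities converted to cm^2 h^-1
#' and the volumetric adsorption constant converted to its areal
#' equivalent `eta / agar_depth` (um^2 h^-1); this is the single
#' unit-conversion point of the package. All other entries are untouched:
#' the remaining rate constants are dimensionally closed when densities
#' are carried in um^-2.
#'
#' @param p a [model_params()] object.
#' @return a plain named list with `D_Bmax`, `D_P`, `D_n` in cm^2 h^-1
#'   and `eta` in um^2 h^-1.
#' @export
internal_params <- function(p) {
  validate_params(p)
  q <- unclass(p)
  q$D_Bmax <- p$D_Bmax * 1e-8
  q$D_P <- p$D_P * 1e-8
  q$D_n <- p$D_n * 1e-8
  q$eta <- eta_areal(p)
  q
}

# depth-converted 2D adsorption constant, um^2 h^-1 (1 cm = 1e4 um)
eta_areal <- function(p) p$eta / (p$agar_depth * 1e4)
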