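#' Monod division rate of susceptible bacteria
#'
#' `g(n) = g_max * n / (n + K_n)`; the division rate saturates at `g_max`
#' and halves at `n = K_n`.
#'
#' @param n nutrient area density (um^-2), scalar or array, `>= 0`.
#' @param p a [model_params()] object.
#' @return division rate in h^-1, same shape as `n`.
#' @export
monod_growth <- function(n, p) {
  check_nonneg(n, "n")
  p$g_max * n / (n + p$K_n)
}

#' Nutrient gating factor of bacterial motility
#'
#' Both diffusion and chemotactic drift of bacteria are multiplied by
#' `nu(n) = (n / (n + K_v))^2`: swimming requires energy, so motility
#' shuts down as nutrient is depleted. With the nutrient-gating ablation
#' the factor is identically 1.
#'
#' @inheritParams monod_growth
#' @return dimensionless factor in `[0, 1]`, same shape as `n`.
#' @export
motility_factor <- function(n, p) {
  check_nonneg(n, "n")
  if (p$ablate_nutrient_gating) {
    out <- n
    out[] <- 1
    return(out)
  }
  (n / (n + p$K_v))^2
}

#' Phage adsorption (infection) rate density
#'
#' Rate at which susceptible bacteria are converted to infected bacteria,
#' `eta_2d * K_b/(B + L + K_b) * B * P`, where `eta_2d = eta/agar_depth`
#' is the depth-converted adsorption constant (see [model_params()]). The
#' factor `K_b/(B+L+K_b)` encodes density inhibition of adsorption
#' (quorum-sensing-like reduction of receptor availability at high cell
#' density); the density-inhibition ablation replaces it by 1.
#'
#' @param B,L,P susceptible, infected and phage area densities (um^-2).
#' @param p a [model_params()] object.
#' @return conversion rate density (um^-2 h^-1), same shape as inputs.
#' @export
adsorption_conversion <- function(B, L, P, p) {
  check_nonneg(B, "B"); check_nonneg(L, "L"); check_nonneg(P, "P")
  eta_areal(p) * adsorption_factor(B, L, p) * B * P
}

adsorption_factor <- function(B, L, p) {
  if (p$ablate_density_inhibition) {
    out <- B + L
    out[] <- 1
    return(out)
  }
  p$K_b / (B + L + p$K_b)
}

#' Lysis rate density of infected bacteria
#'
#' `k_l * L * n`: phage assembly requires energy, so the latent period
#' elongates (the lysis rate drops) as nutrient is depleted. With the
#' nutrient-gating ablation the local nutrient is replaced by the
#' constant `n0`, which preserves units and removes the dependence.
#'
#' @param L infected-bacteria area density (um^-2).
#' @param n nutrient area density (um^-2).
#' @param p a [model_params()] object.
#' @return lysis rate density (um^-2 h^-1).
#' @export
lysis_rate <- function(L, n, p) {
  check_nonneg(L, "L"); check_nonneg(n, "n")
  if (p$ablate_nutrient_gating) p$k_l * L * p$n0 else p$k_l * L * n
}

#' Local (non-spatial) time derivatives of the four fields
#'
#' Evaluates the reaction part of the model at each point:
#' \itemize{
#'   \item `dB = -adsorption + g(n) B` (infection loss, Monod growth)
#'   \item `dL = +adsorption - k_l L n` (infection gain, lysis loss)
#'   \item `dP = -eta_2d K_b/(B+L+K_b) (B+L) P + beta k_l L n`
#'     (multi-adsorption onto both susceptible and infected cells,
#'      burst production)
#'   \item `dn = -lam g(n) (B+L)` (consumption by all bacteria)
#' }
#' There is no phage decay term and infected cells do not divide.
#'
#' @param s a [field_state()] or a list with numeric `B`, `L`, `P`, `n`
#'   of a common shape (um^-2).
#' @param p a [model_params()] object.
#' @return list with `dB`, `dL`, `dP`, `dn` (um^-2 h^-1).
#' @export
reaction_terms <- function(s, p) {
  B <- s$B; L <- s$L; P <- s$P; n <- s$n
  for (nm in c("B", "L", "P", "n")) {
    v <- s[[nm]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
      stop(sprintf("field '%s' must be finite numeric", nm), call. = FALSE)
  }
  check_nonneg(B, "B"); check_nonneg(L, "L")
  check_nonneg(P, "P"); check_nonneg(n, "n")
  ads <- adsorption_conversion(B, L, P, p)
  lys <- lysis_rate(L, n, p)
  g <- monod_growth(n, p)
  list(dB = -ads + g * B,
       dL = ads - lys,
       dP = -eta_areal(p) * adsorption_factor(B, L, p) * (B + L) * P +
         p$beta * lys,
       dn = -p$lam * g * (B + L))
}

#' Bacterial spatial flux on cell faces
#'
#' Finite-volume face fluxes of a bacterial field (B or L):
#' `J = -D_Bmax nu(n) grad X + D_Bmax alpha_c nu(n) K_c/(n+K_c)^2 X grad n`,
#' i.e. nutrient-gated diffusion plus chemotactic drift up the nutrient
#' gradient. Face coefficients are arithmetic means of the two adjacent
#' cell values; gradients are central differences over one spacing. Fluxes
#' across the domain mask boundary are zero (no-flux plate wall).
#'
#' @param X bacterial density matrix (um^-2), `nx x ny`.
#' @param n nutrient density matrix, same shape.
#' @param p a [model_params()] object.
#' @param grid a [plate_grid()] matching the field shape.
#' @param upwind if `TRUE` the advective part uses first-order upwinding
#'   (the solver's scheme); otherwise the face-centred average of `X`.
#' @return list `Jx` (`(nx-1) x ny`, flux in +x across vertical interior
#'   faces) and `Jy` (`nx x (ny-1)`, flux in +y), in density * cm / h.
#' @export
bacterial_flux <- function(X, n, p, grid, upwind = TRUE) {
  if (!all(dim(X) == c(grid$nx, grid$ny)) || !all(dim(n) == dim(X)))
    stop("field shape does not match grid", call. = FALSE)
  q <- internal_params(p)
  h <- grid$h
  nu <- motility_factor(n, p)
  chi <- q$D_Bmax * q$alpha_c * q$K_c / (n + q$K_c)^2  # per-cell drift coef
  msk <- grid$mask
  nx <- grid$nx; ny <- grid$ny

  face_flux <- function(i1, i2) {
    # i1, i2: index matrices of the two cells sharing each face
    open <- msk[i1] & msk[i2]
    nu_f <- 0.5 * (nu[i1] + nu[i2])
    dn <- (n[i2] - n[i1]) / h
    u <- 0.5 * (chi[i1] * nu[i1] + chi[i2] * nu[i2]) * dn  # drift velocity
    Xf <- if (upwind) ifelse(u > 0, X[i1], X[i2]) else 0.5 * (X[i1] + X[i2])
    J <- -q$D_Bmax * nu_f * (X[i2] - X[i1]) / h + u * Xf
    J[!open] <- 0
    J
  }
  ix1 <- cbind(rep(seq_len(nx - 1), ny), rep(seq_len(ny), each = nx - 1))
  ix2 <- cbind(ix1[, 1] + 1L, ix1[, 2])
  iy1 <- cbind(rep(seq_len(nx), ny - 1), rep(seq_len(ny - 1), each = nx))
  iy2 <- cbind(iy1[, 1], iy1[, 2] + 1L)
  list(Jx = matrix(face_flux(ix1, ix2), nx - 1, ny),
       Jy = matrix(face_flux(iy1, iy2), nx, ny - 1))
}

check_nonneg <- function(x, name) {
  if (anyNA(x) || any(x < 0))
    stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  invisible(x)
}
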