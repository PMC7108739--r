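#' Well-mixed (0-D) reference trajectory
#'
#' Integrates the reaction system with all spatial terms removed, using an
#' adaptive embedded Runge-Kutta method (Cash-Karp 4(5)) with tight
#' tolerances. This is the package's reference oracle: on a spatially
#' uniform state with no-flux boundaries the PDE stepper must reproduce it,
#' because every transport term then vanishes identically.
#'
#' @param init named numeric vector or list with entries `B`, `L`, `P`,
#'   `n` (um^-2), all nonnegative.
#' @param p a [model_params()] object.
#' @param T duration (h).
#' @param dt_out output sampling interval (h); the trajectory is reported
#'   at `seq(0, T, by = dt_out)` (plus `T`).
#' @param rtol,atol relative/absolute local error tolerances.
#' @return data.frame with columns `t`, `B`, `L`, `P`, `n`.
#' @export
well_mixed_trajectory <- function(init, p, T, dt_out = T / 100,
                                  rtol = 1e-10, atol = 1e-14) {
  y0 <- unlist(init[c("B", "L", "P", "n")])
  if (anyNA(y0) || any(y0 < 0))
    stop("initial densities must be nonnegative and complete", call. = FALSE)
  stopifnot(T >= 0, dt_out > 0)
  t_out <- unique(c(seq(0, T, by = dt_out), T))
  f <- function(y) {
    y <- pmax(y, 0)  # guard round-off negatives inside stage evaluations
    s <- list(B = y[1], L = y[2], P = y[3], n = y[4])
    d <- reaction_terms(s, p)
    c(d$dB, d$dL, d$dP, d$dn)
  }
  out <- rk45_dense(f, y0, t_out, rtol, atol)
  data.frame(t = t_out, B = out[, 1], L = out[, 2], P = out[, 3],
             n = out[, 4])
}

# Cash-Karp embedded RK4(5) with step-size control and output by
# integration to each requested time (steps never straddle an output time).
rk45_dense <- function(f, y0, t_out, rtol, atol) {
  a <- list(c2 = 1 / 5, c3 = 3 / 10, c4 = 3 / 5, c5 = 1, c6 = 7 / 8)
  b21 <- 1 / 5
  b31 <- 3 / 40; b32 <- 9 / 40
  b41 <- 3 / 10; b42 <- -9 / 10; b43 <- 6 / 5
  b51 <- -11 / 54; b52 <- 5 / 2; b53 <- -70 / 27; b54 <- 35 / 27
  b61 <- 1631 / 55296; b62 <- 175 / 512; b63 <- 575 / 13824
  b64 <- 44275 / 110592; b65 <- 253 / 4096
  c5th <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4th <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296,
            277 / 14336, 1 / 4)

  y <- y0
  t <- t_out[1]
  hstep <- max(diff(t_out)[1] / 10, 1e-8)
  res <- matrix(NA_real_, length(t_out), length(y0))
  res[1, ] <- y0
  for (k in seq_along(t_out)[-1]) {
    tk <- t_out[k]
    while (t < tk - 1e-14) {
      hstep <- min(hstep, tk - t)
      k1 <- f(y)
      k2 <- f(y + hstep * b21 * k1)
      k3 <- f(y + hstep * (b31 * k1 + b32 * k2))
      k4 <- f(y + hstep * (b41 * k1 + b42 * k2 + b43 * k3))
      k5 <- f(y + hstep * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4))
      k6 <- f(y + hstep * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 +
                             b65 * k5))
      y5 <- y + hstep * (c5th[1] * k1 + c5th[3] * k3 + c5th[4] * k4 +
                           c5th[6] * k6)
      y4 <- y + hstep * (c4th[1] * k1 + c4th[3] * k3 + c4th[4] * k4 +
                           c4th[5] * k5 + c4th[6] * k6)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err)) {
        hstep <- hstep / 10
        if (hstep < 1e-14)
          stop("well-mixed integration failed: non-finite error estimate",
               call. = FALSE)
        next
      }
      if (err <= 1) {
        t <- t + hstep
        y <- y5
        hstep <- hstep * min(5, max(0.2, 0.9 * err^(-0.2)))
      } else {
        hstep <- hstep * max(0.1, 0.9 * err^(-0.25))
        if (hstep < 1e-14)
          stop(sprintf("well-mixed integration failed near t = %g: step underflow", t),
               call. = FALSE)
      }
    }
    res[k, ] <- y
  }
  res
}
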