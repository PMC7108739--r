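# Shared fixtures: all inputs are generated in code; expensive reference
# runs are computed once per session and memoised here.

# several acceptance sub-claims are documented expected failures; keep the
# runner from truncating the remaining files when it meets them
options(testthat.progress.max_fails = 100L)

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, maker(), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# standard drop assay (bacteria centre, phage at d on +x), full plate
default_run <- function(h = 0.1) {
  cached(sprintf("default_%g", h), function() {
    run_simulation(drop_assay_config(h = h))
  })
}

variant_run <- function(tag, params = model_params(), T = 14, d = 1,
                        P0 = NULL, nmult = 1, h = 0.1,
                        rod_length = NULL, snapshot_by = 1) {
  cached(tag, function() {
    run_simulation(drop_assay_config(params = params, d = d, h = h, T = T,
                                     P0 = P0, rod_length = rod_length,
                                     n_init_mult = nmult,
                                     snapshot_by = snapshot_by))
  })
}

no_phage_run <- function() {
  cached("no_phage", function() {
    run_simulation(drop_assay_config(d = NULL, T = 14, snapshot_by = 1))
  })
}

concentric_run <- function(h = 0.05) {
  cached(sprintf("concentric_%g", h), function() {
    run_simulation(drop_assay_config(d = 0, h = h, snapshot_by = 1))
  })
}

# initiation-zone run: stops exactly at the 5% depletion time
t1_run <- function(h = 0.05) {
  cached(sprintf("t1_%g", h), function() {
    cfg <- drop_assay_config(h = h, T = 10, snapshot_by = 0.5,
                             stop_depletion_frac = 0.05)
    run_simulation(cfg)
  })
}

# small plate for cheap solver/io tests (seconds, not minutes)
mini_config <- function(T = 2, h = 0.1, d = 0.5, ...) {
  p <- model_params(R_plate = 1.5)
  drop_assay_config(params = p, d = d, h = h, T = T, snapshot_by = 0.5,
                    ...)
}

mini_run <- function() {
  cached("mini", function() run_simulation(mini_config()))
}

# uniform no-flux state on a tiny plate: transport vanishes identically
uniform_state <- function(B = 0.01, L = 0, P = 0.001, n = 1, h = 0.1,
                          R = 0.45) {
  g <- plate_grid(h, R)
  z <- matrix(0, g$nx, g$ny)
  mk <- function(v) { m <- z; m[g$mask] <- v; m }
  field_state(0, mk(B), mk(L), mk(P), mk(n), g)
}

# independently coded fixed-step RK4 on the reaction ODEs (the dual
# implementation used to validate well_mixed_trajectory); deliberately
# written from the model formulas, not via reaction_terms()
rk4_reference <- function(y0, p, T, nstep, times = NULL) {
  eta2 <- p$eta / (p$agar_depth * 1e4)
  f <- function(y) {
    b <- y[1]; l <- y[2]; pp <- y[3]; n <- y[4]
    af <- p$K_b / (b + l + p$K_b)
    a <- eta2 * af
    g <- p$g_max * n / (n + p$K_n)
    d <- p$k_l * n
    c(-a * b * pp + g * b,
      a * b * pp - d * l,
      -a * (b + l) * pp + p$beta * d * l,
      -p$lam * g * (b + l))
  }
  y <- y0
  h <- T / nstep
  out <- list()
  for (k in seq_len(nstep)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- k * h
    if (!is.null(times) && any(abs(times - t) < h / 2))
      out[[length(out) + 1]] <- c(t = t, y)
  }
  if (is.null(times)) y else do.call(rbind, out)
}

# relative difference with an absolute floor (fields can underflow)
rel_err <- function(a, b, floor = 1e-10) abs(a - b) / (abs(b) + floor)
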