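test_that("initial state reproduces the inoculated totals", {
  p <- model_params()
  g <- plate_grid(0.05, p$R_plate)
  inocs <- list(
    inoculation_spec("bacteria", p$B0, center = c(0, 0), radius = p$r_inoc),
    inoculation_spec("phage", p$P0, center = c(1, 0), radius = p$r_inoc))
  s <- build_initial_state(g, inocs, p)
  tot <- field_totals(s)
  expect_lt(abs(tot[["B"]] - p$B0) / p$B0, 0.01)
  expect_lt(abs(tot[["P"]] - p$P0) / p$P0, 0.01)
  expect_true(all(s$L == 0))
  expect_equal(max(s$n), p$n0)

  # no phage inoculum -> P identically zero
  s0 <- build_initial_state(g, inocs[1], p)
  expect_true(all(s0$P == 0))

  # rod inoculum: total normalised by construction
  rod <- inoculation_spec("phage", p$P0, shape = "rod",
                          center = c(0.5, 0), length = 1.5, width = 0.1)
  s1 <- build_initial_state(g, list(inocs[[1]], rod), p)
  expect_lt(abs(field_totals(s1)[["P"]] - p$P0) / p$P0, 0.01)

  # overlapping inocula add
  s2 <- build_initial_state(g, list(inocs[[1]], inocs[[1]]), p)
  expect_equal(max(s2$B), 2 * max(s$B))

  out <- inoculation_spec("phage", 1e5, center = c(5.4, 0), radius = 0.25)
  expect_error(build_initial_state(g, list(inocs[[1]], out), p),
               "outside the plate")
})

test_that("stable_dt combines diffusive, advective and reaction bounds", {
  p <- model_params()
  g <- plate_grid(0.05, 1.5)
  z <- matrix(0, g$nx, g$ny)
  empty <- field_state(0, z, z, z, z, g)
  # all fields zero: diffusive bound from D_n only
  expect_equal(stable_dt(p, g, empty, safety = 1),
               g$h^2 / (4 * 4.5e-2))
  expect_equal(stable_dt(p, g, empty, safety = 0.8),
               0.8 * 0.05^2 / (4 * 4.5e-2))  # = 0.8 * 0.0139

  # dense random state: reaction bound matches a brute-force per-cell scan
  set.seed(11)
  mk <- function(lim) { m <- z; m[g$mask] <- runif(sum(g$mask), 0, lim); m }
  s <- field_state(0, mk(6), mk(2), mk(20), mk(1), g)
  got <- stable_dt(p, g, s, safety = 1, include_reaction = TRUE)
  eta2 <- p$eta / (p$agar_depth * 1e4)
  rmax <- 0
  for (k in which(g$mask)) {
    B <- s$B[k]; L <- s$L[k]; P <- s$P[k]; n <- s$n[k]
    af <- p$K_b / (B + L + p$K_b)
    rmax <- max(rmax, eta2 * af * P, eta2 * af * (B + L),
                p$g_max * n / (n + p$K_n), p$k_l * n,
                p$lam * p$g_max * (B + L) / (n + p$K_n))
  }
  expect_lte(got, 1 / rmax + 1e-12)
  # and it is exactly the min over all three bound families
  diff_bound <- g$h^2 / (4 * max(4.5e-2, 5.25e-3 *
                                   max(motility_factor(s$n, p)[g$mask])))
  expect_equal(got, min(diff_bound, 1 / rmax,
                        g$h / phagesector:::drift_speed_max(s$n, p, g)))
})

test_that("a uniform no-flux state follows the well-mixed oracle", {
  p <- model_params()
  s <- uniform_state()
  g <- s$grid
  # one step
  s1 <- step_state(s, p, g, 0.02, rxn_rtol = 1e-8, rho_cut = 0)
  ref1 <- well_mixed_trajectory(c(B = 0.01, L = 0, P = 0.001, n = 1), p,
                                T = 0.02, dt_out = 0.02)
  i <- which(g$mask)[1]
  for (f in c("B", "L", "P", "n")) {
    expect_lt(rel_err(s1[[f]][i], ref1[[f]][2]), 1e-6)
    # spatial uniformity is preserved exactly (transport cancels)
    expect_equal(diff(range(s1[[f]][g$mask])), 0)
  }
})

test_that("phage-free fields stay phage-free and nutrient mass is conserved", {
  p <- model_params()
  g <- plate_grid(0.1, 0.6)
  z <- matrix(0, g$nx, g$ny)
  B <- z; B[g$mask] <- 0.2
  n <- z; n[g$mask] <- 1
  s <- field_state(0, B, z, z, n, g)
  for (k in 1:5) s <- step_state(s, p, g, 0.02)
  expect_true(all(s$P == 0))
  expect_true(all(s$L == 0))

  # pure diffusion of a nutrient bump: conservative to round-off
  nb <- z; nb[g$mask] <- exp(-(g$r[g$mask] / 0.2)^2)
  s2 <- field_state(0, z, z, z, nb, g)
  total0 <- sum(s2$n)
  for (k in 1:10) s2 <- step_state(s2, p, g, 0.01)
  expect_lt(abs(sum(s2$n) - total0) / total0, 1e-10)
  expect_true(all(s2$n >= 0))
})

test_that("runs are deterministic, hit snapshot times exactly, and T = 0 is the initial state", {
  cfg <- mini_config()
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$times, t2$times)
  for (k in seq_along(t1$snapshots))
    for (f in c("B", "L", "P", "n"))
      expect_identical(t1$snapshots[[k]][[f]], t2$snapshots[[k]][[f]])
  expect_identical(t1$times, seq(0, 2, by = 0.5))

  cfg0 <- mini_config(T = 0)
  tr0 <- run_simulation(cfg0)
  expect_length(tr0$snapshots, 1)
  s0 <- build_initial_state(tr0$grid, cfg0$inoculations, cfg0$params)
  expect_identical(final_state(tr0)$B, s0$B)
})

test_that("mirror-symmetric inocula stay mirror-symmetric", {
  traj <- mini_run()
  s <- final_state(traj)
  ny <- traj$grid$ny
  for (f in c("B", "L", "P", "n")) {
    M <- s[[f]]
    expect_lt(max(abs(M - M[, ny:1])) / max(M, 1e-300), 1e-8)
  }
})

test_that("nutrient total decreases and positivity diagnostics stay clean", {
  traj <- mini_run()
  tot_n <- vapply(traj$snapshots, function(s) sum(s$n), numeric(1))
  expect_true(all(diff(tot_n) <= 1e-12 * tot_n[1]))
  for (s in traj$snapshots) {
    expect_true(all(s$B >= 0) && all(s$L >= 0) &&
                  all(s$P >= 0) && all(s$n >= 0))
  }
  tot0 <- sum(field_totals(traj$snapshots[[1]])[c("B", "P")])
  expect_lt(traj$diagnostics$clamped_mass * 1e8 / tot0, 1e-6)
})

test_that("depletion stop captures the probe crossing", {
  cfg <- mini_config(T = 8, stop_depletion_frac = 0.05)
  traj <- run_simulation(cfg)
  expect_true(traj$diagnostics$stopped_depleted)
  pn <- traj$diagnostics$probe_n
  expect_lt(pn[length(pn)], 0.05 * cfg$params$n0)
  expect_gte(pn[length(pn) - 1], 0.05 * cfg$params$n0 * 0.5)
  expect_lt(max(traj$times), 8)
})
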