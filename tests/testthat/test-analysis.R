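test_that("front radius: inoculum, uniform lawn and empty field", {
  p <- model_params()
  g <- plate_grid(0.1, p$R_plate)
  inocs <- list(inoculation_spec("bacteria", p$B0, center = c(0, 0),
                                 radius = p$r_inoc))
  s0 <- build_initial_state(g, inocs, p)
  expect_lt(abs(front_radius(s0) - p$r_inoc), g$h + 1e-9)

  z <- matrix(0, g$nx, g$ny)
  B <- z; B[g$mask] <- 1
  sU <- field_state(0, B, z, z, z + ifelse(g$mask, 1, 0), g)
  expect_lt(abs(front_radius(sU) - p$R_plate), g$h + 1e-9)

  sE <- field_state(0, z, z, z, z, g)
  fr <- front_radius(sE)
  expect_true(is.na(fr))
  expect_identical(attr(fr, "flag"), "empty")
})

test_that("front radius is nondecreasing along a phage-free expansion", {
  traj <- no_phage_run()
  fr <- vapply(traj$snapshots, front_radius, numeric(1))
  expect_true(all(diff(fr) >= -traj$grid$h / 2))
  expect_gt(fr[length(fr)], fr[1])
})

test_that("ring arrival interpolates and flags truncated trajectories", {
  traj <- no_phage_run()
  arr <- ring_arrival_time(traj)
  expect_true(is.finite(arr))
  fr <- attr(arr, "front_radii")
  k <- which(fr$r >= 0.95 * traj$grid$R_plate)[1]
  expect_gte(arr, fr$t[k - 1])
  expect_lte(arr, fr$t[k])

  short <- traj
  short$times <- traj$times[1:2]
  short$snapshots <- traj$snapshots[1:2]
  arr2 <- ring_arrival_time(short)
  expect_identical(as.numeric(arr2), Inf)
  expect_identical(attr(arr2, "flag"), "not_reached")
})

test_that("initiation zone requires phages and flags missing depletion", {
  expect_error(initiation_zone(no_phage_run()), "phage inoculum")
  # depletion not reached in a very short run
  short <- run_simulation(mini_config(T = 0.5))
  iz <- initiation_zone(short)
  expect_true("depletion_not_reached" %in% iz$flags)
  expect_true(is.na(iz$equiv_radius))
})

test_that("sector angle profile handles controls and synthetic geometries", {
  # phage-free run: no lysed arc anywhere
  s <- final_state(no_phage_run())
  prof <- sector_angle_profile(s, radii = c(2, 3, 4))
  expect_true(all(prof$theta[prof$valid] == 0))

  # synthetic half-plane lysis: theta = pi at any colonised radius
  g <- plate_grid(0.05, 3)
  z <- matrix(0, g$nx, g$ny)
  B <- z; B[g$mask] <- ifelse(g$yc[g$mask] > 0, 1, 0.001)
  st <- field_state(0, B, z, z, z, g)
  pr <- sector_angle_profile(st, radii = c(1, 1.5, 2))
  expect_true(all(abs(pr$theta - pi) < 0.2))

  # fully lysed disk (concentric-style): theta = 2*pi inside it,
  # provided infected remnants mark the area as colonised
  B2 <- z; L2 <- z
  inside <- g$r <= 1 & g$mask
  B2[g$mask] <- 1; B2[inside] <- 1e-4
  L2[inside] <- 0.5
  st2 <- field_state(0, B2, L2, z, z, g)
  pr2 <- sector_angle_profile(st2, radii = c(0.5, 2))
  expect_equal(pr2$theta[1], 2 * pi)
  expect_equal(pr2$theta[2], 0)

  # annulus beyond the colonised area is flagged invalid
  pr3 <- sector_angle_profile(st2, radii = c(3.2))
  expect_false(pr3$valid[1])
})

test_that("pattern classification follows the slope band", {
  prof <- function(theta) data.frame(r = seq(1.5, 4.5, by = 0.5),
                                     theta = theta, valid = TRUE)
  # constant profile: straight
  expect_identical(as.character(classify_pattern(prof(rep(1.2, 7)))),
                   "straight")
  up <- classify_pattern(prof(seq(1, 2.8, length.out = 7)))
  expect_identical(as.character(up), "flared_out")
  expect_equal(attr(up, "slope"), 0.6)
  down <- classify_pattern(prof(seq(2.8, 1, length.out = 7)))
  expect_identical(as.character(down), "closed_up")
  # calibrated band recentres the straight class
  expect_identical(
    as.character(classify_pattern(prof(seq(1, 2.2, length.out = 7)),
                                  slope_tol = 0.2, slope_center = 0.4)),
    "straight")
  # all-zero profile: no sector, straight by convention
  z <- classify_pattern(prof(rep(0, 7)))
  expect_identical(as.character(z), "straight")
  expect_identical(attr(z, "note"), "no_sector")
  # too few radii
  few <- data.frame(r = 1:3, theta = 1, valid = c(TRUE, TRUE, FALSE))
  expect_identical(as.character(classify_pattern(few)), "unclassified")
})

test_that("co-propagation outcome flags phage-free runs", {
  expect_identical(copropagation_outcome(no_phage_run()), "no_phage")
})

test_that("region sampling returns converted area densities", {
  g <- plate_grid(0.1, 5.5)
  z <- matrix(0, g$nx, g$ny)
  B <- z; B[g$mask & g$r < 1] <- 0.5
  P <- z; P[g$mask & g$r < 1] <- 2
  n <- z; n[g$mask] <- 1
  st <- field_state(0, B, z, P, n, g)
  tab <- sample_regions(st, list(core = c(0, 0), agar = c(0, 4)),
                        plug_radius = 0.3)
  expect_equal(tab$bacteria[tab$region == "core"], 0.5 * 1e8)
  expect_equal(tab$phage[tab$region == "core"], 2 * 1e8)
  expect_identical(tab$bacteria[tab$region == "agar"], 0)
  expect_identical(tab$phage[tab$region == "agar"], 0)
  expect_error(sample_regions(st, list(c(6, 0))), "outside")
  expect_length(fig_region_centers(), 6)
})

test_that("flood fill finds 4-connected components", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- m[2, 3] <- m[3, 3] <- TRUE
  m[5, 5] <- TRUE  # disconnected
  ff <- phagesector:::flood_fill(m, 2, 2)
  expect_equal(sum(ff), 3)
  expect_false(ff[5, 5])
  expect_equal(sum(phagesector:::flood_fill(m, 1, 1)), 0)
})

test_that("classification is robust to the lysis detection threshold", {
  s <- final_state(default_run(h = 0.1))
  classes <- vapply(c(0.05, 0.1, 0.2), function(lf) {
    pr <- sector_angle_profile(s, lysis_frac = lf)
    as.character(classify_pattern(pr, slope_tol = 0.2, slope_center = 0.4))
  }, character(1))
  expect_length(unique(classes), 1)
  expect_identical(classes[1], "straight")
})
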