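test_that("presets materialise the documented scenarios", {
  cfg <- preset("fig1")
  expect_s3_class(cfg, "simulation_config")
  pc <- phagesector:::phage_center_of(cfg)
  expect_equal(pc, c(1, 0))
  expect_equal(cfg$T, 14)

  sp <- preset("fig2a", full = TRUE)
  expect_s3_class(sp, "sweep_spec")
  expect_equal(sp$axes$d, c(0.5, 1, 1.5, 2, 2.5))
  # the five configs differ only in the phage offset
  cfgs <- lapply(sp$axes$d, function(d)
    phagesector:::config_for_row(sp, list(d = d)))
  offs <- vapply(cfgs, function(cf)
    phagesector:::phage_center_of(cf)[1], numeric(1))
  expect_equal(offs, c(0.5, 1, 1.5, 2, 2.5))
  for (cf in cfgs) {
    expect_identical(unclass(cf$params), unclass(cfgs[[1]]$params))
    expect_identical(cf$T, cfgs[[1]]$T)
  }

  ab <- preset("s1_ablation_i")
  expect_true(ab$params$ablate_nutrient_gating)
  ab2 <- preset("s1_ablation_ii")
  expect_true(ab2$params$ablate_density_inhibition)

  # factor axes scale the parameter multiplicatively
  sp3 <- preset("fig3a")
  cfg3 <- phagesector:::config_for_row(sp3, list(g_max_factor = 1.5,
                                                 eta_factor = 2))
  expect_equal(cfg3$params$g_max, 9)
  expect_equal(cfg3$params$eta, 1.6e5)
  # slow-ring cells get more time
  cfg3b <- phagesector:::config_for_row(sp3, list(g_max_factor = 2 / 3,
                                                  eta_factor = 1))
  expect_equal(cfg3b$T, 24)

  expect_error(preset("fig99"), "unknown preset")
})

test_that("sweep spec validates axes and the runner records failures", {
  base <- mini_config(T = 1.5)
  expect_error(sweep_spec(base, list(not_a_param = 1:2)), "unknown sweep axis")

  sp <- sweep_spec(base, list(P0_total = c(0, 1.5e6)), name = "tiny")
  tab <- run_sweep(sp)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$outcome %in%
                    c("co_propagation", "phage_encircles",
                      "bacteria_encircles", "no_phage")))

  # a failing cell is recorded and the sweep continues
  sp2 <- sweep_spec(base, list(eta_factor = c(-1, 1)), name = "bad")
  tab2 <- run_sweep(sp2)
  expect_false(is.na(tab2$error[1]))
  expect_true(is.na(tab2$error[2]))
  expect_false(is.na(tab2$arrival_h[2]) && is.na(tab2$theta_2cm[2]))
})
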