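test_that("sphere volume/radius conversions invert and match known values", {
  expect_equal(radius_from_volume(0.86), 5.90, tolerance = 1e-3)
  expect_equal(radius_from_volume(0.02), 1.68, tolerance = 1e-2)
  v <- c(0.02, 0.5, 2.3)
  expect_equal(volume_from_radius(radius_from_volume(v)), v, tolerance = 1e-12)
  expect_error(radius_from_volume(0), "positive")
  expect_error(volume_from_radius(-1), "positive")
})

test_that("passive pressure is zero unloaded, scales with thickness, low when filling", {
  w <- build_wall(default_cfg)
  expect_equal(passive_pressure(w, 1), 0)
  # collagen is deposited slack beyond the voiding stretch, so filling
  # pressure stays well below voiding pressure
  p_fill <- passive_pressure(w, default_cfg$wall$lam_F0)
  expect_lt(p_fill, 1000)
  expect_gt(p_fill, 100)
  # linear in H0
  cfg2 <- default_cfg; cfg2$wall$H0 <- 1.5 * default_cfg$wall$H0
  w2 <- build_wall(cfg2)
  lam <- c(1.3, 1.94, 2.4)
  expect_equal(passive_pressure(w2, lam), 1.5 * passive_pressure(w, lam),
               tolerance = 1e-12)
  # non-negative and continuous; the pressure of the inflating sphere dips
  # after the matrix maximum and then rises steeply once collagen recruits
  lams <- seq(1.01, 2.8, by = 0.005)
  ps <- passive_pressure(w, lams)
  expect_true(all(ps >= 0))
  expect_lt(max(abs(diff(ps))), 500)          # no jumps at this resolution
  expect_true(all(diff(ps[lams > 2.1]) > 0))  # collagen-dominated regime
})

test_that("active pressure matches the membrane reduction of the active stress", {
  w <- build_wall(default_cfg)
  # membrane equilibrium identity: p_act == 2H0/(R0 lam^3) sigma_act with
  # lam = lam_m * lam_Rm, to machine precision
  set.seed(3)
  for (i in 1:25) {
    lam_m <- runif(1, 0.3, 2.4)
    s <- runif(1)
    lam <- lam_m * w$smc$lam_Rm
    lhs <- active_pressure(w, lam_m, s)
    rhs <- 2 * w$H0 / (w$R0 * lam^3) * active_cauchy_stress(w$smc, lam_m, s)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_equal(active_pressure(w, w$smc$lam_m_min, 1), 0)
  # hand value: sham wall at full stimulus near the homeostatic stretch
  w1311 <- w; w1311$smc$lam_Rm <- 1.311
  expect_equal(active_pressure(w1311, 1.5, 1),
               2 * 0.78 * 5770 / (3 * 1.311^3) * (1.5 + 1 / 1.5) * 1.25 * 1.0,
               tolerance = 1e-12)
  expect_equal(active_pressure(w1311, 1.5, 1), 3.6e3, tolerance = 0.01)
})

test_that("total pressure is additive and monotone in stimulus", {
  w <- build_wall(default_cfg)
  lam <- 1.94
  expect_equal(total_pressure(w, lam, 0), passive_pressure(w, lam))
  expect_equal(total_pressure(w, lam, 1),
               passive_pressure(w, lam) +
                 active_pressure(w, lam / w$smc$lam_Rm, 1))
  ss <- seq(0, 1, by = 0.1)
  ps <- vapply(ss, function(s) total_pressure(w, lam, s), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("volumetric growth and thickness evolution follow the mixture rule", {
  w <- build_wall(default_cfg)
  expect_equal(volumetric_growth(w, 1), 1)
  expect_equal(volumetric_growth(w, 2), 0.30 + 0.70 * 2)
  ms <- seq(0.5, 6, by = 0.5)
  expect_true(all(diff(vapply(ms, function(m) volumetric_growth(w, m),
                              numeric(1))) > 0))
  expect_equal(evolved_thickness(w, 1, 1), w$H0)
  expect_equal(evolved_thickness(w, 1, 2), w$H0 / 4)
  expect_equal(evolved_thickness(w, 2, 1.5), 1.70 * w$H0 / 1.5^2)
})

test_that("wall constructor validates layers, fractions and geometry", {
  cfg <- default_cfg
  expect_error(wall_model(R0 = -1, H0 = 0.78,
                          layer_ratios = c(LP = .3, DL = .6, AD = .1),
                          iso = isotropic_params(1000),
                          collagen = build_wall(cfg)$collagen,
                          smc = build_wall(cfg)$smc), "positive")
  w <- build_wall(cfg)
  expect_error(wall_model(3, 0.78, c(LP = .5, DL = .6, AD = .1),
                          w$iso, w$collagen, w$smc), "summing to 1")
  expect_warning(wall_model(3, 1.8, c(LP = .3, DL = .6, AD = .1),
                            w$iso, w$collagen, w$smc,
                            vol_fractions = c(0.01, 0.29, 0.70)),
                 "membrane")
})
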