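cfg <- default_cfg
w <- build_wall(cfg)
outlet <- sham_outlet(cfg)
stim <- build_stimulus(cfg)

test_that("urethral flow law has threshold and unit slope", {
  o <- outlet_model(alpha = 19800, p_c = 1450)
  expect_equal(flow_rate(o, 1450), 0)
  expect_equal(flow_rate(o, 1000), 0)
  expect_equal(flow_rate(o, 1450 + 19800), 1)
  expect_equal(flow_rate(o, 3900), 2450 / 19800)
})

test_that("leakage pressure is linear in inflow", {
  o <- outlet_model(22075, 8487)
  expect_equal(leaky_pressure(o, 0), 8487)
  expect_equal(leaky_pressure(o, 9.72e-6), 22075 * 9.72e-6 + 8487)
  q <- seq(0, 1e-4, length.out = 5)
  expect_equal(diff(leaky_pressure(o, q)) / diff(q), rep(22075, 4))
  expect_error(leaky_pressure(o, -1), "non-negative")
})

test_that("leaky state solves the passive balance and stiffer walls leak smaller", {
  o <- boo_outlet(cfg)
  q_in <- cfg$gr$q_in / 86400
  st <- leaky_state(w, o, q_in)
  p_target <- leaky_pressure(o, q_in)
  expect_lt(abs(passive_pressure(w, st$lam) - p_target), 1e-6 * p_target)
  expect_equal(st$volume, volume_from_radius(st$lam * w$R0))
  # brute-force grid check of the root and stiffness monotonicity
  grid <- seq(1.01, 4, by = 1e-4)
  lam_grid <- grid[which.min(abs(passive_pressure(w, grid) - p_target))]
  expect_equal(st$lam, lam_grid, tolerance = 1e-3)
  cfg2 <- cfg; cfg2$wall$k_nc <- cfg$wall$k_nc * 20
  st2 <- leaky_state(build_wall(cfg2), o, q_in)
  expect_lt(st2$lam, st$lam)
  # an unsustainable leak pressure is an error
  o_big <- outlet_model(22075, 5e6)
  expect_error(leaky_state(w, o_big, q_in), "cannot sustain")
})

test_that("a sham voiding cycle conserves volume and satisfies metric identities", {
  mc <- sham_cycle(cfg)
  expect_false(mc$failed)
  expect_lt(abs(mc$v_fill - (mc$v_void + mc$v_res)), 1e-6)
  expect_equal(mc$p_act_max, mc$p_void_max - mc$p_passive_max)
  expect_equal(mc$q_avg * mc$t_void, mc$v_void, tolerance = 1e-6)
  expect_true(all(mc$series$Q >= 0))
  # pressure exceeds the cutoff whenever there is flow
  expect_true(all(mc$series$P[mc$series$Q > 0] > outlet$p_c))
  # pressure-volume loop: voiding at high pressure, filling at low, net emptying
  p_onset <- mc$series$P[which(mc$series$Q > 0)[1]]
  expect_gt(p_onset, passive_pressure(w, radius_from_volume(mc$v_fill) / w$R0))
  expect_lt(mc$v_res, mc$v_fill)
  expect_gt(mc$p_void_max, 5 * mc$p_passive_max)
})

test_that("an unreachable cutoff yields a failed void with no flow", {
  o_inf <- outlet_model(19800, 1e7)
  mc <- simulate_void(w, o_inf, stim, v_start = 0.83)
  expect_true(mc$failed)
  expect_equal(mc$v_void, 0)
  expect_equal(mc$v_res, 0.83)
  expect_equal(mc$q_max, 0)
})

test_that("raising the cutoff reduces voided volume; raising resistance slows voiding", {
  v0 <- volume_from_radius(cfg$smc$lam_m_h * w$smc$lam_Rm * w$R0)
  pcs <- c(1000, 1450, 2000, 2600)
  vv <- vapply(pcs, function(pc)
    simulate_void(w, outlet_model(19800, pc), stim, v0)$v_void, numeric(1))
  expect_true(all(diff(vv) < 0))
  alphas <- c(12000, 19800, 30000)
  tv <- vapply(alphas, function(a)
    simulate_void(w, outlet_model(a, 1450), stim, v0)$t_void, numeric(1))
  expect_true(all(diff(tv) > 0))
})

test_that("urodynamic metrics recompute from a trajectory", {
  mc <- sham_cycle(cfg)
  m <- urodynamic_metrics(mc$series)
  expect_equal(m$v_void, mc$v_void, tolerance = 5e-3)
  expect_equal(m$t_void, mc$t_void, tolerance = 0.05)
  expect_equal(m$p_void_max, mc$p_void_max)
  expect_equal(m$q_max, mc$q_max)
  expect_equal(m$p_act_max, m$p_void_max - m$p_passive_max)
  expect_equal(m$q_avg * m$t_void, m$v_void, tolerance = 1e-9)
  # zero-flow series
  z <- data.frame(t = 0:5, P = 100, Q = 0, V = 1, lam_m = 1)
  mz <- urodynamic_metrics(z)
  expect_equal(mz$v_void, 0)
  expect_equal(mz$t_void, 0)
  expect_equal(mz$q_max, 0)
  expect_error(urodynamic_metrics(data.frame()), "empty")
})

test_that("quasi-static prediction agrees with the dynamic void at the sham state", {
  pred <- predict_void_qs(w, outlet, q_crit = stim$q_crit)
  mc <- sham_cycle(cfg)
  expect_false(pred$failed)
  expect_equal(pred$v_void, mc$v_void, tolerance = 0.02)
  expect_equal(pred$lam_m_cyc, mc$lam_m_cyc, tolerance = 0.03)
  # an outlet no contraction can open
  pred2 <- predict_void_qs(w, outlet_model(19800, 1e7), q_crit = 1e-3)
  expect_true(pred2$failed)
})
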