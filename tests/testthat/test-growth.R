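cfg <- default_cfg
dep_dl <- recruitment_distribution(0.84, 0.90, 0.97)

test_that("collagen remodeling is stationary at the homeostatic distribution", {
  lamF <- 1.94
  # recruitment placed so fiber stretches at the void equal the targets
  dist <- recruitment_distribution(lamF / 0.97, lamF / 0.90, lamF / 0.84)
  out <- remodel_collagen(dist, lamF, dep_dl, alpha_c = 0.5, dtau = 0.01)
  expect_equal(unlist(out), unlist(dist), tolerance = 1e-12)
})

test_that("over-stretched fibers recruit later after remodeling (sign structure)", {
  lamF <- 2.2  # enlarged bladder: fiber stretches exceed targets
  dist <- recruitment_distribution(1.94 / 0.97, 1.94 / 0.90, 1.94 / 0.84)
  out <- remodel_collagen(dist, lamF, dep_dl, alpha_c = 0.5, dtau = 0.01)
  expect_gt(out$lam_min, dist$lam_min)
  expect_gt(out$lam_max, dist$lam_max)
  # and the max fiber stretch decreases on the next evaluation
  expect_lt(lamF / out$lam_min, lamF / dist$lam_min)
})

test_that("iterated collagen remodeling converges to the target at the linear rate", {
  lamF <- 2.2
  dist <- recruitment_distribution(1.94 / 0.97, 1.94 / 0.90, 1.94 / 0.84)
  alpha_c <- 0.5; dtau <- 0.01
  for (i in 1:12000) {
    dist <- remodel_collagen(dist, lamF, dep_dl, alpha_c, dtau)
    if (abs(lamF / dist$lam_min - 0.97) < 1e-8) break
  }
  expect_equal(lamF / dist$lam_min, 0.97, tolerance = 1e-6)
  expect_equal(lamF / dist$lam_mode, 0.90, tolerance = 1e-6)
  expect_equal(lamF / dist$lam_max, 0.84, tolerance = 1e-6)
  # linear ODE oracle for one component: lam_R' = (a/t)(lamF/lam_R - t_x)
  # has a fixed point at lamF/t_x approached geometrically; two Euler steps
  # by hand match remodel_collagen
  d0 <- recruitment_distribution(2.2, 2.4, 2.6)
  d1 <- remodel_collagen(d0, lamF, dep_dl, alpha_c, dtau)
  expect_equal(d1$lam_min,
               2.2 + dtau * alpha_c * (lamF / 2.2 - 0.97) / 0.97,
               tolerance = 1e-12)
  expect_equal(d1$lam_max,
               2.6 + dtau * alpha_c * (lamF / 2.6 - 0.84) / 0.84,
               tolerance = 1e-12)
})

test_that("SMC recruitment remodeling has the homeostatic fixed point", {
  expect_equal(remodel_smc(1.3, lam_m_F = 1.5, lam_m_h = 1.5,
                           alpha_m = 40, dtau = 0.005), 1.3)
  # above-homeostatic stretch raises the recruitment stretch
  expect_gt(remodel_smc(1.3, 1.6, 1.5, 40, 0.005), 1.3)
  # fixed-lam iteration converges to lam / lam_m_h
  lam <- 2.4; lam_Rm <- 1.2
  for (i in 1:5000) lam_Rm <- remodel_smc(lam_Rm, lam / lam_Rm, 1.5, 40, 0.005)
  expect_equal(lam_Rm, lam / 1.5, tolerance = 1e-9)
  expect_error(remodel_smc(0.001, 0.2, 1.5, 40, 10), "non-positive")
})

test_that("SMC growth law follows the Euler arithmetic for all hypotheses", {
  targets <- homeostatic_targets(
    deposition = list(LP = dep_dl, DL = dep_dl, AD = dep_dl),
    lam_m_h = 1.5, v_void0 = 0.8, q_avg0 = 0.07, lam_m_cyc0 = 1.05)
  at_target <- list(failed = FALSE, v_void = 0.8, q_avg = 0.07,
                    lam_m_cyc = 1.05)
  for (hy in c("GF1", "GF2", "GF3"))
    expect_equal(grow_smc(1.3, at_target, targets, hy, 5, 0.01), 1.3)
  # leaky mode (no functional void): maximal relative growth rate
  expect_equal(grow_smc(1, NULL, targets, "GF1", 5, 0.01), 1.05)
  expect_equal(grow_smc(1, list(failed = TRUE), targets, "GF1", 5, 0.01), 1.05)
  # over-voiding drives atrophy
  over <- list(failed = FALSE, v_void = 1.0, q_avg = 0.07, lam_m_cyc = 1.05)
  expect_lt(grow_smc(1.3, over, targets, "GF1", 5, 0.01), 1.3)
  expect_error(grow_smc(1, NULL, targets["deposition"], "GF1", 5, 0.01))
})

test_that("the sham bladder is a machine-precision fixed point of the G&R loop", {
  sham <- simulate_gr(cfg, tau_end = 4, obstructed = FALSE)
  h <- sham$history
  expect_lt(max(abs(h$m_m - 1)), 1e-9)
  expect_lt(max(abs(h$lam_Rm - h$lam_Rm[1])), 1e-9)
  expect_lt(max(abs(h$dl_min - h$dl_min[1])), 1e-9)
  expect_lt(max(abs(h$lp_max - h$lp_max[1])), 1e-9)
  expect_true(all(h$mode == "functional"))
  # daily voiding with identical cycles
  cl <- sham$cycles
  expect_equal(nrow(cl), 4)
  expect_lt(diff(range(cl$v_void)), 1e-9)
  expect_equal(diff(cl$tau), rep(0.96, 3), tolerance = 0.02)
})

test_that("obstruction triggers leakage then recovery with collagen shifted rightward", {
  gr <- simulate_gr(cfg, tau_end = 6)
  h <- gr$history
  expect_true(any(h$mode == "leaky"))
  # leakage starts immediately after the first post-obstruction trigger
  first_leaky <- min(h$tau[h$mode == "leaky"])
  expect_lt(first_leaky, 1.2)
  # functional voiding resumes
  expect_true(any(h$mode == "functional" & h$tau > first_leaky))
  # recruitment distributions shift rightward in every layer
  n <- nrow(h)
  expect_gt(h$lp_min[n], h$lp_min[1])
  expect_gt(h$dl_min[n], h$dl_min[1])
  expect_gt(h$ad_min[n], h$ad_min[1])
  # mass bookkeeping is monotone in m_m
  expect_equal(h$mass, cfg$gr$mass_sham * (0.30 + 0.70 * h$m_m),
               tolerance = 1e-12)
})
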