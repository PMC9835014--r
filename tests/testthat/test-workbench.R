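test_that("the default configuration carries the calibrated rat parameter set", {
  cfg <- bladder_config()
  expect_equal(cfg$smc$k_m_act, 5770)
  expect_equal(cfg$outlet_boo$p_c, 8487)
  expect_equal(cfg$wall$vol_fractions,
               c(elastin = 0.01, collagen = 0.29, smc = 0.70))
  expect_equal(unname(cfg$deposition$DL), c(0.84, 0.90, 0.97))
  # overrides merge into nested sections; unknown fields are rejected
  cfg2 <- bladder_config(outlet_boo = list(p_c = 9000))
  expect_equal(cfg2$outlet_boo$p_c, 9000)
  expect_equal(cfg2$outlet_boo$alpha, 22075)
  expect_error(bladder_config(nonsense = 1), "unknown field")
  expect_error(bladder_config(wall = list(k_qq = 1)), "unknown field")
})

test_that("configuration validation names the offending field", {
  cfg <- unclass(bladder_config())
  cfg$wall$k_c[["DL"]] <- -1
  expect_error(validate_config(cfg), "wall\\$k_c")
  cfg <- unclass(bladder_config())
  cfg$smc$lam_m_h <- 3.0
  expect_error(validate_config(cfg), "lam_m_h")
  cfg <- unclass(bladder_config())
  cfg$gr$hypothesis <- "GF9"
  expect_error(validate_config(cfg), "hypothesis")
})

test_that("configurations round-trip through YAML and empty files give defaults", {
  cfg <- bladder_config()
  f <- tempfile(fileext = ".yaml")
  save_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(unclass(load_config(empty)), unclass(bladder_config()),
               tolerance = 1e-12)
  bad <- tempfile(fileext = ".yaml")
  writeLines("wrong_key: 1", bad)
  expect_error(load_config(bad), "unknown field")
  expect_error(load_config(tempfile()), "no such file")
})

test_that("the wall built from the configuration is at homeostasis", {
  cfg <- bladder_config()
  w <- build_wall(cfg)
  # fiber stretches at the onset of voiding equal the deposition targets
  for (L in c("LP", "DL", "AD")) {
    r <- w$collagen[[L]]$recruitment
    expect_equal(cfg$wall$lam_F0 / c(r$lam_max, r$lam_mode, r$lam_min),
                 unname(cfg$deposition[[L]]), tolerance = 1e-12)
  }
  # the SMC sits at its homeostatic stretch at the voiding trigger
  expect_equal(cfg$wall$lam_F0 / w$smc$lam_Rm, cfg$smc$lam_m_h)
})

test_that("synthetic biaxial data are deterministic and exact at zero noise", {
  s0 <- synthetic_spec(noise_stress = 0, binom_n = Inf, seed = 3)
  d0 <- make_synthetic_biaxial(s0)
  # stresses lie exactly on the constitutive curve
  pf <- fit_passive_model(d0$stress, s0$recruitment, s0$layer_ratios)
  expect_lt(max(abs(residuals(pf))), 1e-6)
  expect_equal(pf$k_nc, 1170, tolerance = 1e-9)
  # fractions equal the triangular CDF
  dl <- d0$fractions[d0$fractions$layer == "DL", ]
  expect_equal(dl$fraction, recruitment_cdf(s0$recruitment$DL, dl$stretch))
  # the same seed reproduces the noisy dataset exactly
  s1 <- synthetic_spec(seed = 11)
  expect_identical(make_synthetic_biaxial(s1), make_synthetic_biaxial(s1))
  # different seeds differ
  s2 <- synthetic_spec(seed = 12)
  expect_false(identical(make_synthetic_biaxial(s1)$stress$stress,
                         make_synthetic_biaxial(s2)$stress$stress))
  # generation does not disturb the caller RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(make_synthetic_biaxial(s1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("the sham cycle experiment returns the full metric schema", {
  out_dir <- tempfile()
  ex <- run_experiment("sham_cycle", out_dir = out_dir)
  expect_true(all(c("v_void", "t_void", "v_res", "p_void_max",
                    "p_passive_max", "p_act_max", "q_max", "q_avg") %in%
                    names(ex$summary)))
  expect_true(nchar(ex$log$config_hash) == 32)
  expect_true(file.exists(file.path(out_dir, "cycle_series.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")) ||
                file.exists(file.path(out_dir, "summary.R")))
  # determinism of the experiment itself
  ex2 <- run_experiment("sham_cycle")
  expect_identical(ex$summary, ex2$summary)
})
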