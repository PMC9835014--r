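test_that("noise-free recruitment fractions are recovered exactly", {
  rd <- recruitment_distribution(1.1, 1.2, 1.35)
  s <- seq(1.0, 1.5, by = 0.02)
  fit <- fit_recruitment(data.frame(stretch = s,
                                    fraction = recruitment_cdf(rd, s)))
  expect_equal(unname(coef(fit)), c(1.1, 1.2, 1.35), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # the fitted fraction at the modal stretch equals the skew
  expect_equal(predict(fit, fit$dist$lam_mode), recruitment_skew(fit$dist),
               tolerance = 1e-9)
})

test_that("recruitment fit recovers the onset under binomial sampling noise", {
  rd <- recruitment_distribution(1.1, 1.2, 1.35)
  s <- seq(1.0, 1.5, length.out = 20)
  truth <- recruitment_cdf(rd, s)
  set.seed(101)
  err_min <- replicate(200, {
    f <- rbinom(length(truth), 50, truth) / 50
    fit <- tryCatch(fit_recruitment(stretch = s, fraction = f),
                    error = function(e) NULL)
    if (is.null(fit)) NA_real_ else abs(coef(fit)[["lam_min"]] - 1.1)
  })
  expect_lt(mean(err_min, na.rm = TRUE), 0.02)
  expect_lt(mean(is.na(err_min)), 0.05)
})

test_that("degenerate fraction data are rejected", {
  s <- seq(1, 1.5, by = 0.1)
  expect_error(fit_recruitment(stretch = s, fraction = rep(0, length(s))),
               "not identifiable")
  expect_error(fit_recruitment(stretch = s, fraction = rep(1, length(s))),
               "not identifiable")
  expect_error(fit_recruitment(stretch = 1.1, fraction = 0.5), "3 data points")
})

test_that("passive stiffness recovery stays within 5% at 2% stress noise", {
  spec <- synthetic_spec(noise_stress = 0.02, binom_n = Inf)
  rel_err <- t(sapply(1:100, function(i) {
    d <- make_synthetic_biaxial(synthetic_spec(noise_stress = 0.02, seed = i))
    pf <- fit_passive_model(d$stress, spec$recruitment, spec$layer_ratios)
    abs(c(pf$k_nc, pf$k_c) - c(1170, 11.7e6, 0.79e6)) /
      c(1170, 11.7e6, 0.79e6)
  }))
  med <- apply(rel_err, 2, median)
  expect_true(all(med <= 0.05))
})

test_that("toe-region-only data identify the matrix but flag collagen", {
  spec <- synthetic_spec(noise_stress = 0, stretch_max = 1.05)
  d <- make_synthetic_biaxial(spec)  # all below the DL onset 1.08
  expect_warning(
    pf <- fit_passive_model(d$stress, spec$recruitment, spec$layer_ratios),
    "not identifiable")
  expect_equal(pf$k_nc, 1170, tolerance = 1e-6)
  expect_true(all(is.na(pf$k_c)))
})

test_that("the true model outfits a mis-specified exponential fiber law", {
  spec <- synthetic_spec(noise_stress = 0.02, seed = 5)
  d <- make_synthetic_biaxial(spec)
  pf <- fit_passive_model(d$stress, spec$recruitment, spec$layer_ratios)
  rss_true <- sum(residuals(pf)^2)
  mis <- minpack.lm::nlsLM(
    stress ~ 2 * k * (stretch^2 - stretch^-4) + A * (exp(B * (stretch - 1)) - 1),
    data = d$stress, start = list(k = 1000, A = 100, B = 5),
    lower = c(0, 0, 0))
  rss_mis <- sum(residuals(mis)^2)
  expect_lt(rss_true, rss_mis)
})

test_that("void stretch follows the cube-root law and the worked sham anchor", {
  # pure geometry: filled volume 8x the unloaded volume doubles the radius
  g <- explant_geometry(d0 = 5, y0 = 10, h0 = 0.8, v0 = 0.1, v_fill = 0.8,
                        p_void = 300)
  lam <- seq(1, 1.4, by = 0.01)
  curve <- data.frame(stretch = lam, stress = 5e4 * (lam - 1) + 1)
  es <- estimate_void_stretch(g, curve)
  expect_equal(es$lam_F0, 2, tolerance = 1e-9)
  # worked synthetic sham fixture: mean explant geometry anchored at 1.05
  fx <- read.csv(system.file("extdata", "biaxial_sham_synthetic.csv",
                             package = "bladdergr"))
  gs <- explant_geometry(d0 = 4.74, y0 = 10.10, h0 = 0.78,
                         v0 = pi * 4.74^2 * 10.10 / 6 / 1000,
                         v_fill = 0.86, p_void = 300)
  es2 <- estimate_void_stretch(gs, data.frame(stretch = fx$stretch,
                                              stress = fx$stress_pa))
  expect_equal(es2$lam_bar_F, 1.05, tolerance = 0.005)
  expect_equal(es2$lam_F0, 1.93, tolerance = 0.01)
  # refusing to extrapolate
  g_hi <- explant_geometry(5, 10, 0.8, 0.1, 0.8, p_void = 5e5)
  expect_error(estimate_void_stretch(g_hi, curve), "outside the measured")
  # geometric similarity: scaling all lengths by k and volumes by k^3
  g10 <- explant_geometry(50, 100, 8, 100, 800, 300)
  es10 <- estimate_void_stretch(g10, curve)
  expect_equal(es10$lam_F0, es$lam_F0, tolerance = 1e-12)
  expect_equal(es10$lam_bar_F, es$lam_bar_F, tolerance = 1e-9)
})

test_that("deposition inference reverses order and preserves the shape ratio", {
  d <- recruitment_distribution(1.12, 1.20, 1.30)
  dep <- infer_deposition(d, 1.04)
  expect_equal(dep$lam_max, 1.04 / 1.12, tolerance = 1e-12)  # ~0.93
  expect_equal(dep$lam_min, 1.04 / 1.30, tolerance = 1e-12)
  expect_equal(dep$lam_mode, 1.04 / 1.20, tolerance = 1e-12)
  # fibers just taut at the onset of voiding
  dep2 <- infer_deposition(d, 1.12)
  expect_equal(dep2$lam_max, 1)
  # a sheath: max below 1 when the void stretch is below the onset
  expect_lt(dep$lam_max, 1)
  # the dimensionless width/mode ratio maps consistently for any anchor
  shape <- function(x) (x$lam_max - x$lam_min) / x$lam_mode
  r1 <- shape(infer_deposition(d, 1.04))
  r2 <- shape(infer_deposition(d, 2.0))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, (d$lam_max - d$lam_min) * d$lam_mode /
                 (d$lam_min * d$lam_max), tolerance = 1e-12)
})

test_that("stretch frame mapping anchors the void stretches and round-trips", {
  x <- c(1.0, 1.05, 1.2)
  y <- map_stretch(x, lam_F = 1.97, lam_bar_F = 1.05, "to_model")
  expect_equal(map_stretch(y, 1.97, 1.05, "to_biaxial"), x, tolerance = 1e-12)
  expect_equal(map_stretch(1.05, 1.97, 1.05, "to_model"), 1.97)
})
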