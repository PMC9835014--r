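# Quadrature oracle for the collagen ensemble stress: numeric convolution of
# the fiber response with the triangular recruitment density. Independent of
# the closed-form implementation.
collagen_stress_quadrature <- function(p, lam4) {
  d <- p$recruitment
  vapply(lam4, function(lam) {
    if (lam <= d$lam_min) return(0)
    u <- min(lam, d$lam_max)
    p$m_c * stats::integrate(function(x)
      p$k_c * (lam / x) * (lam / x - 1) * recruitment_pdf(d, x),
      d$lam_min, u, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}

# random valid recruitment distribution
random_dist <- function() {
  lo <- runif(1, 0.9, 1.6)
  d1 <- runif(1, 0.01, 0.4)
  d2 <- runif(1, 0.01, 0.4)
  recruitment_distribution(lo, lo + d1, lo + d1 + d2)
}

# a small wall for micturition tests (the default rat configuration)
default_cfg <- bladder_config()
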