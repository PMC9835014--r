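#' Constituent parameter sets
#'
#' Constructors for the passive and active constituents of the bladder wall
#' mixture. All stresses are Cauchy stresses in Pa; stretches are
#' dimensionless; mass densities are normalized to 1 at baseline.
#'
#' \describe{
#'   \item{\code{collagen_params}}{a fiber population with quadratic fiber
#'     strain energy (stiffness \code{k_c}, Pa), normalized mass density
#'     \code{m_c} and a triangular \code{\link{recruitment_distribution}}.}
#'   \item{\code{isotropic_params}}{neo-Hookean ground matrix (elastin,
#'     amorphous matrix and the low-stress response of SMC), stiffness
#'     \code{k_nc} (Pa).}
#'   \item{\code{smc_params}}{active smooth muscle: active modulus
#'     \code{k_m_act} (Pa), active window \code{[lam_m_min, lam_m_max]} of SMC
#'     stretch, recruitment stretch \code{lam_Rm} linking tissue and SMC
#'     stretch (\code{lam_m = lam / lam_Rm}), normalized mass \code{m_m} and
#'     homeostatic voiding stretch \code{lam_m_h}.}
#'   \item{\code{stimulus_params}}{nervous stimulus dynamics: ramp-up constant
#'     \code{k_m1} (s), ramp-down constant \code{k_m2} (s), flow threshold
#'     \code{q_crit} (ml/s) that latches the ramp-down, and hard end time
#'     \code{t_end} (s).}
#' }
#'
#' @param k_c,k_nc,k_m_act stiffness/modulus parameters (Pa), positive.
#' @param m_c,m_m normalized mass densities, positive.
#' @param recruitment a \code{\link{recruitment_distribution}}.
#' @param lam_m_min,lam_m_max,lam_Rm,lam_m_h SMC stretch parameters.
#' @param k_m1,k_m2,q_crit,t_end stimulus parameters.
#' @return A validated parameter list with a class tag.
#' @name constituents
NULL

#' @rdname constituents
#' @export
collagen_params <- function(k_c, m_c = 1, recruitment) {
  stopifnot(inherits(recruitment, "recruitment_distribution"))
  if (!(k_c > 0)) stop("collagen_params: 'k_c' must be positive", call. = FALSE)
  if (!(m_c > 0)) stop("collagen_params: 'm_c' must be positive", call. = FALSE)
  structure(list(k_c = k_c, m_c = m_c, recruitment = recruitment),
            class = "collagen_params")
}

#' @rdname constituents
#' @export
isotropic_params <- function(k_nc) {
  if (!(k_nc > 0)) stop("isotropic_params: 'k_nc' must be positive", call. = FALSE)
  structure(list(k_nc = k_nc), class = "isotropic_params")
}

#' @rdname constituents
#' @export
smc_params <- function(k_m_act, lam_m_min, lam_m_max, lam_Rm, m_m = 1, lam_m_h) {
  if (!(k_m_act > 0)) stop("smc_params: 'k_m_act' must be positive", call. = FALSE)
  if (!(lam_m_min > 0 && lam_m_min < lam_m_h && lam_m_h < lam_m_max))
    stop("smc_params: require 0 < lam_m_min < lam_m_h < lam_m_max", call. = FALSE)
  if (!(lam_Rm > 0)) stop("smc_params: 'lam_Rm' must be positive", call. = FALSE)
  if (!(m_m > 0)) stop("smc_params: 'm_m' must be positive", call. = FALSE)
  structure(list(k_m_act = k_m_act, lam_m_min = lam_m_min,
                 lam_m_max = lam_m_max, lam_Rm = lam_Rm, m_m = m_m,
                 lam_m_h = lam_m_h),
            class = "smc_params")
}

#' @rdname constituents
#' @export
stimulus_params <- function(k_m1, k_m2, q_crit, t_end) {
  if (!(k_m1 > 0 && k_m2 > 0)) stop("stimulus_params: time constants must be positive", call. = FALSE)
  if (q_crit < 0) stop("stimulus_params: 'q_crit' must be non-negative", call. = FALSE)
  if (!(t_end > 0)) stop("stimulus_params: 't_end' must be positive", call. = FALSE)
  structure(list(k_m1 = k_m1, k_m2 = k_m2, q_crit = q_crit, t_end = t_end),
            class = "stimulus_params")
}

# Antiderivative of (lam^2/x^2 - lam/x) * (a + b x) in x, used by the
# closed-form collagen ensemble stress.
.collagen_antideriv <- function(x, lam, a, b) {
  -a * lam^2 / x + (b * lam^2 - a * lam) * log(x) - b * lam * x
}

#' Collagen ensemble Cauchy stress
#'
#' Stress of a collagen fiber population at tissue stretch \code{lam4} (the
#' stretch in the fiber direction; equal to the membrane stretch in the
#' isotropic spherical reduction). Each fiber carries stress
#' \code{k_c * lam_c * (lam_c - 1)} once taut (\code{lam_c = lam4 / lam_R >=
#' 1}) and nothing when slack; the ensemble stress is the convolution of this
#' response with the triangular recruitment density, scaled by the normalized
#' mass density \code{m_c}. Because the density is piecewise linear the
#' convolution integrates in closed form; fibers recruit progressively over
#' \code{[lam_min, min(lam4, lam_max)]}, making the stress C1-continuous at
#' both recruitment onset and saturation.
#'
#' A zero-width (degenerate) distribution is treated as a Dirac mass: all
#' fibers recruit at \code{lam_min}.
#'
#' @param p a \code{\link{collagen_params}}.
#' @param lam4 tissue stretch in the fiber direction (vectorized, positive).
#' @return Cauchy stress (Pa), monotone non-decreasing in \code{lam4}.
#' @export
collagen_cauchy_stress <- function(p, lam4) {
  stopifnot(inherits(p, "collagen_params"))
  d <- p$recruitment
  lo <- d$lam_min; md <- d$lam_mode; hi <- d$lam_max
  w <- hi - lo
  out <- numeric(length(lam4))
  if (w <= 0) {                       # Dirac point mass at lam_min
    i <- lam4 > lo
    lc <- lam4[i] / lo
    out[i] <- p$k_c * lc * (lc - 1)
    return(p$m_c * out)
  }
  d1 <- md - lo
  d2 <- hi - md
  act <- lam4 > lo
  if (any(act)) {
    lam <- lam4[act]
    val <- numeric(length(lam))
    if (d1 > 0) {
      b1 <- 2 / (w * d1); a1 <- -2 * lo / (w * d1)
      u1 <- pmin(lam, md)
      j <- u1 > lo
      val[j] <- val[j] + .collagen_antideriv(u1[j], lam[j], a1, b1) -
        .collagen_antideriv(lo, lam[j], a1, b1)
    }
    if (d2 > 0) {
      b2 <- -2 / (w * d2); a2 <- 2 * hi / (w * d2)
      u2 <- pmin(lam, hi)
      j <- u2 > md
      val[j] <- val[j] + .collagen_antideriv(u2[j], lam[j], a2, b2) -
        .collagen_antideriv(md, lam[j], a2, b2)
    }
    out[act] <- p$k_c * val
  }
  p$m_c * out
}

#' Isotropic (ground matrix) Cauchy stress
#'
#' In-plane Cauchy stress of an incompressible neo-Hookean membrane under
#' equibiaxial stretch \code{lam}: \code{2 k_nc (lam^2 - lam^-4)}. The
#' through-thickness incompressibility pressure is eliminated by the
#' plane-stress condition, so the stress vanishes in the unloaded state
#' (\code{lam = 1}) and the transmural pressure of an unloaded sphere is zero.
#' For \code{lam < 1} a membrane wrinkles rather than supporting in-plane
#' compression, so the stress is cut off at zero.
#'
#' @param p an \code{\link{isotropic_params}}.
#' @param lam equibiaxial stretch (vectorized, positive).
#' @return Cauchy stress (Pa).
#' @export
isotropic_cauchy_stress <- function(p, lam) {
  stopifnot(inherits(p, "isotropic_params"))
  pmax(0, 2 * p$k_nc * (lam^2 - lam^-4))
}

#' Active stress shape function
#'
#' Dimensionless length-tension shape of the smooth muscle:
#' \code{(lam_m^4 + lam_m^2)(lam_m - lam_m_min)(lam_m_max - lam_m)},
#' non-negative on the active window, zero at both ends, with a single
#' interior maximum.
#'
#' @param p an \code{\link{smc_params}}.
#' @param lam_m SMC stretch (vectorized).
#' @export
gm <- function(p, lam_m) {
  (lam_m^4 + lam_m^2) * (lam_m - p$lam_m_min) * (p$lam_m_max - lam_m)
}

#' Active smooth muscle Cauchy stress
#'
#' \code{s * m_m * k_m_act * gm(lam_m)} inside the active window
#' \code{[lam_m_min, lam_m_max]} and zero outside; linear in the stimulus
#' level \code{s} and in the normalized SMC mass \code{m_m}.
#'
#' @param p an \code{\link{smc_params}}.
#' @param lam_m SMC stretch (vectorized).
#' @param s stimulus level in \code{[0, 1]}.
#' @return Cauchy stress (Pa).
#' @export
active_cauchy_stress <- function(p, lam_m, s) {
  stopifnot(s >= 0, s <= 1)
  inside <- lam_m > p$lam_m_min & lam_m < p$lam_m_max
  out <- numeric(length(lam_m))
  out[inside] <- s * p$m_m * p$k_m_act * gm(p, lam_m[inside])
  out
}

#' Nervous stimulus function
#'
#' Voiding stimulus level in \code{[0, 1]}. From stimulus onset the level
#' ramps up as \code{1 - 1/(1 + (t/k_m1)^4)}. Once the outflow has dropped
#' below \code{q_crit} (at the latched time \code{t_crit}) the level is
#' multiplied by a mirrored ramp-down with time constant \code{k_m2}, and it
#' is zero beyond \code{t_end}. Continuous at \code{t_crit}. The quartic
#' ramp approaches 1 asymptotically; the plateau is treated as "fully on".
#'
#' @param p a \code{\link{stimulus_params}}.
#' @param t time since stimulus onset (s, vectorized).
#' @param t_crit latched ramp-down time (s), or \code{NA}/\code{NULL} if the
#'   flow has not yet fallen below \code{q_crit}.
#' @return Stimulus level in \code{[0, 1]}.
#' @export
stimulus <- function(p, t, t_crit = NULL) {
  tc <- if (is.null(t_crit) || is.na(t_crit)) Inf else t_crit
  up <- 1 - 1 / (1 + (t / p$k_m1)^4)
  out <- ifelse(t <= tc, up,
                (1 - 1 / (1 + (tc / p$k_m1)^4)) *
                  (1 / (1 + ((t - tc) / p$k_m2)^4)))
  out[t > p$t_end] <- 0
  out[t < 0] <- 0
  out
}
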