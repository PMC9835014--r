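#' Layered spherical bladder wall model
#'
#' Assembles the constitutive description of the bladder wall as a thin
#' spherical membrane with three layers: lamina propria (LP), detrusor smooth
#' muscle layer (DL) and adventitia (AD). Each layer contributes a collagen
#' fiber population; the neo-Hookean ground matrix acts across the full
#' thickness; active smooth muscle acts in the DL. Units are Pa, mm, ml
#' throughout.
#'
#' @param R0 unloaded radius (mm).
#' @param H0 unloaded wall thickness (mm).
#' @param layer_ratios named numeric vector of per-layer thickness fractions
#'   \code{c(LP=, DL=, AD=)}; must sum to 1.
#' @param iso an \code{\link{isotropic_params}}.
#' @param collagen named list \code{list(LP=, DL=, AD=)} of
#'   \code{\link{collagen_params}} (recruitment relative to the unloaded
#'   configuration).
#' @param smc an \code{\link{smc_params}}.
#' @param vol_fractions initial volume fractions \code{c(elastin=, collagen=,
#'   smc=)}; must sum to 1.
#' @param m_e,m_c_global normalized elastin and collagen mass densities
#'   (held at 1: no elastogenesis or collagen growth).
#' @return An object of class \code{"wall_model"}.
#' @seealso \code{\link{sham_wall}} for the default parameterization.
#' @export
wall_model <- function(R0, H0, layer_ratios, iso, collagen, smc,
                       vol_fractions = c(elastin = 0.01, collagen = 0.29, smc = 0.70),
                       m_e = 1, m_c_global = 1) {
  stopifnot(inherits(iso, "isotropic_params"), inherits(smc, "smc_params"),
            is.list(collagen))
  if (!(R0 > 0 && H0 > 0)) stop("wall_model: R0 and H0 must be positive", call. = FALSE)
  if (H0 / R0 > 0.5)
    warning("wall_model: H0/R0 > 0.5 strains the thin-membrane assumption")
  lay <- c("LP", "DL", "AD")
  if (!all(lay %in% names(layer_ratios)) ||
      abs(sum(layer_ratios[lay]) - 1) > 1e-8 ||
      any(layer_ratios[lay] <= 0) || any(layer_ratios[lay] >= 1))
    stop("wall_model: layer_ratios must be fractions in (0,1) for LP, DL, AD summing to 1",
         call. = FALSE)
  if (!all(lay %in% names(collagen)) ||
      !all(vapply(collagen[lay], inherits, TRUE, "collagen_params")))
    stop("wall_model: 'collagen' must supply collagen_params for LP, DL, AD",
         call. = FALSE)
  if (abs(sum(vol_fractions) - 1) > 1e-8)
    stop("wall_model: volume fractions must sum to 1", call. = FALSE)
  structure(list(R0 = R0, H0 = H0, layer_ratios = layer_ratios[lay],
                 iso = iso, collagen = collagen[lay], smc = smc,
                 vol_fractions = vol_fractions, m_e = m_e,
                 m_c_global = m_c_global),
            class = "wall_model")
}

#' @export
print.wall_model <- function(x, ...) {
  cat("Spherical bladder wall model\n")
  cat(sprintf("  unloaded radius R0 = %.3g mm, thickness H0 = %.3g mm\n",
              x$R0, x$H0))
  cat(sprintf("  layers LP:DL:AD = %.2f:%.2f:%.2f of thickness\n",
              x$layer_ratios[["LP"]], x$layer_ratios[["DL"]], x$layer_ratios[["AD"]]))
  cat(sprintf("  ground matrix k_nc = %.4g Pa\n", x$iso$k_nc))
  for (L in names(x$collagen))
    cat(sprintf("  collagen %s: k_c = %.4g Pa, recruitment [%.3f, %.3f, %.3f]\n",
                L, x$collagen[[L]]$k_c, x$collagen[[L]]$recruitment$lam_min,
                x$collagen[[L]]$recruitment$lam_mode,
                x$collagen[[L]]$recruitment$lam_max))
  cat(sprintf("  SMC: k_m_act = %.4g Pa, window [%.3g, %.3g], lam_Rm = %.4f, m_m = %.4g\n",
              x$smc$k_m_act, x$smc$lam_m_min, x$smc$lam_m_max, x$smc$lam_Rm,
              x$smc$m_m))
  invisible(x)
}

#' Sphere geometry helpers
#'
#' Conversions between luminal volume (ml) and radius (mm) of a spherical
#' bladder; exact inverses of each other.
#'
#' @param volume luminal volume (ml), positive.
#' @param radius radius (mm), positive.
#' @return radius in mm / volume in ml.
#' @export
radius_from_volume <- function(volume) {
  if (any(volume <= 0)) stop("radius_from_volume: volume must be positive", call. = FALSE)
  (3 * volume * 1000 / (4 * pi))^(1 / 3)
}

#' @rdname radius_from_volume
#' @export
volume_from_radius <- function(radius) {
  if (any(radius <= 0)) stop("volume_from_radius: radius must be positive", call. = FALSE)
  (4 / 3) * pi * radius^3 / 1000
}

#' Passive transmural pressure of the inflated membrane
#'
#' Quasi-static pressure of the spherical membrane without active stress:
#' \code{p = 2 H0 / (R0 lam^3) * (sigma_nc + sum_L r_L * sigma_c_L(lam))}.
#' The ground matrix acts across the full thickness; each collagen layer is
#' weighted by its thickness fraction. Zero at \code{lam = 1} when all
#' collagen recruitment onsets exceed the current stretch.
#'
#' @param w a \code{\link{wall_model}}.
#' @param lam membrane stretch relative to the unloaded radius (vectorized).
#' @return Pressure (Pa).
#' @export
passive_pressure <- function(w, lam) {
  sig <- isotropic_cauchy_stress(w$iso, lam)
  for (L in names(w$collagen))
    sig <- sig + w$layer_ratios[[L]] * collagen_cauchy_stress(w$collagen[[L]], lam)
  2 * w$H0 / (w$R0 * lam^3) * sig
}

#' Active transmural pressure
#'
#' Pressure generated by the detrusor smooth muscle, expressed directly in
#' terms of the SMC stretch:
#' \code{p_act = 2 H0 k_m_act / (R0 lam_Rm^3) * s * m_m *
#' (lam_m + 1/lam_m)(lam_m - lam_m_min)(lam_m_max - lam_m)}, zero outside the
#' active window. Algebraically identical to pushing the active Cauchy stress
#' through the membrane equilibrium with \code{lam = lam_m * lam_Rm}. The
#' printed active modulus absorbs the detrusor thickness fraction.
#'
#' @param w a \code{\link{wall_model}}.
#' @param lam_m SMC stretch (vectorized).
#' @param s stimulus level in \code{[0, 1]}.
#' @return Pressure (Pa).
#' @export
active_pressure <- function(w, lam_m, s) {
  m <- w$smc
  inside <- lam_m > m$lam_m_min & lam_m < m$lam_m_max
  out <- numeric(length(lam_m))
  out[inside] <- 2 * w$H0 * m$k_m_act / (w$R0 * m$lam_Rm^3) * s * m$m_m *
    (lam_m[inside] + 1 / lam_m[inside]) *
    (lam_m[inside] - m$lam_m_min) * (m$lam_m_max - lam_m[inside])
  out
}

#' Total transmural pressure
#'
#' Passive plus active pressure at membrane stretch \code{lam}, with the SMC
#' stretch given by \code{lam / lam_Rm}.
#'
#' @param w a \code{\link{wall_model}}.
#' @param lam membrane stretch (vectorized).
#' @param s stimulus level in \code{[0, 1]}.
#' @return Pressure (Pa).
#' @export
total_pressure <- function(w, lam, s) {
  passive_pressure(w, lam) + active_pressure(w, lam / w$smc$lam_Rm, s)
}

#' Normalized volumetric growth
#'
#' Wall volume relative to baseline, from initial constituent volume
#' fractions and normalized mass densities:
#' \code{v_hat = f_e0 m_e + f_c0 m_c + f_m0 m_m}. With elastin and collagen
#' mass held at baseline, only SMC hypertrophy grows the wall.
#'
#' @param w a \code{\link{wall_model}}.
#' @param m_m normalized SMC mass density (defaults to the wall's current value).
#' @return Dimensionless volume ratio.
#' @export
volumetric_growth <- function(w, m_m = w$smc$m_m) {
  f <- w$vol_fractions
  f[[1]] * w$m_e + f[[2]] * w$m_c_global + f[[3]] * m_m
}

#' Grown wall thickness at the onset of voiding
#'
#' Membrane thickness in the voiding configuration after growth:
#' \code{v_hat * H0 / lam_V^2} (incompressible thinning of a grown wall).
#'
#' @param w a \code{\link{wall_model}}.
#' @param m_m normalized SMC mass density.
#' @param lam_V membrane stretch at the onset of voiding.
#' @return Thickness (mm).
#' @export
evolved_thickness <- function(w, m_m = w$smc$m_m, lam_V) {
  if (any(lam_V <= 0)) stop("evolved_thickness: lam_V must be positive", call. = FALSE)
  volumetric_growth(w, m_m) * w$H0 / lam_V^2
}

#' Urethral outlet model
#'
#' Linear pressure-flow law of the urethra: no flow below the cutoff pressure
#' \code{p_c}; above it the flow rate is \code{(p - p_c) / alpha} where
#' \code{alpha} is the urethral resistance. Partial outlet obstruction raises
#' both parameters.
#'
#' @param alpha urethral resistance (Pa per ml/s).
#' @param p_c cutoff pressure (Pa).
#' @return An object of class \code{"outlet_model"}.
#' @export
outlet_model <- function(alpha, p_c) {
  if (!(alpha > 0)) stop("outlet_model: 'alpha' must be positive", call. = FALSE)
  if (!(p_c > 0)) stop("outlet_model: 'p_c' must be positive", call. = FALSE)
  structure(list(alpha = alpha, p_c = p_c), class = "outlet_model")
}

#' @export
print.outlet_model <- function(x, ...) {
  cat(sprintf("Urethral outlet: resistance %.5g Pa/(ml/s), cutoff %.5g Pa\n",
              x$alpha, x$p_c))
  invisible(x)
}
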