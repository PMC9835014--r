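#' Fit a triangular recruitment distribution to recruited-fraction data
#'
#' Fiber tracing under multiphoton microscopy yields, at each applied biaxial
#' stretch, the fraction of collagen fibers that have straightened and are
#' load bearing. That fraction is the cumulative distribution of the
#' recruitment stretch, so the triangular distribution is fit by least
#' squares on its (piecewise quadratic) CDF. The parameters are optimized
#' under the ordering constraint \code{1 <= min <= mode <= max} through the
#' reparameterization \code{(min, mode - min, max - mode)} with bound
#' constraints.
#'
#' @param fractions a data frame with columns \code{stretch} and
#'   \code{fraction} (recruited fraction in \code{[0, 1]}), or two vectors
#'   via \code{stretch} and \code{fraction}.
#' @param stretch,fraction alternative vector interface.
#' @param start optional starting \code{\link{recruitment_distribution}}.
#' @return An object of class \code{"recruitment_fit"} with components
#'   \code{dist} (the fitted \code{\link{recruitment_distribution}}),
#'   \code{residuals}, \code{rss}, \code{fitted}, \code{data} and the
#'   underlying \code{nls} fit. Methods: \code{print}, \code{coef},
#'   \code{predict}, \code{residuals}.
#' @examples
#' rd <- recruitment_distribution(1.1, 1.2, 1.35)
#' s <- seq(1.0, 1.5, by = 0.02)
#' fit <- fit_recruitment(data.frame(stretch = s, fraction = recruitment_cdf(rd, s)))
#' coef(fit)
#' @export
fit_recruitment <- function(fractions = NULL, stretch = fractions$stretch,
                            fraction = fractions$fraction, start = NULL) {
  ok <- is.finite(stretch) & is.finite(fraction)
  stretch <- stretch[ok]; fraction <- fraction[ok]
  if (length(stretch) < 3)
    stop("fit_recruitment: need at least 3 data points", call. = FALSE)
  if (all(fraction <= 0) || all(fraction >= 1))
    stop("fit_recruitment: fractions are all 0 or all 1; ",
         "the recruitment distribution is not identifiable", call. = FALSE)
  o <- order(stretch)
  stretch <- stretch[o]; fraction <- fraction[o]

  if (is.null(start)) {
    # quantile heuristics for the starting triangle
    f <- stats::approxfun(fraction, stretch, ties = mean, rule = 2)
    lo <- max(1, f(0.05)); hi <- max(f(0.95), lo + 1e-3)
    start <- recruitment_distribution(lo, (lo + hi) / 2, hi)
  }
  cdf3 <- function(mn, d1, d2, x)
    recruitment_cdf(recruitment_distribution(mn, mn + d1, mn + d1 + d2), x)
  df <- data.frame(x = stretch, y = fraction)
  fit <- minpack.lm::nlsLM(
    y ~ cdf3(mn, d1, d2, x), data = df,
    start = list(mn = start$lam_min,
                 d1 = max(start$lam_mode - start$lam_min, 1e-4),
                 d2 = max(start$lam_max - start$lam_mode, 1e-4)),
    lower = c(1, 0, 0), upper = c(Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  dist <- recruitment_distribution(cf[["mn"]], cf[["mn"]] + cf[["d1"]],
                                   cf[["mn"]] + cf[["d1"]] + cf[["d2"]])
  res <- structure(list(dist = dist,
                        fitted = recruitment_cdf(dist, stretch),
                        residuals = fraction - recruitment_cdf(dist, stretch),
                        rss = sum((fraction - recruitment_cdf(dist, stretch))^2),
                        data = df, nls = fit),
                   class = "recruitment_fit")
  res
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat("Triangular recruitment distribution fit (least squares on the CDF)\n")
  print(x$dist)
  cat(sprintf("  %d points, residual sum of squares %.3g\n", nrow(x$data), x$rss))
  invisible(x)
}

#' @export
coef.recruitment_fit <- function(object, ...) {
  c(lam_min = object$dist$lam_min, lam_mode = object$dist$lam_mode,
    lam_max = object$dist$lam_max)
}

#' @export
predict.recruitment_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$stretch else newdata
  recruitment_cdf(object$dist, x)
}

#' @export
residuals.recruitment_fit <- function(object, ...) object$residuals

#' Fit the passive constitutive model to biaxial stress-stretch data
#'
#' With the per-layer recruitment distributions fixed (from
#' \code{\link{fit_recruitment}}), the total in-plane Cauchy stress is linear
#' in the stiffness parameters: the neo-Hookean ground matrix contributes
#' \code{2 k_nc (lam^2 - lam^-4)} and each layer's collagen ensemble
#' contributes its thickness-weighted unit-stiffness stress scaled by
#' \code{k_c}. The fit is therefore an ordinary least-squares regression on
#' these basis functions. A layer whose collagen is never recruited over the
#' measured stretch range has a structurally non-identifiable stiffness and
#' is flagged (coefficient \code{NA}).
#'
#' @param data a data frame with columns \code{stretch} and \code{stress}
#'   (Pa), stretches relative to the biaxial reference.
#' @param recruitment named list of \code{\link{recruitment_distribution}}
#'   per layer (in the same stretch frame as \code{data}).
#' @param layer_ratios named thickness fractions for the layers in
#'   \code{recruitment}.
#' @param weights \code{"relative"} (default) weights each point by the
#'   inverse square of its observed stress (floored at 1\% of the maximum),
#'   matching the multiplicative error structure of biaxial measurements and
#'   keeping the soft toe region identifiable next to MPa-scale collagen
#'   stresses; \code{"uniform"} is ordinary least squares.
#' @return An object of class \code{"passive_fit"}: \code{k_nc}, \code{k_c}
#'   (named, \code{NA} when non-identifiable), \code{fitted},
#'   \code{residuals}, \code{sigma}, \code{r_squared}, the underlying
#'   \code{lm}. Methods: \code{print}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{summary}.
#' @export
fit_passive_model <- function(data, recruitment, layer_ratios,
                              weights = c("relative", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(data), all(c("stretch", "stress") %in% names(data)),
            is.list(recruitment))
  lay <- names(recruitment)
  stopifnot(all(lay %in% names(layer_ratios)))
  lam <- data$stretch
  X <- cbind(iso = 2 * (lam^2 - lam^-4))
  for (L in lay) {
    unit <- collagen_params(k_c = 1, m_c = 1, recruitment = recruitment[[L]])
    X <- cbind(X, layer_ratios[[L]] * collagen_cauchy_stress(unit, lam))
  }
  colnames(X) <- c("iso", lay)
  identifiable <- apply(X, 2, function(col) any(abs(col) > 1e-12))
  wts <- if (weights == "relative") {
    floor_s <- 0.01 * max(abs(data$stress))
    1 / pmax(abs(data$stress), floor_s)^2
  } else rep(1, nrow(data))
  fit <- stats::lm(data$stress ~ X[, identifiable, drop = FALSE] - 1,
                   weights = wts)
  cf <- rep(NA_real_, ncol(X)); names(cf) <- colnames(X)
  cf[identifiable] <- stats::coef(fit)
  fitted <- as.vector(X[, identifiable, drop = FALSE] %*% stats::coef(fit))
  res <- data$stress - fitted
  out <- structure(list(
    k_nc = cf[["iso"]],
    k_c = cf[lay],
    identifiable = identifiable,
    fitted = fitted, residuals = res,
    sigma = sqrt(sum(res^2) / max(1, length(res) - sum(identifiable))),
    r_squared = 1 - sum(res^2) / sum((data$stress - mean(data$stress))^2),
    data = data, recruitment = recruitment, layer_ratios = layer_ratios,
    lm = fit), class = "passive_fit")
  if (!all(identifiable))
    warning("fit_passive_model: no recruitment within the measured range; ",
            "k_c not identifiable for layer(s): ",
            paste(colnames(X)[!identifiable], collapse = ", "))
  out
}

#' @export
print.passive_fit <- function(x, ...) {
  cat("Passive constitutive model fit (linear least squares)\n")
  cat(sprintf("  k_nc = %.4g Pa\n", x$k_nc))
  for (L in names(x$k_c))
    cat(sprintf("  k_c[%s] = %s\n", L,
                if (is.na(x$k_c[[L]])) "not identifiable"
                else sprintf("%.4g Pa", x$k_c[[L]])))
  cat(sprintf("  residual sd %.3g Pa, R^2 %.5f\n", x$sigma, x$r_squared))
  invisible(x)
}

#' @export
coef.passive_fit <- function(object, ...) c(k_nc = object$k_nc, object$k_c)

#' @export
predict.passive_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$data$stretch else
    if (is.data.frame(newdata)) newdata$stretch else newdata
  out <- ifelse(is.na(object$k_nc), 0, object$k_nc) * 2 * (lam^2 - lam^-4)
  for (L in names(object$k_c)) {
    if (is.na(object$k_c[[L]])) next
    p <- collagen_params(object$k_c[[L]], 1, object$recruitment[[L]])
    out <- out + object$layer_ratios[[L]] * collagen_cauchy_stress(p, lam)
  }
  out
}

#' @export
residuals.passive_fit <- function(object, ...) object$residuals

#' @export
summary.passive_fit <- function(object, ...) {
  cat(sprintf("Passive fit on %d points: k_nc %.4g Pa; ",
              nrow(object$data), object$k_nc))
  cat(paste(sprintf("k_c[%s] %.4g", names(object$k_c), object$k_c),
            collapse = ", "))
  cat(sprintf("; R^2 %.5f\n", object$r_squared))
  invisible(object)
}

#' Explant geometry record
#'
#' Measured geometry of a harvested bladder used to estimate the void
#' stretch: unloaded outer diameter and height, wall thickness, unloaded
#' internal volume, filled volume, and the passive pressure at the onset of
#' voiding.
#'
#' @param d0 unloaded outer diameter (mm).
#' @param y0 unloaded height (mm).
#' @param h0 unloaded wall thickness (mm).
#' @param v0 unloaded internal volume (ml).
#' @param v_fill filled volume (ml).
#' @param p_void pressure at onset of voiding (Pa).
#' @return An object of class \code{"explant_geometry"}.
#' @export
explant_geometry <- function(d0, y0, h0, v0, v_fill, p_void) {
  vals <- c(d0 = d0, y0 = y0, h0 = h0, v0 = v0, v_fill = v_fill,
            p_void = p_void)
  if (any(vals <= 0))
    stop("explant_geometry: all fields must be positive", call. = FALSE)
  structure(as.list(vals), class = "explant_geometry")
}

#' Estimate the void stretch from explant geometry and biaxial data
#'
#' Computes the tissue stretch at the onset of voiding in two frames. The
#' model frame: the unloaded bladder is replaced by an equivalent sphere of
#' equal internal volume; the filled bladder is assumed spherical; the void
#' stretch is the ratio of filled to unloaded radii. The biaxial frame: the
#' law of Laplace gives the passive wall stress of the filled bladder
#' (thinned by incompressibility, \code{h_fill = h0 / lam_F^2}), and that
#' stress is inverted on the measured biaxial stress-stretch curve by
#' monotone interpolation. Extrapolation beyond the measured stress range is
#' refused.
#'
#' @param g an \code{\link{explant_geometry}}.
#' @param data a data frame with columns \code{stretch} and \code{stress}
#'   (Pa) from biaxial testing.
#' @return A list with \code{lam_F0} (model frame), \code{lam_bar_F}
#'   (biaxial frame), \code{sigma_void} (wall stress, Pa), \code{r0} and
#'   \code{r_fill} (mm).
#' @export
estimate_void_stretch <- function(g, data) {
  stopifnot(inherits(g, "explant_geometry"))
  r0 <- radius_from_volume(g$v0)
  r_fill <- radius_from_volume(g$v_fill)
  lam_F0 <- r_fill / r0
  h_fill <- g$h0 / lam_F0^2
  sigma_void <- g$p_void * r_fill / (2 * h_fill)
  lam <- data$stretch; sig <- data$stress
  o <- order(lam); lam <- lam[o]; sig <- sig[o]
  if (sigma_void > max(sig) || sigma_void < min(sig))
    stop("estimate_void_stretch: the Laplace wall stress ",
         sprintf("%.4g Pa lies outside the measured stress range [%.4g, %.4g]; ",
                 sigma_void, min(sig), max(sig)),
         "extrapolation of the biaxial curve is not supported", call. = FALSE)
  inv <- stats::splinefun(sig, lam, method = "hyman")
  list(lam_F0 = lam_F0, lam_bar_F = inv(sigma_void),
       sigma_void = sigma_void, r0 = r0, r_fill = r_fill)
}

#' Infer the homeostatic (deposition) stretch distribution
#'
#' Converts a recruitment stretch distribution (measured relative to the
#' biaxial reference) into the distribution of fiber stretches at the onset
#' of voiding: a fiber recruited at \code{lam_R} carries stretch
#' \code{lam_bar_F / lam_R} in the voiding configuration, so the order of
#' the three parameters reverses. A maximum below 1 means all fibers are
#' slack at the onset of voiding (collagen acting as a protective sheath).
#'
#' @param dist a \code{\link{recruitment_distribution}} (biaxial frame).
#' @param lam_bar_F biaxial-frame tissue stretch at the onset of voiding.
#' @return A \code{\link{recruitment_distribution}} holding the homeostatic
#'   fiber stretches (min/mode/max).
#' @export
infer_deposition <- function(dist, lam_bar_F) {
  stopifnot(inherits(dist, "recruitment_distribution"), lam_bar_F > 0)
  .reciprocal_dist(dist, lam_bar_F)
}

#' Map stretches between the biaxial and model reference frames
#'
#' The biaxial tests and the membrane model use different unloaded reference
#' configurations; stretches map between them by anchoring the two voiding
#' stretches: multiply by \code{lam_F / lam_bar_F} (biaxial to model) or its
#' reciprocal (model to biaxial). The round trip is the identity.
#'
#' @param x stretch values to map.
#' @param lam_F model-frame void stretch.
#' @param lam_bar_F biaxial-frame void stretch.
#' @param direction \code{"to_model"} or \code{"to_biaxial"}.
#' @return Mapped stretch values.
#' @export
map_stretch <- function(x, lam_F, lam_bar_F,
                        direction = c("to_model", "to_biaxial")) {
  direction <- match.arg(direction)
  stopifnot(lam_F > 0, lam_bar_F > 0)
  if (direction == "to_model") x * lam_F / lam_bar_F else x * lam_bar_F / lam_F
}
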