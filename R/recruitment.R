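#' Triangular fiber recruitment distribution
#'
#' Collagen fibers in the bladder wall are wavy in the unloaded tissue and are
#' recruited to load bearing progressively as the tissue is stretched. The
#' stretch at which an individual fiber straightens (its recruitment stretch)
#' is modeled with a triangular probability density over
#' \code{[lam_min, lam_max]} with mode \code{lam_mode}. The same object is
#' reused to describe homeostatic (deposition) stretch distributions, i.e. the
#' preferred fiber stretch distribution at the onset of voiding.
#'
#' @param lam_min,lam_mode,lam_max minimum, modal and maximum recruitment
#'   stretch (dimensionless), \code{0 < lam_min <= lam_mode <= lam_max}.
#' @return An object of class \code{"recruitment_distribution"} with fields
#'   \code{lam_min}, \code{lam_mode}, \code{lam_max}.
#' @examples
#' rd <- recruitment_distribution(1.0, 1.2, 1.4)
#' recruitment_pdf(rd, c(0.9, 1.2, 1.5))
#' @export
recruitment_distribution <- function(lam_min, lam_mode, lam_max) {
  stopifnot(is.numeric(lam_min), is.numeric(lam_mode), is.numeric(lam_max),
            length(lam_min) == 1L, length(lam_mode) == 1L, length(lam_max) == 1L)
  if (!(lam_min > 0))
    stop("recruitment_distribution: 'lam_min' must be positive", call. = FALSE)
  if (!(lam_min <= lam_mode && lam_mode <= lam_max))
    stop("recruitment_distribution: require lam_min <= lam_mode <= lam_max ",
         sprintf("(got %.6g, %.6g, %.6g)", lam_min, lam_mode, lam_max),
         call. = FALSE)
  structure(list(lam_min = lam_min, lam_mode = lam_mode, lam_max = lam_max),
            class = "recruitment_distribution")
}

#' @export
print.recruitment_distribution <- function(x, ...) {
  if (recruitment_width(x) == 0) {
    cat(sprintf("Recruitment distribution: point mass at %.4g\n", x$lam_min))
  } else {
    cat(sprintf(
      "Recruitment distribution: min %.4g, mode %.4g, max %.4g (width %.4g, skew %.3g)\n",
      x$lam_min, x$lam_mode, x$lam_max, recruitment_width(x),
      recruitment_skew(x)))
  }
  invisible(x)
}

#' Width and skew of a recruitment distribution
#'
#' The width is \code{lam_max - lam_min}; the skew is
#' \code{(lam_mode - lam_min) / width}, in \code{[0, 1]}, with 0.5 a symmetric
#' triangle. The skew of a degenerate (zero width) distribution is \code{NA}.
#'
#' @param dist a \code{\link{recruitment_distribution}}.
#' @return A single number.
#' @export
recruitment_width <- function(dist) dist$lam_max - dist$lam_min

#' @rdname recruitment_width
#' @export
recruitment_skew <- function(dist) {
  w <- recruitment_width(dist)
  if (w == 0) return(NA_real_)
  (dist$lam_mode - dist$lam_min) / w
}

#' @rdname recruitment_width
#' @export
is_degenerate <- function(dist) recruitment_width(dist) <= 0

#' Triangular recruitment probability density
#'
#' Piecewise-linear density, zero outside \code{[lam_min, lam_max]} and
#' continuous at the mode. A zero-width distribution is a Dirac point mass;
#' its density is flagged with \code{Inf} at \code{lam_min} (dependent
#' integrals must use the point-mass branch instead of quadrature).
#'
#' @param dist a \code{\link{recruitment_distribution}}.
#' @param lam_R recruitment stretch (vectorized).
#' @return Density values (1/stretch).
#' @export
recruitment_pdf <- function(dist, lam_R) {
  lo <- dist$lam_min; md <- dist$lam_mode; hi <- dist$lam_max
  w <- hi - lo
  if (w <= 0) return(ifelse(lam_R == lo, Inf, 0))
  d1 <- md - lo
  d2 <- hi - md
  out <- numeric(length(lam_R))
  if (d1 > 0) {
    i <- lam_R > lo & lam_R <= md
    out[i] <- 2 * (lam_R[i] - lo) / (w * d1)
  }
  if (d2 > 0) {
    i <- lam_R > md & lam_R <= hi
    out[i] <- 2 * (hi - lam_R[i]) / (w * d2)
  }
  out
}

#' Triangular recruitment cumulative distribution
#'
#' The fraction of fibers recruited at tissue stretch \code{lam_R}; the
#' quantity measured experimentally by fiber tracing under multiphoton
#' microscopy. Piecewise quadratic; the value at the mode equals the skew.
#'
#' @inheritParams recruitment_pdf
#' @return Recruited fraction in \code{[0, 1]}.
#' @export
recruitment_cdf <- function(dist, lam_R) {
  lo <- dist$lam_min; md <- dist$lam_mode; hi <- dist$lam_max
  w <- hi - lo
  if (w <= 0) return(as.numeric(lam_R >= lo))
  d1 <- md - lo
  d2 <- hi - md
  out <- numeric(length(lam_R))
  if (d1 > 0) {
    i <- lam_R > lo & lam_R <= md
    out[i] <- (lam_R[i] - lo)^2 / (w * d1)
  }
  if (d2 > 0) {
    i <- lam_R > md & lam_R < hi
    out[i] <- 1 - (hi - lam_R[i])^2 / (w * d2)
  } else {
    # mode == max: upper edge is vertical, CDF reaches 1 exactly at the mode
    out[lam_R > md & lam_R < hi] <- 1
  }
  out[lam_R >= hi] <- 1
  out
}
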