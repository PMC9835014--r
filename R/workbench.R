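#' Specification for synthetic biaxial fixtures
#'
#' Describes the ground truth and noise model used to generate synthetic
#' biaxial stress-stretch curves and fiber recruited-fraction tables for
#' parameter-recovery studies. Stress noise is multiplicative Gaussian
#' (measurement and specimen variability); recruited fractions carry
#' binomial sampling noise (a finite number of traced fibers per image
#' stack).
#'
#' @param k_nc true ground-matrix stiffness (Pa).
#' @param k_c named per-layer true fiber stiffness (Pa).
#' @param recruitment named list of true
#'   \code{\link{recruitment_distribution}} per layer (biaxial frame).
#' @param layer_ratios named per-layer thickness fractions.
#' @param stretch_max largest applied equibiaxial stretch.
#' @param n_stress number of stress sample points.
#' @param n_fraction number of recruited-fraction sample points per layer.
#' @param noise_stress multiplicative stress noise standard deviation.
#' @param binom_n number of traced fibers per observation (binomial size);
#'   \code{Inf} for noise-free fractions.
#' @param seed integer seed fixing all randomness.
#' @return An object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(k_nc = 1170,
                           k_c = c(LP = 11.7e6, DL = 0.79e6),
                           recruitment = list(
                             LP = recruitment_distribution(1.17, 1.30, 1.45),
                             DL = recruitment_distribution(1.08, 1.20, 1.35)),
                           layer_ratios = c(LP = 0.30, DL = 0.60),
                           stretch_max = 1.6, n_stress = 60L,
                           n_fraction = 25L, noise_stress = 0.02,
                           binom_n = 50, seed = 1L) {
  stopifnot(noise_stress >= 0, binom_n > 0, seed == as.integer(seed))
  stopifnot(all(names(k_c) %in% names(recruitment)),
            all(names(k_c) %in% names(layer_ratios)))
  structure(list(k_nc = k_nc, k_c = k_c, recruitment = recruitment,
                 layer_ratios = layer_ratios, stretch_max = stretch_max,
                 n_stress = as.integer(n_stress),
                 n_fraction = as.integer(n_fraction),
                 noise_stress = noise_stress, binom_n = binom_n,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# evaluate a local expression under a fixed seed without disturbing the
# caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic biaxial dataset
#'
#' Produces an equibiaxial stress-stretch table and per-layer
#' recruited-fraction tables from known constitutive parameters plus seeded
#' noise. With zero noise the data lie exactly on the model curve and the
#' fraction curves equal the triangular CDF; the output is deterministic
#' given the seed.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list of class \code{"biaxial_dataset"} with \code{$stress}
#'   (data frame: stretch, stress) and \code{$fractions} (data frame: layer,
#'   stretch, fraction), plus the generating \code{$spec}.
#' @export
make_synthetic_biaxial <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    lam <- seq(1.0, spec$stretch_max, length.out = spec$n_stress)
    sig <- 2 * spec$k_nc * (lam^2 - lam^-4)
    for (L in names(spec$k_c)) {
      p <- collagen_params(spec$k_c[[L]], 1, spec$recruitment[[L]])
      sig <- sig + spec$layer_ratios[[L]] * collagen_cauchy_stress(p, lam)
    }
    if (spec$noise_stress > 0)
      sig <- sig * (1 + stats::rnorm(length(sig), 0, spec$noise_stress))
    frac <- do.call(rbind, lapply(names(spec$recruitment), function(L) {
      xs <- seq(1.0, spec$stretch_max, length.out = spec$n_fraction)
      f <- recruitment_cdf(spec$recruitment[[L]], xs)
      if (is.finite(spec$binom_n))
        f <- stats::rbinom(length(f), spec$binom_n, f) / spec$binom_n
      data.frame(layer = L, stretch = xs, fraction = f,
                 stringsAsFactors = FALSE)
    }))
    structure(list(stress = data.frame(stretch = lam, stress = sig),
                   fractions = frac, spec = spec),
              class = "biaxial_dataset")
  })
}

#' @export
print.biaxial_dataset <- function(x, ...) {
  cat(sprintf("Synthetic biaxial dataset: %d stress points to stretch %.3g; ",
              nrow(x$stress), max(x$stress$stretch)))
  cat(sprintf("%d recruited-fraction points in %d layer(s)\n",
              nrow(x$fractions), length(unique(x$fractions$layer))))
  invisible(x)
}

# hash of the configuration for provenance logging in result bundles
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Run a canned experiment
#'
#' Three ready-made simulation experiments: \code{"sham_cycle"} (one healthy
#' filling/voiding cycle), \code{"boo_adaptation"} (4 weeks of growth and
#' remodeling after partial outlet obstruction under the configured growth
#' hypothesis) and \code{"growth_comparison"} (the obstruction scenario under
#' all three growth hypotheses). Returns the simulation objects plus a flat
#' summary of the headline quantities; optionally writes time-series CSVs
#' and a JSON summary to \code{out_dir}.
#'
#' @param name experiment name.
#' @param cfg a \code{\link{bladder_config}}.
#' @param out_dir optional output directory (created if missing).
#' @param tau_end duration (day) of the growth-remodeling experiments.
#' @return A list with \code{$summary} (named numerics), the underlying
#'   result objects, and \code{$log} (config hash and solver settings).
#' @export
run_experiment <- function(name = c("sham_cycle", "boo_adaptation",
                                    "growth_comparison"),
                           cfg = bladder_config(), out_dir = NULL,
                           tau_end = 28) {
  name <- match.arg(name)
  log <- list(config_hash = .config_hash(cfg), dt = cfg$solver$dt,
              dtau = cfg$solver$dtau, seed = cfg$seed)
  out <- switch(
    name,
    sham_cycle = {
      mc <- sham_cycle(cfg)
      list(summary = c(v_void = mc$v_void, t_void = mc$t_void,
                       v_res = mc$v_res, p_void_max = mc$p_void_max,
                       p_passive_max = mc$p_passive_max,
                       p_act_max = mc$p_act_max, q_max = mc$q_max,
                       q_avg = mc$q_avg),
           cycle = mc)
    },
    boo_adaptation = {
      mc <- sham_cycle(cfg)
      gr <- simulate_gr(cfg, tau_end = tau_end)
      h <- gr$history; cl <- gr$cycles; n <- nrow(h)
      last <- cl[nrow(cl), ]
      list(summary = c(
        radius_filled = last$radius_F, v_res = last$v_res,
        v_void = last$v_void, t_void = last$t_void,
        p_void_max = last$p_void_max, q_max = last$q_max,
        mass = h$mass[n], m_m = h$m_m[n], v_hat = h$v_hat[n],
        thickness = h$thickness[n],
        max_leaky_radius = max(h$radius[h$mode == "leaky"]),
        flow_reduction_pct = 100 * (1 - last$q_max / mc$q_max)),
        gr = gr, sham = mc)
    },
    growth_comparison = {
      runs <- lapply(c(GF1 = "GF1", GF2 = "GF2", GF3 = "GF3"), function(hy)
        simulate_gr(cfg, hypothesis = hy, tau_end = tau_end))
      sm <- unlist(lapply(names(runs), function(hy) {
        g <- runs[[hy]]
        last <- g$cycles[nrow(g$cycles), ]
        stats::setNames(c(g$history$m_m[nrow(g$history)], last$v_void,
                          last$p_void_max, last$t_void),
                        paste0(tolower(hy), c("_m_m", "_v_void",
                                              "_p_void_max", "_t_void")))
      }))
      c(list(summary = sm), runs)
    })
  out$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$cycle))
      utils::write.csv(out$cycle$series,
                       file.path(out_dir, "cycle_series.csv"),
                       row.names = FALSE)
    if (!is.null(out$gr)) {
      utils::write.csv(out$gr$history, file.path(out_dir, "gr_history.csv"),
                       row.names = FALSE)
      utils::write.csv(out$gr$cycles, file.path(out_dir, "gr_cycles.csv"),
                       row.names = FALSE)
    }
    summ <- c(as.list(out$summary), out$log)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      dput(summ, file.path(out_dir, "summary.R"))
    }
  }
  out
}
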