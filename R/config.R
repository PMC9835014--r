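#' Default scenario configuration
#'
#' Builds the full configuration of a simulation scenario: wall geometry and
#' constitutive parameters of the healthy male rat bladder, sham and
#' obstructed outlet parameters, stimulus dynamics, homeostatic targets,
#' growth-remodeling rates and solver settings. Values not overridden default
#' to the calibrated rat parameter set. Units are fixed repo-wide: Pa, mm,
#' ml, s (fast time), day (slow time).
#'
#' The stimulus constants (\code{k_m1}, \code{k_m2}, \code{q_crit},
#' \code{t_end}) are not identifiable from tissue data; the shipped defaults
#' are calibrated with \code{\link{calibrate_stimulus}} so that the sham
#' bladder reproduces the measured voided volume and voiding duration.
#'
#' @param ... named overrides of top-level fields (nested lists are replaced
#'   wholesale). Unknown names are rejected.
#' @return An object of class \code{"bladder_config"} (a nested list).
#' @examples
#' cfg <- bladder_config()
#' cfg$outlet_boo$p_c
#' @export
bladder_config <- function(...) {
  cfg <- list(
    wall = list(
      R0 = 3.0,                    # unloaded radius, mm
      H0 = 0.78,                   # unloaded wall thickness, mm
      layer_ratios = c(LP = 0.30, DL = 0.60, AD = 0.10),
      k_nc = 1170,                 # ground matrix stiffness, Pa
      k_c = c(LP = 11.7e6, DL = 0.79e6, AD = 11.7e6),  # fiber stiffness, Pa
      vol_fractions = c(elastin = 0.01, collagen = 0.29, smc = 0.70),
      lam_F0 = 1.94                # initial stretch at onset of voiding
    ),
    smc = list(
      k_m_act = 5770,              # active modulus, Pa (absorbs DL ratio)
      lam_m_min = 0.25,
      lam_m_max = 2.5,
      lam_m_h = 1.5,               # homeostatic SMC stretch at voiding onset
      m_m = 1
    ),
    deposition = list(             # homeostatic fiber stretch distributions
      LP = c(0.77, 0.82, 0.87),
      DL = c(0.84, 0.90, 0.97),
      AD = c(0.60, 0.70, 0.80)
    ),
    outlet_sham = list(alpha = 19800, p_c = 1450),    # Pa/(ml/s), Pa
    outlet_boo  = list(alpha = 22075, p_c = 8487),
    stimulus = list(
      k_m1 = 3.856,                # ramp-up time constant, s (calibrated)
      k_m2 = 1.0,                  # ramp-down time constant, s
      q_crit = 0.001,              # flow threshold for ramp-down, ml/s
      t_end = 50                   # hard stimulus end, s
    ),
    gr = list(
      alpha_c = 3.6,               # collagen remodeling rate, 1/week
      alpha_m = 40,                # SMC remodeling rate, 1/day (fast)
      beta_smc = 5,                # SMC growth rate, 1/week
      hypothesis = "GF1",          # GF1 voided volume | GF2 mean flow | GF3 contractile range
      recovery_margin = 0.02,      # voided SMC stretch margin ending leaky mode
      q_in = 0.84,                 # filling rate, ml/day (one sham void per day)
      mass_sham = 0.11             # sham bladder mass, g, for mass reporting
    ),
    solver = list(
      dt = 0.01,                   # micturition integration step, s
      dtau = 0.005,                # growth-remodeling step, day
      t_max_void = 300,            # voiding time cap, s
      lam_cap = 6                  # abort if the stretch grows past this
    ),
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("bladder_config: unknown field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(over)) {
      if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
        bad2 <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
        if (length(bad2))
          stop("bladder_config: unknown field(s) in '", nm, "': ",
               paste(bad2, collapse = ", "), call. = FALSE)
        cfg[[nm]][names(over[[nm]])] <- over[[nm]]
      } else {
        cfg[[nm]] <- over[[nm]]
      }
    }
  }
  structure(validate_config(cfg), class = "bladder_config")
}

#' Validate a scenario configuration
#'
#' Checks field-level invariants (positivity, ordering, fractions summing to
#' one) and returns the configuration invisibly unchanged; errors name the
#' offending field.
#'
#' @param cfg a configuration list.
#' @return The validated configuration.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("config: field '", field, "' ", msg, call. = FALSE)
  }
  chk(cfg$wall$R0 > 0, "wall$R0", "must be positive")
  chk(cfg$wall$H0 > 0, "wall$H0", "must be positive")
  chk(abs(sum(cfg$wall$layer_ratios) - 1) < 1e-8, "wall$layer_ratios",
      "must sum to 1")
  chk(cfg$wall$k_nc > 0, "wall$k_nc", "must be positive")
  chk(all(cfg$wall$k_c > 0), "wall$k_c", "must be positive")
  chk(abs(sum(cfg$wall$vol_fractions) - 1) < 1e-8, "wall$vol_fractions",
      "must sum to 1")
  chk(cfg$wall$lam_F0 > 1, "wall$lam_F0", "must exceed 1")
  for (L in c("LP", "DL", "AD")) {
    d <- cfg$deposition[[L]]
    chk(length(d) == 3 && all(d > 0) && !is.unsorted(d),
        paste0("deposition$", L), "must be three increasing positive stretches")
  }
  chk(cfg$smc$k_m_act > 0, "smc$k_m_act", "must be positive")
  chk(cfg$smc$lam_m_min > 0 && cfg$smc$lam_m_min < cfg$smc$lam_m_h &&
        cfg$smc$lam_m_h < cfg$smc$lam_m_max, "smc",
      "requires lam_m_min < lam_m_h < lam_m_max")
  for (o in c("outlet_sham", "outlet_boo")) {
    chk(cfg[[o]]$alpha > 0, paste0(o, "$alpha"), "must be positive")
    chk(cfg[[o]]$p_c > 0, paste0(o, "$p_c"), "must be positive")
  }
  chk(cfg$stimulus$k_m1 > 0 && cfg$stimulus$k_m2 > 0, "stimulus",
      "time constants must be positive")
  chk(cfg$stimulus$q_crit >= 0, "stimulus$q_crit", "must be non-negative")
  chk(cfg$stimulus$t_end > 0, "stimulus$t_end", "must be positive")
  chk(all(unlist(cfg$gr[c("alpha_c", "alpha_m", "beta_smc")]) >= 0),
      "gr rates", "must be non-negative")
  chk(cfg$gr$hypothesis %in% c("GF1", "GF2", "GF3"), "gr$hypothesis",
      "must be GF1, GF2 or GF3")
  chk(cfg$gr$q_in > 0, "gr$q_in", "must be positive")
  chk(cfg$solver$dt > 0 && cfg$solver$dtau > 0, "solver", "steps must be positive")
  invisible(cfg)
}

#' @export
print.bladder_config <- function(x, ...) {
  cat("Bladder scenario configuration\n")
  cat(sprintf("  wall: R0 %.3g mm, H0 %.3g mm, k_nc %.4g Pa, lam_F0 %.4g\n",
              x$wall$R0, x$wall$H0, x$wall$k_nc, x$wall$lam_F0))
  cat(sprintf("  outlets: sham (alpha %.5g, Pc %.5g) | obstructed (alpha %.5g, Pc %.5g)\n",
              x$outlet_sham$alpha, x$outlet_sham$p_c,
              x$outlet_boo$alpha, x$outlet_boo$p_c))
  cat(sprintf("  stimulus: k_m1 %.3g s, k_m2 %.3g s, q_crit %.3g ml/s, t_end %.3g s\n",
              x$stimulus$k_m1, x$stimulus$k_m2, x$stimulus$q_crit,
              x$stimulus$t_end))
  cat(sprintf("  G&R: alpha_c %.3g, alpha_m %.3g, beta_smc %.3g /day, hypothesis %s, q_in %.3g ml/day\n",
              x$gr$alpha_c, x$gr$alpha_m, x$gr$beta_smc, x$gr$hypothesis,
              x$gr$q_in))
  invisible(x)
}

#' Save or load a configuration
#'
#' Round-trips a \code{\link{bladder_config}} through YAML. Loading starts
#' from the defaults, overlays the stored fields, rejects unknown keys and
#' re-validates, so an empty file yields the default scenario.
#'
#' @param cfg a \code{\link{bladder_config}}.
#' @param path file path.
#' @return \code{load_config} returns a validated \code{bladder_config};
#'   \code{save_config} returns \code{path} invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(prepare_yaml(unclass(cfg)), path)
  invisible(path)
}

prepare_yaml <- function(x) {
  if (is.list(x)) return(lapply(x, prepare_yaml))
  if (!is.null(names(x))) return(as.list(x))
  x
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(bladder_config())
  cfg <- unclass(bladder_config())
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("load_config: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(raw)) {
    if (is.list(cfg[[nm]]) && !is.null(names(raw[[nm]]))) {
      bad2 <- setdiff(names(raw[[nm]]), names(cfg[[nm]]))
      if (length(bad2))
        stop("load_config: unknown field(s) in '", nm, "': ",
             paste(bad2, collapse = ", "), call. = FALSE)
      for (k in names(raw[[nm]])) {
        v <- raw[[nm]][[k]]
        tmpl <- cfg[[nm]][[k]]
        if (!is.null(names(tmpl)) && is.list(v)) v <- unlist(v)
        cfg[[nm]][[k]] <- v
      }
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  structure(validate_config(cfg), class = "bladder_config")
}

# Reciprocal stretch map between a recruitment-type distribution and its
# paired deposition-type distribution: (s/max, s/mode, s/min).
.reciprocal_dist <- function(dist, s) {
  recruitment_distribution(s / dist$lam_max, s / dist$lam_mode, s / dist$lam_min)
}

#' Build the wall model of a configuration
#'
#' Assembles a \code{\link{wall_model}} from a configuration. Collagen
#' recruitment distributions (relative to the unloaded configuration) are
#' placed so that the fiber stretch distribution at the onset of voiding
#' (membrane stretch \code{lam_F0}) equals the homeostatic deposition
#' distribution; the SMC recruitment stretch is \code{lam_F0 / lam_m_h} so
#' the muscle sits at its homeostatic stretch when voiding is triggered.
#'
#' @param cfg a \code{\link{bladder_config}}.
#' @return A \code{\link{wall_model}}.
#' @export
build_wall <- function(cfg = bladder_config()) {
  lamF <- cfg$wall$lam_F0
  coll <- lapply(c(LP = "LP", DL = "DL", AD = "AD"), function(L) {
    dep <- cfg$deposition[[L]]
    collagen_params(
      k_c = cfg$wall$k_c[[L]], m_c = 1,
      recruitment = .reciprocal_dist(
        recruitment_distribution(dep[1], dep[2], dep[3]), lamF))
  })
  wall_model(
    R0 = cfg$wall$R0, H0 = cfg$wall$H0,
    layer_ratios = cfg$wall$layer_ratios,
    iso = isotropic_params(cfg$wall$k_nc),
    collagen = coll,
    smc = smc_params(k_m_act = cfg$smc$k_m_act,
                     lam_m_min = cfg$smc$lam_m_min,
                     lam_m_max = cfg$smc$lam_m_max,
                     lam_Rm = lamF / cfg$smc$lam_m_h,
                     m_m = cfg$smc$m_m,
                     lam_m_h = cfg$smc$lam_m_h),
    vol_fractions = cfg$wall$vol_fractions)
}

#' @rdname build_wall
#' @export
sham_wall <- function(cfg = bladder_config()) build_wall(cfg)

#' Outlet models of a configuration
#'
#' @param cfg a \code{\link{bladder_config}}.
#' @return An \code{\link{outlet_model}}.
#' @export
sham_outlet <- function(cfg = bladder_config())
  outlet_model(cfg$outlet_sham$alpha, cfg$outlet_sham$p_c)

#' @rdname sham_outlet
#' @export
boo_outlet <- function(cfg = bladder_config())
  outlet_model(cfg$outlet_boo$alpha, cfg$outlet_boo$p_c)

#' @rdname sham_outlet
#' @export
build_stimulus <- function(cfg = bladder_config())
  stimulus_params(cfg$stimulus$k_m1, cfg$stimulus$k_m2, cfg$stimulus$q_crit,
                  cfg$stimulus$t_end)

#' Simulate one sham filling/voiding cycle
#'
#' Fills the configured healthy bladder to the voiding trigger (SMC stretch
#' reaching its homeostatic value) and simulates the voiding event.
#'
#' @param cfg a \code{\link{bladder_config}}.
#' @return A \code{\link{simulate_void}} result.
#' @export
sham_cycle <- function(cfg = bladder_config()) {
  w <- build_wall(cfg)
  v_trigger <- volume_from_radius(cfg$smc$lam_m_h * w$smc$lam_Rm * w$R0)
  simulate_void(w, sham_outlet(cfg), build_stimulus(cfg), v_start = v_trigger,
                q_in = cfg$gr$q_in / 86400, dt = cfg$solver$dt,
                t_max = cfg$solver$t_max_void)
}

#' Calibrate the stimulus ramp-up to the sham voiding duration
#'
#' The stimulus constants cannot be identified from tissue data, so the
#' ramp-up constant is tuned (by bisection) until one sham cycle reproduces a
#' target voiding duration. The remaining constants are fixed: the ramp-down
#' constant shapes only the tail of the flow curve and the flow threshold
#' sets where the tail is cut.
#'
#' @param cfg a \code{\link{bladder_config}}.
#' @param t_void_target target sham voiding duration (s).
#' @param interval search interval for \code{k_m1} (s).
#' @return The calibrated \code{k_m1} (s).
#' @export
calibrate_stimulus <- function(cfg = bladder_config(), t_void_target = 12,
                               interval = c(0.3, 6)) {
  f <- function(k1) {
    cfg$stimulus$k_m1 <- k1
    sham_cycle(cfg)$t_void - t_void_target
  }
  stats::uniroot(f, interval, tol = 1e-3)$root
}
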