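#' Urethral flow rate
#'
#' Flow through the outlet at bladder pressure \code{p}: zero below the
#' cutoff, linear above it with slope \code{1/alpha}.
#'
#' @param o an \code{\link{outlet_model}}.
#' @param p bladder pressure (Pa, vectorized).
#' @return Flow rate (ml/s).
#' @export
flow_rate <- function(o, p) pmax(0, p - o$p_c) / o$alpha

#' Steady leakage pressure
#'
#' In the leaky (overflow incontinence) mode the outflow equals the filling
#' rate, which fixes the pressure at \code{alpha * q_in + p_c}.
#'
#' @param o an \code{\link{outlet_model}}.
#' @param q_in filling rate (ml/s), non-negative.
#' @return Pressure (Pa).
#' @export
leaky_pressure <- function(o, q_in) {
  if (any(q_in < 0)) stop("leaky_pressure: q_in must be non-negative", call. = FALSE)
  o$alpha * q_in + o$p_c
}

#' Bladder state snapshot
#'
#' @param volume luminal volume (ml).
#' @param lam membrane stretch (consistent with \code{volume} for a given
#'   unloaded radius).
#' @param mode \code{"functional"} or \code{"leaky"}.
#' @return An object of class \code{"bladder_state"}.
#' @export
bladder_state <- function(volume, lam, mode = c("functional", "leaky")) {
  mode <- match.arg(mode)
  if (!(volume > 0)) stop("bladder_state: volume must be positive", call. = FALSE)
  structure(list(volume = volume, lam = lam, mode = mode),
            class = "bladder_state")
}

#' Steady leaky state
#'
#' Finds the membrane stretch at which the passive wall pressure balances the
#' steady leakage pressure, by bracketed root finding. This is the state the
#' obstructed bladder settles into while it cannot actively void.
#'
#' @param w a \code{\link{wall_model}}.
#' @param o an \code{\link{outlet_model}}.
#' @param q_in filling rate (ml/s).
#' @param lam_max upper end of the search bracket for the stretch.
#' @return A \code{\link{bladder_state}} with \code{mode = "leaky"}.
#' @export
leaky_state <- function(w, o, q_in, lam_max = 6) {
  p_target <- leaky_pressure(o, q_in)
  f <- function(lam) passive_pressure(w, lam) - p_target
  if (f(lam_max) < 0)
    stop("leaky_state: the passive wall cannot sustain the leakage pressure ",
         sprintf("%.4g Pa within the stretch bracket (1, %.3g]", p_target, lam_max),
         call. = FALSE)
  root <- stats::uniroot(f, c(1 + 1e-9, lam_max), tol = 1e-12)
  lam <- root$root
  bladder_state(volume = volume_from_radius(lam * w$R0), lam = lam,
                mode = "leaky")
}

# Fast scalar evaluator of the passive pressure: a monotone cubic
# interpolant built once per voiding simulation (collagen recruitment is
# frozen on the micturition timescale).
.passive_interp <- function(w, lam_hi, n = 400L) {
  grid <- seq(0.05, lam_hi, length.out = n)
  stats::splinefun(grid, passive_pressure(w, grid), method = "monoH.FC")
}

#' Simulate one voiding event
#'
#' Integrates the volume balance \code{dV/dt = q_in - Q(t)} of a triggered
#' voiding contraction. The nervous stimulus ramps up from the start of the
#' simulation; flow begins once the total (passive + active) pressure exceeds
#' the outlet cutoff, and the stimulus ramp-down is latched when the flow
#' falls back below \code{stim$q_crit}. Classic fourth-order Runge-Kutta with
#' a fixed step; the voided volume is accumulated as a second state variable
#' so that volume is conserved to machine precision.
#'
#' If the wall cannot reach the cutoff pressure even at full stimulus, the
#' result is returned immediately as a failed void (\code{failed = TRUE},
#' zero voided volume); the growth-remodeling loop uses this marker to enter
#' the leaky mode.
#'
#' @param w a \code{\link{wall_model}} (its \code{smc$lam_Rm} and
#'   \code{smc$m_m} describe the current remodeling state).
#' @param o an \code{\link{outlet_model}}.
#' @param stim a \code{\link{stimulus_params}}.
#' @param v_start bladder volume at the trigger (ml).
#' @param q_in filling rate held during voiding (ml/s); negligible in
#'   practice.
#' @param dt integration step (s).
#' @param t_max hard time cap (s).
#' @return An object of class \code{"micturition"}: urodynamic metrics
#'   (\code{v_void}, \code{v_res}, \code{v_fill}, \code{t_void},
#'   \code{p_void_max}, \code{p_passive_max}, \code{p_act_max}, \code{q_max},
#'   \code{q_avg}, \code{lam_m_cyc}, \code{t_crit}, \code{failed}) plus the
#'   sampled trajectory in \code{$series}.
#' @export
simulate_void <- function(w, o, stim, v_start, q_in = 0, dt = 0.01,
                          t_max = 300) {
  stopifnot(v_start > 0)
  R0 <- w$R0
  lam_Rm <- w$smc$lam_Rm
  m_m <- w$smc$m_m
  lm_min <- w$smc$lam_m_min
  lm_max <- w$smc$lam_m_max
  act_pref <- 2 * w$H0 * w$smc$k_m_act / (R0 * lam_Rm^3) * m_m
  alpha <- o$alpha; p_c <- o$p_c
  k1 <- stim$k_m1; k2 <- stim$k_m2; q_crit <- stim$q_crit; t_end <- stim$t_end
  vol_c <- 3000 / (4 * pi)            # ml -> mm^3 radius conversion constant

  lam_start <- radius_from_volume(v_start) / R0
  pfun <- .passive_interp(w, lam_hi = lam_start * 1.2 + 0.2)

  lam_of_v <- function(v) (vol_c * pmax(v, 1e-9))^(1 / 3) / R0
  press <- function(v, s) {
    lam <- lam_of_v(v)
    lm <- lam / lam_Rm
    pa <- if (lm > lm_min && lm < lm_max)
      act_pref * s * (lm + 1 / lm) * (lm - lm_min) * (lm_max - lm) else 0
    max(0, pfun(lam)) + pa
  }

  # unreachable cutoff even at full stimulus: failed void
  if (press(v_start, 1) <= p_c) {
    res <- list(v_void = 0, v_res = v_start, v_fill = v_start, t_void = 0,
                p_void_max = press(v_start, 1), p_passive_max = NA_real_,
                p_act_max = NA_real_, q_max = 0, q_avg = 0,
                lam_m_cyc = 0, t_crit = NA_real_, failed = TRUE,
                series = data.frame(t = 0, V = v_start,
                                    P = press(v_start, 1), Q = 0, S = 0,
                                    lam = lam_start,
                                    lam_m = lam_start / lam_Rm))
    class(res) <- "micturition"
    return(res)
  }

  s_up <- function(t) 1 - 1 / (1 + (t / k1)^4)
  n_cap <- ceiling(t_max / dt) + 1L
  ts <- Ps <- Qs <- Vs <- Ss <- numeric(n_cap)

  V <- v_start; Vout <- 0; t <- 0
  t_crit <- NA_real_; s_at_crit <- NA_real_
  exceeded <- FALSE; started <- FALSE
  t_first <- NA_real_; t_last <- NA_real_; lam_onset <- NA_real_
  i <- 1L

  s_of <- function(t) {
    if (t > t_end) return(0)
    if (is.na(t_crit) || t <= t_crit) return(s_up(t))
    s_at_crit / (1 + ((t - t_crit) / k2)^4)
  }
  deriv <- function(t, V) {
    P <- press(V, s_of(t))
    Q <- if (P > p_c) (P - p_c) / alpha else 0
    c(q_in - Q, Q)
  }

  repeat {
    s_now <- s_of(t)
    P_now <- press(V, s_now)
    Q_now <- if (P_now > p_c) (P_now - p_c) / alpha else 0
    ts[i] <- t; Vs[i] <- V; Ps[i] <- P_now; Qs[i] <- Q_now; Ss[i] <- s_now
    if (Q_now > 0) {
      if (!started) { started <- TRUE; t_first <- t; lam_onset <- lam_of_v(V) }
      t_last <- t
      if (Q_now >= q_crit) exceeded <- TRUE
    }
    if (is.na(t_crit) && exceeded && Q_now < q_crit) {
      t_crit <- t
      s_at_crit <- s_up(t)
    }
    # after the ramp-down is latched the stimulus only decays, so once flow
    # has ceased it cannot restart
    if (started && Q_now == 0 && (!is.na(t_crit) || s_now < 1e-4)) break
    if (t > t_end && Q_now == 0) break
    if (i >= n_cap) break

    k1v <- deriv(t, V)
    k2v <- deriv(t + dt / 2, V + dt / 2 * k1v[1])
    k3v <- deriv(t + dt / 2, V + dt / 2 * k2v[1])
    k4v <- deriv(t + dt, V + dt * k3v[1])
    V <- max(V + dt / 6 * (k1v[1] + 2 * k2v[1] + 2 * k3v[1] + k4v[1]), 1e-8)
    Vout <- Vout + dt / 6 * (k1v[2] + 2 * k2v[2] + 2 * k3v[2] + k4v[2])
    t <- t + dt
    i <- i + 1L
  }

  idx <- seq_len(i)
  series <- data.frame(t = ts[idx], V = Vs[idx], P = Ps[idx], Q = Qs[idx],
                       S = Ss[idx], lam = lam_of_v(Vs[idx]),
                       lam_m = lam_of_v(Vs[idx]) / lam_Rm)

  t_void <- if (started) t_last - t_first else 0
  v_void <- Vout
  lam_end <- lam_of_v(V)
  p_passive_max <- if (started) max(0, pfun(lam_onset)) else NA_real_
  p_void_max <- max(series$P)
  res <- list(
    v_void = v_void,
    v_res = V,
    v_fill = v_start + q_in * t,
    t_void = t_void,
    p_void_max = p_void_max,
    p_passive_max = p_passive_max,
    p_act_max = if (started) p_void_max - p_passive_max else NA_real_,
    q_max = max(series$Q),
    q_avg = if (t_void > 0) v_void / t_void else 0,
    lam_m_cyc = lam_start / lam_Rm - lam_end / lam_Rm,
    t_crit = t_crit,
    failed = !started,
    series = series)
  class(res) <- "micturition"
  res
}

#' Urodynamic metrics from a sampled trajectory
#'
#' Recomputes the scalar cystometric metrics from a \code{(t, P, Q, V)}
#' trajectory: peak voiding pressure, passive pressure at flow onset, their
#' difference (maximum active pressure), peak and average flow, voided
#' volume and voiding duration (first to last nonzero flow).
#'
#' @param series a data frame with columns \code{t}, \code{P}, \code{Q},
#'   \code{V} (and optionally \code{lam_m}).
#' @return A named list of metrics.
#' @export
urodynamic_metrics <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0)
    stop("urodynamic_metrics: empty trajectory", call. = FALSE)
  flowing <- which(series$Q > 0)
  if (length(flowing) == 0) {
    return(list(v_void = 0, t_void = 0, p_void_max = max(series$P),
                p_passive_max = NA_real_, p_act_max = NA_real_,
                q_max = 0, q_avg = 0,
                lam_m_cyc = if (!is.null(series$lam_m))
                  series$lam_m[1] - series$lam_m[nrow(series)] else NA_real_))
  }
  i0 <- flowing[1]; i1 <- flowing[length(flowing)]
  t_void <- series$t[i1] - series$t[i0]
  # trapezoidal voided volume over the flow interval
  tt <- series$t[i0:i1]; qq <- series$Q[i0:i1]
  v_void <- if (length(tt) > 1)
    sum(diff(tt) * (utils::head(qq, -1) + utils::tail(qq, -1)) / 2) else 0
  p_void_max <- max(series$P)
  # passive pressure at flow onset; the total pressure there is passive plus
  # whatever active stress the ramp has produced, so a dedicated passive
  # column is used when present and the onset total otherwise
  p_passive_max <- if (!is.null(series$P_passive)) series$P_passive[i0] else series$P[i0]
  list(v_void = v_void, t_void = t_void, p_void_max = p_void_max,
       p_passive_max = p_passive_max, p_act_max = p_void_max - p_passive_max,
       q_max = max(series$Q), q_avg = if (t_void > 0) v_void / t_void else 0,
       lam_m_cyc = if (!is.null(series$lam_m))
         series$lam_m[1] - series$lam_m[nrow(series)] else NA_real_)
  }

#' @export
print.micturition <- function(x, ...) {
  if (x$failed) {
    cat("Voiding attempt FAILED (cutoff pressure not reached)\n")
    cat(sprintf("  peak achievable pressure %.4g Pa, volume %.3g ml retained\n",
                x$p_void_max, x$v_res))
    return(invisible(x))
  }
  cat("Micturition cycle\n")
  cat(sprintf("  voided %.3f ml in %.1f s (residual %.3f ml)\n",
              x$v_void, x$t_void, x$v_res))
  cat(sprintf("  peak pressure %.3g kPa (passive %.3g kPa, active %.3g kPa)\n",
              x$p_void_max / 1000, x$p_passive_max / 1000, x$p_act_max / 1000))
  cat(sprintf("  peak flow %.3g ml/s, mean flow %.3g ml/s\n", x$q_max, x$q_avg))
  invisible(x)
}

#' @export
summary.micturition <- function(object, ...) {
  out <- unclass(object)
  out$series <- NULL
  structure(out, class = "summary.micturition")
}

#' @export
print.summary.micturition <- function(x, ...) {
  df <- data.frame(metric = names(x),
                   value = vapply(x, function(v) as.numeric(v)[1], 0))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.micturition <- function(x, ...) x$series

#' @export
plot.micturition <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$series$t, x$series$P / 1000, type = "l", xlab = "time (s)",
                 ylab = "pressure (kPa)", ...)
  graphics::plot(x$series$t, x$series$Q, type = "l", xlab = "time (s)",
                 ylab = "flow (ml/s)", ...)
  invisible(x)
}
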