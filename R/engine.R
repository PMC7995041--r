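#' Simulation configuration
#'
#' Bundles the lung, diverter, screw, trigger and integration settings of
#' one run. The 60 s default horizon gives 12-20 steady-state breaths
#' depending on the EC screw; the first \code{transient_discard} cycles
#' are dropped by the downstream analytics.
#'
#' @param lung a [lung_parameters()] object.
#' @param diverter a [diverter_config()] object.
#' @param screws a [screw_settings()] object.
#' @param trigger a [trigger_schedule()] object.
#' @param dt base integration step, s.
#' @param duration simulated horizon, s; must be at least \code{10 * dt}.
#' @param transient_discard initial cycles dropped by analytics.
#' @return An object of class \code{simulation_config}.
#' @export
#' @examples
#' cfg <- simulation_config(lung = lung_preset("healthy"))
simulation_config <- function(lung = lung_preset("healthy"),
                              diverter = diverter_config(),
                              screws = screw_settings(),
                              trigger = trigger_schedule(),
                              dt = 0.001, duration = 60,
                              transient_discard = 2) {
  stopifnot(inherits(lung, "lung_parameters"),
            inherits(diverter, "diverter_config"),
            inherits(screws, "screw_settings"),
            inherits(trigger, "trigger_schedule"))
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (duration < 10 * dt) {
    stop("`duration` must be at least 10 * dt", call. = FALSE)
  }
  check_number(transient_discard, "transient_discard", lower = 0)
  # validate the threshold map for these screws up front
  switching_thresholds(screws, diverter)
  structure(
    list(lung = lung, diverter = diverter, screws = screws,
         trigger = trigger, dt = dt, duration = duration,
         transient_discard = as.integer(transient_discard)),
    class = "simulation_config")
}

#' Closed-form expiratory pressure decay
#'
#' During expiration (no trigger, constant resistances) the coupled
#' diverter-lung system reduces to a linear RC discharge: alveolar
#' pressure relaxes exponentially from \code{P_start} toward the
#' configured asymptote (atmosphere, i.e. 0 gauge, for the exhaust path)
#' with time constant \code{R_exp * C}. This analytic solution serves as
#' an independent oracle for the numerical integrator.
#'
#' @param P_start pressure at the start of expiration, cmH2O.
#' @param R_exp total discharge resistance seen by the compliance,
#'   cmH2O.s/L. For an engine run this is the EC-path resistance plus
#'   twice the airway resistance: once inside the assembled exhaust path
#'   and once in the alveolar pressure equation (see the methods
#'   vignette).
#' @param lung a [lung_parameters()] object (supplies C).
#' @param t time since the start of expiration, s (vectorised).
#' @param asymptote pressure approached as \code{t} grows, cmH2O.
#' @return Pressure in cmH2O.
#' @export
expiration_closed_form <- function(P_start, R_exp, lung, t, asymptote = 0) {
  stopifnot(inherits(lung, "lung_parameters"), all(t >= 0))
  asymptote + (P_start - asymptote) * exp(-t / (R_exp * lung$C))
}

#' Simulate the coupled oscillator-lung-trigger system
#'
#' Integrates the switched linear system with a fixed-step explicit
#' midpoint (RK2) scheme. Volume above the end-expiratory baseline is the
#' only continuous state; alveolar pressure is algebraic. Phase switches
#' are event-located: the threshold crossing inside a step is refined by
#' bisection to within \code{dt / 100}, and the state at the switch
#' instant is recorded twice (pre- and post-switch) so that downstream
#' segmentation sees exact phase boundaries. The engine is fully
#' deterministic: identical configurations give bit-identical records.
#'
#' @param config a [simulation_config()] object.
#' @return A \code{waveform_record}: a data.frame with columns \code{t}
#'   (s), \code{P_alv}, \code{P_pl} (cmH2O), \code{Q} (L/s), \code{V}
#'   (L) and \code{phase}, plus attributes \code{switch_times} (a
#'   data.frame of switch instants and the phase entered) and
#'   \code{config}.
#' @export
#' @examples
#' cfg <- simulation_config(duration = 12)
#' rec <- simulate_ventilator(cfg)
#' range(rec$P_alv)
simulate_ventilator <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lung <- config$lung
  div <- config$diverter
  scr <- config$screws
  trg <- config$trigger
  dt <- config$dt
  duration <- config$duration

  thr <- switching_thresholds(scr, div)
  P_high <- thr[["P_high"]]
  P_low <- thr[["P_low"]]
  R_aw <- lung$R_aw
  C <- lung$C
  peep <- lung$P_peep_base
  Q_insp <- div$eta_insp * div$Q_src
  R_ec <- occlusion_to_resistance(scr$d_EC, div$R_EC_open, div$R_EC_span,
                                  div$delta_EC)
  R_exp <- R_ec + R_aw          # assembled exhaust-path resistance
  R_tot <- R_exp + R_aw         # total discharge resistance seen by C
  tau_trig <- if (!is.null(trg$tau_s)) trg$tau_s else R_aw * C
  A_trig <- trg$amplitude_cmH2O
  sched <- trigger_times(trg, duration)

  if (P_low <= 0) {
    stop("non-oscillation: P_low = ", signif(P_low, 3),
         " cmH2O is not above atmosphere; the exhaust discharge can never",
         " reach it", call. = FALSE)
  }

  # watchdog horizon: 10x an analytic estimate of the cycle period
  T_i_est <- if (Q_insp > 0) {
    max((P_high - (Q_insp * R_aw + peep)) * C / Q_insp, dt)
  } else Inf
  T_e_est <- R_tot * C * log(max(P_high / P_low, 1.001))
  watchdog <- 10 * (T_i_est + T_e_est)

  # pleural pressure of the active effort (0 when none)
  pl_at <- function(t, eff) {
    if (is.na(eff) || t <= eff) 0 else -A_trig * (1 - exp(-(t - eff) / tau_trig))
  }
  # alveolar pressure given phase (1 = INSPIRATION, 2 = EXPIRATION)
  p_alv_of <- function(ph, V, pl) {
    if (ph == 1L) Q_insp * R_aw + V / C + peep + pl
    else (V / C + peep + pl) * R_exp / R_tot
  }
  q_of <- function(ph, V, pl) {
    if (ph == 1L) Q_insp else -(V / C + peep + pl) / R_tot
  }
  # explicit midpoint step of size h from (t0, V0)
  rk2 <- function(ph, t0, V0, h, eff) {
    if (ph == 1L) return(V0 + h * Q_insp)
    f1 <- q_of(ph, V0, pl_at(t0, eff))
    f2 <- q_of(ph, V0 + 0.5 * h * f1, pl_at(t0 + 0.5 * h, eff))
    V0 + h * f2
  }

  n_grid <- ceiling(duration / dt) + 1L
  cap <- n_grid + 2L * (ceiling(duration / 1.5) + 10L)
  t_rec <- numeric(cap); P_rec <- numeric(cap); pl_rec <- numeric(cap)
  Q_rec <- numeric(cap); V_rec <- numeric(cap); ph_rec <- integer(cap)
  k <- 0L
  push <- function(tt, ph, V, eff) {
    pl <- pl_at(tt, eff)
    k <<- k + 1L
    t_rec[k] <<- tt; V_rec[k] <<- V; pl_rec[k] <<- pl
    P_rec[k] <<- p_alv_of(ph, V, pl); Q_rec[k] <<- q_of(ph, V, pl)
    ph_rec[k] <<- ph
  }

  phase <- 1L                    # start charging an empty lung
  V <- 0; t <- 0
  eff <- NA_real_                # start time of the active effort
  sched_i <- 1L
  t_last_switch <- 0
  sw_t <- numeric(0); sw_ph <- integer(0)
  push(t, phase, V, eff)
  grid_i <- 1L                   # index of last emitted grid point

  while (t < duration - 1e-12) {
    # trigger bookkeeping at the current time
    while (sched_i <= length(sched) && sched[sched_i] <= t + 1e-12) {
      if (phase == 2L && is.na(eff)) eff <- sched[sched_i]
      sched_i <- sched_i + 1L    # landed in inspiration: skipped
    }
    t_next_grid <- min(grid_i * dt, duration)
    h <- t_next_grid - t
    # split the step at an upcoming effort start so it is hit exactly
    if (phase == 2L && is.na(eff) && sched_i <= length(sched) &&
        sched[sched_i] < t + h - 1e-12) {
      h <- sched[sched_i] - t
      t_next_grid <- t + h
    }
    V_new <- rk2(phase, t, V, h, eff)
    P_new <- p_alv_of(phase, V_new, pl_at(t + h, eff))
    crossed <- (phase == 1L && P_new >= P_high) ||
      (phase == 2L && P_new <= P_low)
    if (crossed) {
      # bisection on the sub-step size to dt/100
      lo <- 0; hi <- h
      while (hi - lo > dt / 100) {
        mid <- 0.5 * (lo + hi)
        Vm <- rk2(phase, t, V, mid, eff)
        Pm <- p_alv_of(phase, Vm, pl_at(t + mid, eff))
        if ((phase == 1L && Pm >= P_high) || (phase == 2L && Pm <= P_low)) {
          hi <- mid
        } else lo <- mid
      }
      h_sw <- hi
      V <- rk2(phase, t, V, h_sw, eff)
      t <- t + h_sw
      push(t, phase, V, eff)               # pre-switch state
      phase <- if (phase == 1L) 2L else 1L
      if (phase == 1L) eff <- NA_real_     # effort ends with expiration
      push(t, phase, V, eff)               # post-switch state
      sw_t <- c(sw_t, t); sw_ph <- c(sw_ph, phase)
      t_last_switch <- t
      next
    }
    V <- V_new
    t <- t_next_grid
    push(t, phase, V, eff)
    if (abs(t - grid_i * dt) < 1e-12) grid_i <- grid_i + 1L
    if (t - t_last_switch > watchdog) {
      stop(non_oscillation_message(phase, P_rec[k], P_high, P_low),
           call. = FALSE)
    }
  }

  if (length(sw_t) < 2L) {
    stop(non_oscillation_message(phase, P_rec[k], P_high, P_low),
         call. = FALSE)
  }

  phases <- c("INSPIRATION", "EXPIRATION")
  rec <- data.frame(t = t_rec[seq_len(k)], P_alv = P_rec[seq_len(k)],
                    P_pl = pl_rec[seq_len(k)], Q = Q_rec[seq_len(k)],
                    V = V_rec[seq_len(k)],
                    phase = phases[ph_rec[seq_len(k)]],
                    stringsAsFactors = FALSE)
  attr(rec, "switch_times") <- data.frame(time = sw_t,
                                          new_phase = phases[sw_ph],
                                          stringsAsFactors = FALSE)
  attr(rec, "config") <- config
  attr(rec, "thresholds") <- thr
  class(rec) <- c("waveform_record", "data.frame")
  rec
}

non_oscillation_message <- function(phase, P_now, P_high, P_low) {
  if (phase == 1L) {
    sprintf(paste0(
      "non-oscillation: no INSPIRATION -> EXPIRATION switch; alveolar ",
      "pressure %.3g cmH2O cannot reach P_high = %.3g cmH2O ",
      "(inspiratory flow eta_insp * Q_src may be zero or too small)"),
      P_now, P_high)
  } else {
    sprintf(paste0(
      "non-oscillation: no EXPIRATION -> INSPIRATION switch; alveolar ",
      "pressure %.3g cmH2O does not fall to P_low = %.3g cmH2O ",
      "(exhaust resistance may be too large for the horizon)"),
      P_now, P_low)
  }
}

#' @export
print.waveform_record <- function(x, ...) {
  sw <- attr(x, "switch_times")
  cat(sprintf("waveform_record: %d samples over %.3g s, %d phase switches\n",
              nrow(x), max(x$t), nrow(sw)))
  cat(sprintf("  P_alv range [%.3f, %.3f] cmH2O\n",
              min(x$P_alv), max(x$P_alv)))
  invisible(x)
}

#' Plot a simulated or synthetic waveform
#'
#' Base-graphics pressure and flow traces, the in-silico counterpart of a
#' ventilator screen.
#'
#' @param x a \code{waveform_record}.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.waveform_record <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$P_alv, type = "l", xlab = "time (s)",
                 ylab = "P_alv (cmH2O)", ...)
  if (!all(is.na(x$Q))) {
    graphics::plot(x$t, x$Q, type = "l", xlab = "time (s)",
                   ylab = "flow (L/s)", ...)
  }
  invisible(x)
}
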