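#' Specification of a synthetic respiratory waveform
#'
#' Parameters of the analytic pressure waveform used to test the
#' analytics independently of the simulator: per cycle, an exponential
#' rise from PEEP that reaches PIP at exactly \code{T_i}, then an
#' exponential decay that reaches PEEP at exactly \code{T_e}, with
#' optional additive Gaussian noise. The default 17/11 cmH2O levels
#' mirror the pressure band of the hardware bench tests.
#'
#' @param PIP peak pressure, cmH2O.
#' @param PEEP end-expiratory pressure, cmH2O; must be below \code{PIP}.
#' @param T_i,T_e inspiratory and expiratory durations, s.
#' @param n_cycles number of breath cycles.
#' @param rise_tau,decay_tau shape time constants of the two exponential
#'   segments, s.
#' @param noise_sd SD of additive Gaussian noise, cmH2O (0 = clean).
#' @param seed integer seed for the noise; the only random element in
#'   the package.
#' @param dt sample spacing, s.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(PIP = 17, PEEP = 11, T_i = 1, T_e = 3,
                         n_cycles = 10, rise_tau = 0.3, decay_tau = 0.8,
                         noise_sd = 0, seed = 1L, dt = 0.01) {
  check_number(PIP, "PIP"); check_number(PEEP, "PEEP")
  if (PIP <= PEEP) stop("PIP must exceed PEEP", call. = FALSE)
  check_number(T_i, "T_i", lower = 0, strict_lower = TRUE)
  check_number(T_e, "T_e", lower = 0, strict_lower = TRUE)
  check_number(n_cycles, "n_cycles", lower = 1)
  check_number(rise_tau, "rise_tau", lower = 0, strict_lower = TRUE)
  check_number(decay_tau, "decay_tau", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(PIP = PIP, PEEP = PEEP, T_i = T_i, T_e = T_e,
                 n_cycles = as.integer(n_cycles), rise_tau = rise_tau,
                 decay_tau = decay_tau, noise_sd = noise_sd,
                 seed = as.integer(seed), dt = dt),
            class = "fixture_spec")
}

#' Generate a synthetic respiratory waveform
#'
#' Builds the analytic waveform described by a [fixture_spec()]. The
#' rise asymptote is placed so the pressure passes through PIP at
#' exactly \code{T_i}, and the decay asymptote so it returns to PEEP at
#' exactly \code{T_i + T_e}; with zero noise the recovered indices are
#' therefore exact by construction. Noise is generated from the spec's
#' seed without disturbing the caller's RNG state, so two calls with the
#' same spec are identical.
#'
#' @param spec a [fixture_spec()] object.
#' @return A \code{waveform_record} with pressure and phase labels
#'   (\code{Q} and \code{V} are NA: the fixture is a pressure trace).
#' @export
#' @examples
#' rec <- make_synthetic_waveform(fixture_spec(n_cycles = 3))
#' range(rec$P_alv)
make_synthetic_waveform <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  period <- spec$T_i + spec$T_e
  q_r <- exp(-spec$T_i / spec$rise_tau)
  asym_r <- spec$PEEP + (spec$PIP - spec$PEEP) / (1 - q_r)
  q_d <- exp(-spec$T_e / spec$decay_tau)
  asym_d <- (spec$PEEP - spec$PIP * q_d) / (1 - q_d)
  # one cycle, sampled so that both phase boundaries fall exactly on a
  # sample and, as in the simulator, the switch instant appears twice
  # (end of one phase, start of the next)
  t_rise <- seq(0, spec$T_i, by = spec$dt)
  if (t_rise[length(t_rise)] < spec$T_i) t_rise <- c(t_rise, spec$T_i)
  t_decay <- seq(spec$T_i, period, by = spec$dt)
  if (t_decay[length(t_decay)] < period) t_decay <- c(t_decay, period)
  p_rise <- asym_r - (asym_r - spec$PEEP) * exp(-t_rise / spec$rise_tau)
  p_decay <- asym_d + (spec$PIP - asym_d) *
    exp(-(t_decay - spec$T_i) / spec$decay_tau)
  tc <- c(t_rise, t_decay)
  pc <- c(p_rise, p_decay)
  phc <- rep(c("INSPIRATION", "EXPIRATION"),
             c(length(t_rise), length(t_decay)))
  off <- rep((seq_len(spec$n_cycles) - 1) * period, each = length(tc))
  tt <- off + rep(tc, spec$n_cycles)
  p <- rep(pc, spec$n_cycles)
  phase <- rep(phc, spec$n_cycles)
  if (spec$noise_sd > 0) {
    p <- p + local_rnorm(spec$seed, length(p), sd = spec$noise_sd)
  }
  rec <- data.frame(t = tt, P_alv = p, P_pl = 0, Q = NA_real_,
                    V = NA_real_, phase = phase, stringsAsFactors = FALSE)
  k <- seq_len(spec$n_cycles)
  sw <- data.frame(
    time = sort(c((k - 1) * period + spec$T_i, k[-length(k)] * period)),
    new_phase = rep(c("EXPIRATION", "INSPIRATION"),
                    length.out = 2L * spec$n_cycles - 1L),
    stringsAsFactors = FALSE)
  attr(rec, "switch_times") <- sw
  attr(rec, "config") <- spec
  class(rec) <- c("waveform_record", "data.frame")
  rec
}

# draw Gaussian noise from a private RNG stream, restoring the caller's
local_rnorm <- function(seed, n, sd = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}
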