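#' Patient inspiratory-effort (trigger) schedule
#'
#' Models the diaphragmatic effort a spontaneously triggering patient
#' exerts during expiration: a forced step of pleural pressure with
#' first-order dynamics,
#' \deqn{P_{pl}(t) = -A (1 - e^{-(t - t_0)/\tau}),}
#' active from the effort start \eqn{t_0} until the diverter answers with
#' an inspiration, at which point the effort resets to zero. Efforts are
#' scheduled either at a fixed interval (the bench protocol: one
#' patient-initiated breath every 4 s) or at explicit times; a scheduled
#' effort landing during INSPIRATION is skipped, not queued, since only
#' triggering during expiration is characterized.
#'
#' @param enabled logical; when FALSE the patient is passive.
#' @param interval_s effort interval, s (ignored when \code{times_s} is
#'   given).
#' @param times_s optional strictly increasing vector of explicit effort
#'   start times, s.
#' @param amplitude_cmH2O effort magnitude A, cmH2O, applied as a
#'   negative pleural pressure. The in-silico characterization uses 3
#'   cmH2O; \code{profile = "bench"} selects the 5.5 cmH2O setting used
#'   with the hardware lung simulator.
#' @param tau_s first-order time constant, s. Default NULL: the engine
#'   fills in the active lung's \code{R_aw * C} at simulation start.
#' @param profile convenience selector: \code{"insilico"} (A = 3) or
#'   \code{"bench"} (A = 5.5). Ignored when \code{amplitude_cmH2O} is
#'   supplied explicitly.
#' @return An object of class \code{trigger_schedule}.
#' @export
#' @examples
#' trigger_schedule(enabled = TRUE, interval_s = 4)
trigger_schedule <- function(enabled = FALSE, interval_s = 4,
                             times_s = NULL, amplitude_cmH2O = NULL,
                             tau_s = NULL,
                             profile = c("insilico", "bench")) {
  profile <- match.arg(profile)
  if (is.null(amplitude_cmH2O)) {
    amplitude_cmH2O <- switch(profile, insilico = 3, bench = 5.5)
  }
  check_number(amplitude_cmH2O, "amplitude_cmH2O", lower = 0)
  if (!is.null(times_s)) {
    if (length(times_s) < 1L || any(!is.finite(times_s)) ||
        is.unsorted(times_s, strictly = TRUE) || any(times_s < 0)) {
      stop("`times_s` must be a strictly increasing vector of non-negative times",
           call. = FALSE)
    }
  } else {
    check_number(interval_s, "interval_s", lower = 0, strict_lower = TRUE)
  }
  if (!is.null(tau_s)) check_number(tau_s, "tau_s", lower = 0, strict_lower = TRUE)
  structure(
    list(enabled = isTRUE(enabled), interval_s = interval_s,
         times_s = times_s, amplitude_cmH2O = amplitude_cmH2O,
         tau_s = tau_s),
    class = "trigger_schedule")
}

#' Pleural pressure of an active effort
#'
#' Evaluates the first-order effort step. Returns 0 when no effort is
#' active (\code{effort_start} is NULL/NA or \code{t < effort_start}).
#'
#' @param t time, s (vectorised).
#' @param effort_start start time of the active effort, s, or NULL/NA.
#' @param schedule a [trigger_schedule()] object.
#' @param tau_s time constant override, s; required when the schedule was
#'   built with \code{tau_s = NULL} and no lung context is available.
#' @return Pleural pressure in cmH2O (non-positive).
#' @export
#' @examples
#' sch <- trigger_schedule(enabled = TRUE, tau_s = 0.09)
#' pleural_pressure(c(0, 0.09, 10), effort_start = 0, schedule = sch)
pleural_pressure <- function(t, effort_start, schedule, tau_s = NULL) {
  stopifnot(inherits(schedule, "trigger_schedule"))
  tau <- if (!is.null(tau_s)) tau_s else schedule$tau_s
  if (is.null(tau)) {
    stop("no time constant available: supply `tau_s` or build the schedule with one",
         call. = FALSE)
  }
  if (is.null(effort_start) || length(effort_start) == 0L ||
      is.na(effort_start)) {
    return(rep(0, length(t)))
  }
  A <- schedule$amplitude_cmH2O
  ifelse(t < effort_start, 0, -A * (1 - exp(-(t - effort_start) / tau)))
}

# internal: effort start times over a horizon
trigger_times <- function(schedule, duration) {
  if (!schedule$enabled) return(numeric(0))
  if (!is.null(schedule$times_s)) {
    schedule$times_s[schedule$times_s <= duration]
  } else {
    seq(schedule$interval_s, duration, by = schedule$interval_s)
  }
}
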