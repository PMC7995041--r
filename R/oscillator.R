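#' Vortex-chamber geometry
#'
#' Dimensions of the oscillator's vortex chamber, used by the
#' characteristic-time design calculator. Defaults are the as-built
#' device: 88 mm diameter, 2.4 mm height.
#'
#' @param D chamber diameter, m.
#' @param h chamber height, m.
#' @return An object of class \code{geometry_parameters}.
#' @export
geometry_parameters <- function(D = 0.088, h = 0.0024) {
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  structure(list(D = D, h = h), class = "geometry_parameters")
}

#' Calibration-screw settings
#'
#' The physical device is tuned with three set-screws that occlude the
#' exhaust channel (EC), feedback channel (FC) and side channel (SC).
#' Each is expressed as an occlusion fraction in [0, 1]: 0 = fully open,
#' 1 = fully closed. The EC screw sets the expiratory decay rate (hence
#' the oscillation period); FC and SC move the switching thresholds
#' (hence PIP and PEEP). The default 0.5 midpoints are the calibrated
#' reference configuration.
#'
#' @param d_EC,d_FC,d_SC occlusion fractions in [0, 1].
#' @return An object of class \code{screw_settings}.
#' @export
screw_settings <- function(d_EC = 0.5, d_FC = 0.5, d_SC = 0.5) {
  for (nm in c("d_EC", "d_FC", "d_SC")) {
    check_number(get(nm), nm, lower = 0, upper = 1)
  }
  structure(list(d_EC = d_EC, d_FC = d_FC, d_SC = d_SC),
            class = "screw_settings")
}

#' Screw occlusion to flow resistance
#'
#' Maps an occlusion fraction to a pneumatic resistance:
#' \code{R_open + R_span * d / (1 - d + delta)}. The law is strictly
#' increasing in \code{d} and, thanks to the regularizer \code{delta},
#' finite at full closure. \code{delta} controls the taper of the screw:
#' small values concentrate the resistance change near full closure,
#' larger values spread it nearly linearly across the travel.
#'
#' @param d occlusion fraction in [0, 1].
#' @param R_open resistance with the screw fully open, cmH2O.s/L.
#' @param R_span resistance scale of the occlusion term, cmH2O.s/L.
#' @param delta positive regularizer (dimensionless).
#' @return Resistance in cmH2O.s/L. Vectorised over \code{d}.
#' @export
#' @examples
#' occlusion_to_resistance(0.5, R_open = 10, R_span = 10, delta = 0.01)
occlusion_to_resistance <- function(d, R_open, R_span, delta = 0.01) {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("occlusion fraction `d` must lie in [0, 1]", call. = FALSE)
  }
  check_number(R_open, "R_open", lower = 0, strict_lower = TRUE)
  check_number(R_span, "R_span", lower = 0, strict_lower = TRUE)
  check_number(delta, "delta", lower = 0, strict_lower = TRUE)
  R_open + R_span * d / (1 - d + delta)
}

#' Reduced-order diverter configuration
#'
#' Constants of the two-phase hysteretic diverter that stands in for the
#' Coanda-effect jet switching of the physical oscillator. The jet's two
#' stable attachment states become the INSPIRATION / EXPIRATION phases of
#' a hysteresis element that trips at an upper alveolar-pressure
#' threshold \code{P_high} (end of inspiration) and a lower threshold
#' \code{P_low} (end of expiration). Both thresholds are affine in the FC
#' and SC screw occlusions, with signs chosen so that closing SC raises
#' and closing FC lowers them.
#'
#' Defaults are the frozen output of the package's one-off calibration
#' (see the methods vignette): with all screws at midpoint the thresholds
#' are (20, 8) cmH2O, inspiratory time is about 0.92 s for the healthy
#' lung, and sweeping the EC screw across its travel spans steady-state
#' periods of 3 to 5 s.
#'
#' @param Q_src source volumetric flow, L/s (default 0.5 L/s = 30 L/min).
#'   A zero value is accepted so that an unpowered system can be
#'   simulated; it cannot oscillate and the engine will say so.
#' @param eta_insp fraction of source flow delivered to the lung during
#'   inspiration, in (0, 1]; the remainder vents through the side channel.
#' @param R_EC_open,R_EC_span exhaust-path resistance law constants,
#'   cmH2O.s/L (see [occlusion_to_resistance()]).
#' @param delta_EC taper regularizer of the EC screw's occlusion law.
#' @param R_SC_open,R_SC_span side-channel leak resistance law constants,
#'   cmH2O.s/L. The reduced model folds the SC leak's steady effect into
#'   \code{eta_insp} and the threshold maps; these constants document the
#'   leak path and are validated but do not enter the phase dynamics.
#' @param P_high_base,k_SC,k_FC upper-threshold map constants, cmH2O:
#'   \code{P_high = P_high_base + k_SC * d_SC - k_FC * d_FC}.
#' @param P_low_base,m_SC,m_FC lower-threshold map constants, cmH2O:
#'   \code{P_low = P_low_base + m_SC * d_SC - m_FC * d_FC}.
#' @return An object of class \code{diverter_config}.
#' @export
diverter_config <- function(Q_src = 0.5,
                            eta_insp = 0.6945,
                            R_EC_open = 77.86,
                            R_EC_span = 57.57,
                            delta_EC = 0.75,
                            R_SC_open = 25,
                            R_SC_span = 25,
                            P_high_base = 20, k_SC = 8, k_FC = 8,
                            P_low_base = 8, m_SC = 4, m_FC = 4) {
  check_number(Q_src, "Q_src", lower = 0)
  check_number(eta_insp, "eta_insp", lower = 0, upper = 1,
               strict_lower = TRUE)
  for (nm in c("R_EC_open", "R_EC_span", "R_SC_open", "R_SC_span",
               "delta_EC")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  for (nm in c("P_high_base", "k_SC", "k_FC", "P_low_base", "m_SC", "m_FC")) {
    check_number(get(nm), nm)
  }
  cfg <- structure(
    list(Q_src = Q_src, eta_insp = eta_insp,
         R_EC_open = R_EC_open, R_EC_span = R_EC_span, delta_EC = delta_EC,
         R_SC_open = R_SC_open, R_SC_span = R_SC_span,
         P_high_base = P_high_base, k_SC = k_SC, k_FC = k_FC,
         P_low_base = P_low_base, m_SC = m_SC, m_FC = m_FC),
    class = "diverter_config")
  # P_high > P_low must hold over the whole admissible screw box, else
  # some settings would deadlock the oscillator; check the worst corner.
  gap_min <- (P_high_base - P_low_base) -
    max(0, k_FC - m_FC) - max(0, m_SC - k_SC)
  if (gap_min <= 0) {
    stop("diverter configuration admits P_high <= P_low for some screw ",
         "settings (no oscillation possible); adjust the threshold maps",
         call. = FALSE)
  }
  cfg
}

#' Switching thresholds implied by the screw settings
#'
#' Evaluates the affine threshold maps of the diverter: closing the SC
#' screw raises PIP (and PEEP), closing the FC screw lowers them, the
#' directions observed on the physical device.
#'
#' @param settings a [screw_settings()] object.
#' @param config a [diverter_config()] object.
#' @return Named numeric vector \code{c(P_high = , P_low = )} in cmH2O.
#' @export
#' @examples
#' switching_thresholds(screw_settings(), diverter_config())
switching_thresholds <- function(settings, config) {
  stopifnot(inherits(settings, "screw_settings"),
            inherits(config, "diverter_config"))
  P_high <- config$P_high_base + config$k_SC * settings$d_SC -
    config$k_FC * settings$d_FC
  P_low <- config$P_low_base + config$m_SC * settings$d_SC -
    config$m_FC * settings$d_FC
  if (P_high <= P_low) {
    stop(sprintf(
      "derived thresholds P_high = %.3g <= P_low = %.3g: no oscillation possible",
      P_high, P_low), call. = FALSE)
  }
  c(P_high = P_high, P_low = P_low)
}

#' Lung flow delivered by the diverter
#'
#' During INSPIRATION the source jet attaches to the vortex-chamber side
#' and the lung is charged at constant flow \code{eta_insp * Q_src} (the
#' rest of the source vents through the side channel). During EXPIRATION
#' the jet attaches to the exhaust side and the lung discharges through
#' the exhaust path: \code{Q = -P_alv / R_exp}, with \code{R_exp} the
#' total discharge resistance (EC screw law plus the airway contribution,
#' assembled by the engine). Pressures are gauge; flow is positive into
#' the lung.
#'
#' @param phase \code{"INSPIRATION"} or \code{"EXPIRATION"}.
#' @param P_alv alveolar pressure, cmH2O.
#' @param settings a [screw_settings()] object.
#' @param config a [diverter_config()] object.
#' @param R_exp total expiratory discharge resistance, cmH2O.s/L. When
#'   NULL, the EC occlusion law alone is used (the engine adds the airway
#'   term).
#' @return Flow in L/s, positive into the lung.
#' @export
lung_flow <- function(phase, P_alv, settings, config, R_exp = NULL) {
  phase <- match.arg(phase, c("INSPIRATION", "EXPIRATION"))
  stopifnot(is.finite(P_alv))
  if (phase == "INSPIRATION") {
    return(config$eta_insp * config$Q_src)
  }
  if (is.null(R_exp)) {
    R_exp <- occlusion_to_resistance(settings$d_EC, config$R_EC_open,
                                     config$R_EC_span, config$delta_EC)
  }
  -P_alv / R_exp
}

#' Hysteretic phase transition rule
#'
#' The diverter leaves INSPIRATION when alveolar pressure reaches the
#' upper threshold and leaves EXPIRATION when it falls to the lower
#' threshold; between the thresholds the phase is held (hysteresis), so
#' the rule is idempotent inside the band and the closed loop cannot
#' chatter.
#'
#' @param phase current phase, \code{"INSPIRATION"} or \code{"EXPIRATION"}.
#' @param P_alv alveolar pressure, cmH2O.
#' @param P_high,P_low switching thresholds, cmH2O, with
#'   \code{P_high > P_low}.
#' @return The next phase label.
#' @export
#' @examples
#' next_phase("INSPIRATION", 20, P_high = 20, P_low = 8)
next_phase <- function(phase, P_alv, P_high, P_low) {
  phase <- match.arg(phase, c("INSPIRATION", "EXPIRATION"))
  if (P_high <= P_low) stop("P_high must exceed P_low", call. = FALSE)
  if (phase == "INSPIRATION" && P_alv >= P_high) return("EXPIRATION")
  if (phase == "EXPIRATION" && P_alv <= P_low) return("INSPIRATION")
  phase
}

#' Characteristic fill time of the vortex chamber
#'
#' Design-stage estimate of the oscillator's switching timescale: the
#' time to fill the vortex chamber (a cylinder of diameter \code{D} and
#' height \code{h}) at a given mass flow,
#' \deqn{\Delta t_c = \pi D^2 h / (4 v \dot m),}
#' with \eqn{v} the fluid's specific volume. Since \eqn{v \dot m} is the
#' volumetric flow, the latter may be supplied directly.
#'
#' @param geom a [geometry_parameters()] object.
#' @param v specific volume of the fluid, m^3/kg.
#' @param mdot mass flow rate, kg/s.
#' @param vol_flow volumetric flow, m^3/s; shortcut for \code{v * mdot}.
#'   Supply either \code{vol_flow} or both \code{v} and \code{mdot}.
#' @return Characteristic time in seconds.
#' @export
#' @examples
#' # as-built chamber at 30 L/min
#' characteristic_time(geometry_parameters(), vol_flow = 30 / 60 / 1000)
characteristic_time <- function(geom, v = NULL, mdot = NULL,
                                vol_flow = NULL) {
  stopifnot(inherits(geom, "geometry_parameters"))
  if (is.null(vol_flow)) {
    if (is.null(v) || is.null(mdot)) {
      stop("supply either `vol_flow` or both `v` and `mdot`", call. = FALSE)
    }
    check_number(v, "v", lower = 0, strict_lower = TRUE)
    check_number(mdot, "mdot", lower = 0, strict_lower = TRUE)
    vol_flow <- v * mdot
  } else {
    check_number(vol_flow, "vol_flow", lower = 0, strict_lower = TRUE)
  }
  pi * geom$D^2 * geom$h / 4 / vol_flow
}
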