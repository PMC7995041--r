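#' Single-compartment Windkessel lung parameters
#'
#' The lung is described by a first-order resistance-compliance (Windkessel)
#' model: an airway resistance \code{R_aw} in series with a compliant
#' compartment \code{C}, inflated above a baseline end-expiratory pressure.
#' Alveolar pressure then follows the equation of motion of the respiratory
#' system,
#' \deqn{P_{alv}(t) = Q R_{aw} + V/C + P_{peep} + P_{pl},}
#' where \eqn{Q} is flow into the lung, \eqn{V = \int Q\,dt} the volume
#' accumulated above the end-expiratory baseline, and \eqn{P_{pl}} the
#' pleural (patient-effort) pressure.
#'
#' @param R_aw airway resistance, cmH2O.s/L. Must be non-negative.
#' @param C lung compliance, L/cmH2O. Must be positive. Values below
#'   0.005 L/cmH2O (5 mL/cmH2O) are accepted with a warning: they sit at
#'   the extreme stiff end of the clinically plausible range.
#' @param P_peep_base baseline end-expiratory pressure, cmH2O (gauge).
#' @param label free-text condition name.
#' @return An object of class \code{lung_parameters}.
#' @seealso [lung_preset()] for the named compliance presets,
#'   [alveolar_pressure()] for the pressure equation.
#' @export
#' @examples
#' lung_parameters(R_aw = 3, C = 0.030, P_peep_base = 8, label = "healthy")
lung_parameters <- function(R_aw = 3, C = 0.030, P_peep_base = 8,
                            label = "custom") {
  check_number(R_aw, "R_aw", lower = 0)
  check_number(C, "C", lower = 0, strict_lower = TRUE)
  check_number(P_peep_base, "P_peep_base", lower = 0)
  if (C < 0.005) {
    warning(sprintf(
      "compliance C = %g L/cmH2O (%g mL/cmH2O) is below 5 mL/cmH2O; ",
      C, l_per_cmh2o_to_ml(C)),
      "this is at the extreme stiff end of the plausible range",
      call. = FALSE)
  }
  structure(
    list(R_aw = R_aw, C = C, P_peep_base = P_peep_base,
         label = as.character(label)[1L]),
    class = "lung_parameters")
}

#' @export
print.lung_parameters <- function(x, ...) {
  cat(sprintf("Windkessel lung '%s': R_aw = %g cmH2O.s/L, C = %g mL/cmH2O, PEEP base = %g cmH2O\n",
              x$label, x$R_aw, l_per_cmh2o_to_ml(x$C), x$P_peep_base))
  invisible(x)
}

#' Alveolar pressure of the Windkessel lung
#'
#' Evaluates the equation of motion of the respiratory system:
#' \code{Q * R_aw + V / C + P_peep_base + P_pl}. All pressures are gauge
#' (atmosphere = 0 cmH2O).
#'
#' @param params a [lung_parameters()] object.
#' @param Q instantaneous flow into the lung, L/s.
#' @param V volume above the end-expiratory baseline, L.
#' @param P_pl pleural (effort) pressure, cmH2O; 0 when the patient is
#'   passive.
#' @return Alveolar pressure in cmH2O. Vectorised over \code{Q}, \code{V}
#'   and \code{P_pl}.
#' @export
#' @examples
#' hl <- lung_preset("healthy")
#' alveolar_pressure(hl, Q = 0.5, V = 0.36, P_pl = 0)
alveolar_pressure <- function(params, Q, V, P_pl = 0) {
  stopifnot(inherits(params, "lung_parameters"))
  if (params$C <= 0) stop("invalid lung parameters: C must be > 0", call. = FALSE)
  Q * params$R_aw + V / params$C + params$P_peep_base + P_pl
}

#' Named lung-condition presets
#'
#' Three canonical compliance settings spanning stiff to floppy lungs:
#' pulmonary fibrosis (10 mL/cmH2O), healthy (30 mL/cmH2O) and emphysema
#' (50 mL/cmH2O), all with airway resistance 3 cmH2O.s/L and an 8 cmH2O
#' end-expiratory baseline.
#'
#' @param condition one of \code{"fibrosis"}, \code{"healthy"},
#'   \code{"emphysema"}.
#' @param P_peep_base baseline end-expiratory pressure, cmH2O.
#' @return A [lung_parameters()] object.
#' @export
#' @examples
#' lung_preset("fibrosis")
lung_preset <- function(condition = c("healthy", "fibrosis", "emphysema"),
                        P_peep_base = 8) {
  presets <- c(fibrosis = 0.010, healthy = 0.030, emphysema = 0.050)
  if (length(condition) == 1L && !condition %in% names(presets)) {
    stop(sprintf("unknown lung condition '%s'; valid names: %s",
                 condition, paste(names(presets), collapse = ", ")),
         call. = FALSE)
  }
  condition <- match.arg(condition)
  lung_parameters(R_aw = 3, C = presets[[condition]],
                  P_peep_base = P_peep_base, label = condition)
}

#' Table of available lung presets
#'
#' @return data.frame with one row per preset (name, R_aw, compliance in
#'   both unit conventions).
#' @export
lung_preset_table <- function() {
  conditions <- c("fibrosis", "healthy", "emphysema")
  C <- vapply(conditions, function(cc) lung_preset(cc)$C, numeric(1))
  data.frame(condition = conditions,
             R_aw_cmH2O_s_L = 3,
             C_L_cmH2O = unname(C),
             C_mL_cmH2O = unname(l_per_cmh2o_to_ml(C)),
             stringsAsFactors = FALSE)
}
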