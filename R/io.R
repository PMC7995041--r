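#' Export a waveform as delimited text
#'
#' Writes the record as a comma-separated file with fixed column names
#' \code{t_s, P_alv_cmH2O, P_pl_cmH2O, Q_Lps, V_L, phase}; times are
#' printed to 6 decimals and pressures, flows and volumes to 4, decimal
#' separator '.'.
#'
#' @param record a \code{waveform_record}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(is.data.frame(record))
  out <- data.frame(
    t_s = sprintf("%.6f", record$t),
    P_alv_cmH2O = sprintf("%.4f", record$P_alv),
    P_pl_cmH2O = sprintf("%.4f", record$P_pl),
    Q_Lps = ifelse(is.na(record$Q), "NA", sprintf("%.4f", record$Q)),
    V_L = ifelse(is.na(record$V), "NA", sprintf("%.4f", record$V)),
    phase = record$phase,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a waveform CSV
#'
#' Reads a file written by [write_waveform_csv()], or a minimal
#' two-column \code{t_s,P_alv_cmH2O} (or \code{t,pressure}) file. Phase
#' switch times are reconstructed from the phase labels when present.
#'
#' @param path file path.
#' @return A \code{waveform_record}.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("waveform file '%s' does not exist", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    NULL
  }
  t <- pick("t_s", "t")
  p <- pick("P_alv_cmH2O", "P_alv", "pressure_cmH2O", "pressure")
  if (is.null(t) || is.null(p)) {
    stop("waveform CSV must contain a time and a pressure column ",
         "(t_s / P_alv_cmH2O)", call. = FALSE)
  }
  rec <- data.frame(
    t = as.numeric(t), P_alv = as.numeric(p),
    P_pl = { x <- pick("P_pl_cmH2O", "P_pl"); if (is.null(x)) 0 else as.numeric(x) },
    Q = { x <- pick("Q_Lps", "Q"); if (is.null(x)) NA_real_ else as.numeric(x) },
    V = { x <- pick("V_L", "V"); if (is.null(x)) NA_real_ else as.numeric(x) },
    phase = { x <- pick("phase"); if (is.null(x)) NA_character_ else as.character(x) },
    stringsAsFactors = FALSE)
  if (!all(is.na(rec$phase))) {
    ch <- which(rec$phase[-1L] != rec$phase[-nrow(rec)]) + 1L
    attr(rec, "switch_times") <- data.frame(
      time = rec$t[ch], new_phase = rec$phase[ch], stringsAsFactors = FALSE)
  }
  class(rec) <- c("waveform_record", "data.frame")
  rec
}

#' Read a simulation configuration from YAML or JSON
#'
#' The configuration file holds up to five named blocks (\code{lung},
#' \code{diverter}, \code{screws}, \code{trigger}, \code{sim}), each
#' optional: omitted fields take the package defaults. User-facing units
#' are the conventional ones (compliance in mL/cmH2O, flow in L/min) and
#' are converted on load. The full schema ships with the package:
#' \code{system.file("extdata", "config_schema.md", package = "oscvent")}.
#'
#' @param path file path (.yaml/.yml/.json).
#' @return A [simulation_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("malformed config: top level must be a mapping",
                          call. = FALSE)
  config_from_list(raw)
}

# build a simulation_config from a plain nested list in user units
config_from_list <- function(raw) {
  known <- c("lung", "diverter", "screws", "trigger", "sim")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("malformed config: unknown block(s) ", paste(bad, collapse = ", "),
         "; valid blocks are ", paste(known, collapse = ", "), call. = FALSE)
  }
  lg <- raw$lung
  lung <- if (is.null(lg)) {
    lung_preset("healthy")
  } else if (!is.null(lg$preset)) {
    lung_preset(lg$preset,
                P_peep_base = lg$peep_cmH2O %||% 8)
  } else {
    lung_parameters(R_aw = lg$R_cmH2O_s_L %||% 3,
                    C = ml_per_cmh2o_to_l(lg$C_mL_cmH2O %||% 30),
                    P_peep_base = lg$peep_cmH2O %||% 8,
                    label = lg$label %||% "custom")
  }
  dv <- raw$diverter %||% list()
  dflt <- diverter_config()
  diverter <- diverter_config(
    Q_src = if (!is.null(dv$flow_L_min)) lpm_to_lps(dv$flow_L_min) else dflt$Q_src,
    eta_insp = dv$eta_insp %||% dflt$eta_insp,
    R_EC_open = dv$R_EC_open %||% dflt$R_EC_open,
    R_EC_span = dv$R_EC_span %||% dflt$R_EC_span,
    delta_EC = dv$delta_EC %||% dflt$delta_EC,
    R_SC_open = dv$R_SC_open %||% dflt$R_SC_open,
    R_SC_span = dv$R_SC_span %||% dflt$R_SC_span,
    P_high_base = dv$P_high_base %||% dflt$P_high_base,
    k_SC = dv$k_SC %||% dflt$k_SC, k_FC = dv$k_FC %||% dflt$k_FC,
    P_low_base = dv$P_low_base %||% dflt$P_low_base,
    m_SC = dv$m_SC %||% dflt$m_SC, m_FC = dv$m_FC %||% dflt$m_FC)
  sc <- raw$screws %||% list()
  screws <- screw_settings(d_EC = sc$EC %||% 0.5, d_FC = sc$FC %||% 0.5,
                           d_SC = sc$SC %||% 0.5)
  tg <- raw$trigger %||% list()
  trigger <- trigger_schedule(
    enabled = tg$enabled %||% FALSE,
    interval_s = tg$interval_s %||% 4,
    times_s = tg$times_s,
    amplitude_cmH2O = tg$amplitude_cmH2O,
    tau_s = tg$tau_s,
    profile = tg$profile %||% "insilico")
  sm <- raw$sim %||% list()
  simulation_config(lung = lung, diverter = diverter, screws = screws,
                    trigger = trigger,
                    dt = sm$dt_s %||% 0.001,
                    duration = sm$duration_s %||% 60,
                    transient_discard = sm$transient_discard %||% 2)
}

#' Serialize a simulation configuration to YAML
#'
#' Inverse of [read_config()]: the emitted file uses the same user-facing
#' units, so load / save round-trips are value-identical.
#'
#' @param config a [simulation_config()] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  lg <- config$lung; dv <- config$diverter; tg <- config$trigger
  out <- list(
    lung = list(R_cmH2O_s_L = lg$R_aw,
                C_mL_cmH2O = l_per_cmh2o_to_ml(lg$C),
                peep_cmH2O = lg$P_peep_base, label = lg$label),
    diverter = list(flow_L_min = lps_to_lpm(dv$Q_src),
                    eta_insp = dv$eta_insp,
                    R_EC_open = dv$R_EC_open, R_EC_span = dv$R_EC_span,
                    delta_EC = dv$delta_EC,
                    R_SC_open = dv$R_SC_open, R_SC_span = dv$R_SC_span,
                    P_high_base = dv$P_high_base, k_SC = dv$k_SC,
                    k_FC = dv$k_FC, P_low_base = dv$P_low_base,
                    m_SC = dv$m_SC, m_FC = dv$m_FC),
    screws = list(EC = config$screws$d_EC, FC = config$screws$d_FC,
                  SC = config$screws$d_SC),
    trigger = list(enabled = tg$enabled, interval_s = tg$interval_s,
                   times_s = tg$times_s,
                   amplitude_cmH2O = tg$amplitude_cmH2O, tau_s = tg$tau_s),
    sim = list(dt_s = config$dt, duration_s = config$duration,
               transient_discard = config$transient_discard))
  drop_null <- function(x) {
    if (is.list(x)) lapply(Filter(Negate(is.null), x), drop_null) else x
  }
  yaml::write_yaml(drop_null(out), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
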