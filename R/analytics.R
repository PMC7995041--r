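stop_insufficient <- function(msg) {
  stop(errorCondition(msg,
                      class = c("oscvent_insufficient_data", "error",
                                "condition")))
}

#' Segment a waveform into breath cycles
#'
#' Splits a pressure record into breaths and measures the per-cycle
#' respiratory indices. Two routes are available:
#' \itemize{
#'   \item records carrying phase labels (simulator output, synthetic
#'     fixtures, or a re-imported waveform CSV) are cut exactly at the
#'     EXPIRATION to INSPIRATION transitions;
#'   \item bare pressure traces are cut by threshold-free peak/trough
#'     detection: turning points closer in amplitude than
#'     \code{prominence_frac} of the trace range or closer in time than
#'     \code{min_separation} are discarded as jitter.
#' }
#' PIP is the maximum pressure over the cycle, PEEP the end-expiratory
#' pressure (at the switch into the next inspiration), and tidal volume
#' the integral of inspiratory flow when a flow channel is present.
#' Cycles during which a patient effort was active (negative pleural
#' pressure) are flagged \code{triggered}.
#'
#' @param record a \code{waveform_record}, or any data.frame with columns
#'   \code{t} and \code{P_alv} (a \code{pressure} column is also
#'   accepted).
#' @param min_separation minimum spacing between same-type turning
#'   points, s (trace route only).
#' @param prominence_frac minimum turning-point amplitude as a fraction
#'   of the trace range (trace route only).
#' @return A data.frame of class \code{breath_cycles}, one row per
#'   complete cycle: \code{t_insp_start}, \code{t_exp_start},
#'   \code{t_end}, \code{PIP}, \code{PEEP}, \code{T_i}, \code{T_e},
#'   \code{period}, \code{tidal_volume}, \code{triggered}.
#' @export
segment_breaths <- function(record, min_separation = 0.5,
                            prominence_frac = 0.1) {
  if (!is.data.frame(record)) {
    stop("`record` must be a data.frame-like waveform", call. = FALSE)
  }
  p_col <- if ("P_alv" %in% names(record)) "P_alv" else "pressure"
  if (!p_col %in% names(record) || !"t" %in% names(record)) {
    stop("waveform must have columns `t` and `P_alv` (or `pressure`)",
         call. = FALSE)
  }
  t <- record$t
  p <- record[[p_col]]
  has_phase <- "phase" %in% names(record) && !all(is.na(record$phase))
  if (has_phase) {
    cycles <- segment_by_phase(record, t, p)
  } else {
    cycles <- segment_by_extrema(t, p, min_separation, prominence_frac)
  }
  if (nrow(cycles) < 2L) {
    stop_insufficient(sprintf(
      "insufficient data: %d complete cycle(s) found, need at least 2",
      nrow(cycles)))
  }
  class(cycles) <- c("breath_cycles", "data.frame")
  cycles
}

# segmentation route 1: exact phase labels
segment_by_phase <- function(record, t, p) {
  ph <- record$phase
  # inspiration starts: first sample, plus every EXP -> INSP transition
  trans <- which(ph[-1L] == "INSPIRATION" & ph[-length(ph)] == "EXPIRATION") + 1L
  starts <- if (ph[1L] == "INSPIRATION") c(1L, trans) else trans
  n_cyc <- length(starts) - 1L
  if (n_cyc < 1L) {
    stop_insufficient("insufficient data: fewer than 2 inspiration onsets")
  }
  has_flow <- "Q" %in% names(record) && !all(is.na(record$Q))
  has_pl <- "P_pl" %in% names(record)
  out <- vector("list", n_cyc)
  for (i in seq_len(n_cyc)) {
    i0 <- starts[i]; i1 <- starts[i + 1L]
    idx <- i0:i1
    # switch into expiration inside this cycle
    exp_i <- idx[which(ph[idx] == "EXPIRATION")[1L]]
    if (is.na(exp_i)) next
    t_exp <- t[exp_i]
    # end-expiratory pressure: last EXPIRATION sample of the cycle
    pre_end <- idx[max(which(ph[idx] == "EXPIRATION"))]
    vt <- if (has_flow) {
      q <- pmax(record$Q[idx], 0)
      sum(diff(t[idx]) * (q[-1L] + q[-length(q)]) / 2)
    } else NA_real_
    out[[i]] <- data.frame(
      t_insp_start = t[i0], t_exp_start = t_exp, t_end = t[i1],
      PIP = max(p[idx]), PEEP = p[pre_end],
      T_i = t_exp - t[i0], T_e = t[i1] - t_exp,
      period = t[i1] - t[i0], tidal_volume = vt,
      triggered = if (has_pl) any(record$P_pl[idx] < -1e-9) else FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# segmentation route 2: peak/trough detection on a bare trace
segment_by_extrema <- function(t, p, min_separation, prominence_frac) {
  dt_med <- stats::median(diff(t))
  # light smoothing for turning-point *location* only; indices are then
  # snapped back to the raw trace
  w <- max(3L, 2L * floor(0.05 / dt_med) + 1L)
  ps <- stats::filter(p, rep(1 / w, w), sides = 2)
  ps[is.na(ps)] <- p[is.na(ps)]
  ex <- turning_points(as.numeric(ps), prominence_frac * diff(range(p)),
                       min_sep_n = ceiling(min_separation / dt_med))
  # a record edge only counts as a trough if it sits near the bottom of
  # the band: a trace cut off mid-decay must not close a spurious cycle
  near_bottom <- min(p) + 0.25 * diff(range(p))
  edge <- ex$idx %in% c(1L, length(p)) & ex$kind < 0
  drop <- edge & p[ex$idx] > near_bottom
  ex$idx <- ex$idx[!drop]; ex$kind <- ex$kind[!drop]
  if (length(ex$kind) < 3L) {
    stop_insufficient("insufficient data: fewer than 2 cycles detected in trace")
  }
  # snap each extremum to the raw-trace extreme within half a window
  half <- max(w, ceiling(0.05 / dt_med))
  snap <- function(i, kind) {
    lo <- max(1L, i - half); hi <- min(length(p), i + half)
    j <- if (kind > 0) which.max(p[lo:hi]) else which.min(p[lo:hi])
    lo + j - 1L
  }
  idx <- mapply(snap, ex$idx, ex$kind)
  kind <- ex$kind
  troughs <- idx[kind < 0]
  n_cyc <- length(troughs) - 1L
  if (n_cyc < 1L) {
    stop_insufficient("insufficient data: fewer than 2 cycles detected in trace")
  }
  out <- vector("list", n_cyc)
  for (i in seq_len(n_cyc)) {
    i0 <- troughs[i]; i1 <- troughs[i + 1L]
    seg <- i0:i1
    pk <- seg[which.max(p[seg])]
    out[[i]] <- data.frame(
      t_insp_start = t[i0], t_exp_start = t[pk], t_end = t[i1],
      PIP = p[pk], PEEP = p[i1],
      T_i = t[pk] - t[i0], T_e = t[i1] - t[pk],
      period = t[i1] - t[i0], tidal_volume = NA_real_,
      triggered = FALSE)
  }
  do.call(rbind, out)
}

# alternating max/min sequence with amplitude and spacing filters;
# endpoints count as candidate troughs so a record starting at
# end-expiration is not silently shortened by one cycle
turning_points <- function(x, min_amp, min_sep_n) {
  n <- length(x)
  dx <- diff(x)
  sgn <- sign(dx)
  sgn[sgn == 0] <- NA
  sgn <- fill_forward(sgn)
  chg <- which(diff(sgn) != 0) + 1L
  kind <- ifelse(sgn[chg - 1L] > 0, 1L, -1L)   # 1 = max, -1 = min
  idx <- chg
  # boundary candidates
  idx <- c(1L, idx, n)
  kind <- c(if (length(sgn) && !is.na(sgn[1L]) && sgn[1L] > 0) -1L else 1L,
            kind,
            if (length(sgn) && !is.na(sgn[n - 1L]) && sgn[n - 1L] > 0) 1L else -1L)
  # iteratively delete the adjacent pair with the smallest amplitude
  # difference until all alternations are significant
  repeat {
    if (length(idx) < 2L) break
    amp <- abs(diff(x[idx]))
    j <- which.min(amp)
    if (amp[j] >= min_amp) break
    keep <- setdiff(seq_along(idx), c(j, j + 1L))
    # deleting an interior pair keeps the sequence alternating
    if (j == 1L) keep <- c(1L, setdiff(keep, 1L))  # keep boundary, drop partner
    idx <- idx[keep]; kind <- kind[keep]
    ck <- collapse_runs(x, idx, kind)
    idx <- ck$idx; kind <- ck$kind
  }
  ck <- collapse_runs(x, idx, kind)
  idx <- ck$idx; kind <- ck$kind
  # enforce temporal separation between same-type extrema
  ok <- rep(TRUE, length(idx))
  for (s in c(-1L, 1L)) {
    pos <- which(kind == s)
    if (length(pos) < 2L) next
    last <- pos[1L]
    for (q in pos[-1L]) {
      if (idx[q] - idx[last] < min_sep_n) {
        better <- if (s > 0) x[idx[q]] > x[idx[last]] else x[idx[q]] < x[idx[last]]
        if (better) { ok[last] <- FALSE; last <- q } else ok[q] <- FALSE
      } else last <- q
    }
  }
  idx <- idx[ok]; kind <- kind[ok]
  ck <- collapse_runs(x, idx, kind)
  list(idx = ck$idx, kind = ck$kind)
}

# merge consecutive extrema of the same type, keeping the extreme one
collapse_runs <- function(x, idx, kind) {
  if (length(idx) < 2L) return(list(idx = idx, kind = kind))
  keep_idx <- integer(0); keep_kind <- integer(0)
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && kind[j + 1L] == kind[i]) j <- j + 1L
    run <- idx[i:j]
    best <- if (kind[i] > 0) run[which.max(x[run])] else run[which.min(x[run])]
    keep_idx <- c(keep_idx, best); keep_kind <- c(keep_kind, kind[i])
    i <- j + 1L
  }
  list(idx = keep_idx, kind = keep_kind)
}

fill_forward <- function(x) {
  if (length(x) == 0L) return(x)
  for (i in seq_along(x)[-1L]) if (is.na(x[i])) x[i] <- x[i - 1L]
  # leading NAs: backfill
  for (i in rev(seq_along(x))[-1L]) if (is.na(x[i])) x[i] <- x[i + 1L]
  x
}

#' Aggregate respiratory metrics over breath cycles
#'
#' Drops the first \code{discard} (transient) cycles, optionally excludes
#' patient-triggered cycles, and reports mean and sample SD (n-1
#' denominator) of each respiratory index: PIP, PEEP, period,
#' respiratory rate (60 / period, breaths/min), I:E ratio (T_e / T_i)
#' and tidal volume.
#'
#' @param cycles a \code{breath_cycles} data.frame from
#'   [segment_breaths()].
#' @param discard number of initial cycles to drop.
#' @param include_triggered logical; triggered cycles are excluded from
#'   the steady-state summary by default.
#' @return An object of class \code{respiratory_metrics}: a list with
#'   \code{n_cycles} and \code{mean} / \code{sd} named vectors over the
#'   indices.
#' @export
#' @examples
#' fs <- fixture_spec(n_cycles = 6)
#' compute_metrics(segment_breaths(make_synthetic_waveform(fs)), discard = 1)
compute_metrics <- function(cycles, discard = 2, include_triggered = FALSE) {
  stopifnot(is.data.frame(cycles))
  if (discard > 0) cycles <- cycles[-seq_len(min(discard, nrow(cycles))), ]
  if (!include_triggered && "triggered" %in% names(cycles)) {
    cycles <- cycles[!cycles$triggered, ]
  }
  if (nrow(cycles) < 1L) {
    stop_insufficient("insufficient data: no cycles left after discarding")
  }
  vals <- list(PIP = cycles$PIP, PEEP = cycles$PEEP,
               period = cycles$period, RR = 60 / cycles$period,
               IE_ratio = cycles$T_e / cycles$T_i,
               tidal_volume = cycles$tidal_volume)
  structure(
    list(n_cycles = nrow(cycles),
         mean = vapply(vals, mean, numeric(1)),
         sd = vapply(vals, stats::sd, numeric(1))),
    class = "respiratory_metrics")
}

#' @export
print.respiratory_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Respiratory metrics over %d cycles (mean +/- SD):\n",
              x$n_cycles))
  units <- c(PIP = "cmH2O", PEEP = "cmH2O", period = "s", RR = "bpm",
             IE_ratio = "(1:x)", tidal_volume = "L")
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s %8.*f +/- %.*f %s\n", nm, digits, x$mean[[nm]],
                digits, x$sd[[nm]], units[[nm]]))
  }
  invisible(x)
}

#' Exhaust-screw (EC) parameter sweep
#'
#' Re-runs the simulation across a set of EC occlusion fractions, all
#' other settings fixed, and tabulates the steady-state indices at each
#' setting. This is the in-silico analogue of turning the period screw
#' on the physical device.
#'
#' @param base a [simulation_config()] used as the template.
#' @param d_values EC occlusion fractions in [0, 1].
#' @return A data.frame of class \code{ec_sweep}, ordered by \code{d_EC},
#'   with columns \code{d_EC}, \code{period}, \code{PIP}, \code{PEEP},
#'   \code{IE_ratio}, \code{RR}, \code{tidal_volume}, \code{n_cycles}.
#' @export
ec_sweep <- function(base = simulation_config(),
                     d_values = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(base, "simulation_config"))
  if (any(d_values < 0 | d_values > 1)) {
    stop("all `d_values` must lie in [0, 1]", call. = FALSE)
  }
  d_values <- sort(d_values)
  rows <- lapply(d_values, function(d) {
    scr <- screw_settings(d_EC = d, d_FC = base$screws$d_FC,
                          d_SC = base$screws$d_SC)
    cfg <- simulation_config(lung = base$lung, diverter = base$diverter,
                             screws = scr, trigger = base$trigger,
                             dt = base$dt, duration = base$duration,
                             transient_discard = base$transient_discard)
    m <- compute_metrics(segment_breaths(simulate_ventilator(cfg)),
                         discard = base$transient_discard)
    data.frame(d_EC = d, period = m$mean[["period"]],
               PIP = m$mean[["PIP"]], PEEP = m$mean[["PEEP"]],
               IE_ratio = m$mean[["IE_ratio"]], RR = m$mean[["RR"]],
               tidal_volume = m$mean[["tidal_volume"]],
               n_cycles = m$n_cycles)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ec_sweep", "data.frame")
  out
}

#' Linear fit of oscillation period on EC screw depth
#'
#' Ordinary least squares of the steady-state period on the EC occlusion
#' fraction. On the calibrated device the relation is close to linear
#' with positive slope, so the fit summarises the period screw's "gain".
#'
#' @param table an [ec_sweep()] table (or any data.frame with columns
#'   \code{d_EC} and \code{period}).
#' @return A list with \code{slope} (s per unit occlusion),
#'   \code{intercept} (s) and \code{r_squared}.
#' @export
fit_period_vs_depth <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("d_EC", "period") %in% names(table)))
  if (nrow(table) < 3L) {
    stop_insufficient("insufficient data: need at least 3 sweep points to fit")
  }
  fit <- stats::lm(period ~ d_EC, data = table)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((table$period - mean(table$period))^2)
  list(slope = unname(stats::coef(fit)[["d_EC"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}
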