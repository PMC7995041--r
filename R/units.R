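#' Unit conversion helpers
#'
#' Internally the package works in cmH2O, litres and seconds. User-facing
#' configuration accepts the mixed conventions common on ventilator spec
#' sheets: compliance in mL/cmH2O, flow in L/min and geometry in mm. These
#' helpers convert on ingest and are exact (a single multiplication), so
#' round-tripping is lossless to machine precision.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ml_per_cmh2o_to_l <- function(x) x / 1000

#' @rdname units
#' @export
l_per_cmh2o_to_ml <- function(x) x * 1000

#' @rdname units
#' @export
lpm_to_lps <- function(x) x / 60

#' @rdname units
#' @export
lps_to_lpm <- function(x) x * 60

#' @rdname units
#' @export
mm_to_m <- function(x) x / 1000

# internal: scalar numeric check used by constructors throughout
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop(sprintf("`%s` = %g is outside its admissible range %s%g, %g]",
                 name, x, if (strict_lower) "(" else "[", lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
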