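# shared fixtures: short default runs keep the suite quick; the
# acceptance tests use the full 60 s horizon
quick_config <- function(duration = 30, ...) {
  simulation_config(duration = duration, ...)
}

# steady-state metrics of a config in one call
run_metrics <- function(cfg) {
  compute_metrics(segment_breaths(simulate_ventilator(cfg)),
                  discard = cfg$transient_discard)
}

# trapezoidal running integral, the independent volume oracle
cumtrapz <- function(t, y) {
  c(0, cumsum(diff(t) * (y[-1] + y[-length(y)]) / 2))
}
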