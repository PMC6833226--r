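# Classed error conditions used across the package so callers and tests can
# distinguish failure modes programmatically.

abort_spindlemag <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "spindlemag_error"),
                      call = call))
}

abort_invalid_field <- function(msg) abort_spindlemag(msg, "invalid_field_error")
abort_invalid_geometry <- function(msg) abort_spindlemag(msg, "invalid_geometry_error")
abort_domain <- function(msg) abort_spindlemag(msg, "domain_error")
abort_degenerate_bending <- function(msg) abort_spindlemag(msg, "degenerate_bending_error")
abort_timestep <- function(msg) abort_spindlemag(msg, "timestep_too_large_error")
abort_no_relaxation <- function(msg) abort_spindlemag(msg, "no_relaxation_error")
abort_config <- function(msg) abort_spindlemag(msg, "config_error")
abort_parse <- function(msg) abort_spindlemag(msg, "parse_error")
abort_instability <- function(msg) abort_spindlemag(msg, "instability_error")

stop_unless_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_domain(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort_domain(sprintf("`%s` must be strictly positive", name))
  if (nonneg && x < 0)
    abort_domain(sprintf("`%s` must be non-negative", name))
  invisible(x)
}
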