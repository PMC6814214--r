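# Classed conditions so callers (and tests) can distinguish failure modes.

stop_proptab <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "proptab_error"), call = call))
}

stop_domain <- function(msg) stop_proptab(msg, "proptab_domain_error")
stop_degenerate <- function(msg) stop_proptab(msg, "proptab_degenerate_error")
stop_zero_margin <- function(msg) stop_proptab(msg, "proptab_zero_margin_error")
stop_undefined <- function(msg) stop_proptab(msg, "proptab_undefined_error")

warn_proptab <- function(msg) {
  warning(warningCondition(msg, class = c("proptab_warning", "warning")))
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("'%s' must be a single finite number", name))
  as.numeric(x)
}

# Deterministic per-run seed below 2^31, mixing a root seed with a run index.
derive_seed <- function(seed, run_index) {
  s <- (as.double(seed) %% 65521) * 31607 + as.double(run_index) * 2654435761
  as.integer(s %% 2147483647)
}
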