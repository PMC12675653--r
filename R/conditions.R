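# Classed error conditions so callers (and tests) can discriminate failure
# modes without parsing messages.

psaqc_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "psaqc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_config      <- function(msg) psaqc_abort(msg, "psaqc_config_error")
abort_domain      <- function(msg) psaqc_abort(msg, "psaqc_domain_error")
abort_geometry    <- function(msg) psaqc_abort(msg, "psaqc_geometry_error")
abort_degenerate  <- function(msg) psaqc_abort(msg, "psaqc_degenerate_geometry")
abort_no_markers  <- function(msg) psaqc_abort(msg, "psaqc_markers_not_found")
abort_ambiguous   <- function(msg) psaqc_abort(msg, "psaqc_ambiguous_detection")
abort_empty_trial <- function(msg) psaqc_abort(msg, "psaqc_empty_trial")
abort_insufficient <- function(msg) psaqc_abort(msg, "psaqc_insufficient_data")

# Run an expression with a locally seeded RNG, restoring global RNG state.
# All generator functions route randomness through this so identical
# (inputs, seed) give bit-identical output regardless of ambient RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_config("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
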