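# Internal helpers shared across modules.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vagusnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_parse <- function(msg, ...) abort(msg, "vagusnet_parse_error", ...)
abort_lookup <- function(msg, ...) abort(msg, "vagusnet_lookup_error", ...)
abort_validation <- function(msg, ...) abort(msg, "vagusnet_validation_error", ...)
abort_insufficient <- function(msg, ...) abort(msg, "vagusnet_insufficient_data_error", ...)

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never perturb a user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic numeric rendering used by all text writers (SWC, CSV):
# plain decimal notation, up to 15 significant digits, no trailing zeros.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, trim = TRUE, scientific = FALSE, digits = 15, drop0trailing = TRUE)
  }, character(1))
  out
}
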