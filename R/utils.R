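# internal helpers shared across modules

# Evaluate expr under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-stage seed from a master seed; keeps results independently
# re-runnable per stage. Stays within 32-bit integer range.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
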