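# Classed conditions so callers (and the CLI) can distinguish bad user input
# from genuine runtime failures.

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("rh_validation_error", "rh_error")))
}

abort_structural <- function(...) {
  stop(errorCondition(paste0(...), class = c("rh_structural_error", "rh_error")))
}

abort_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("rh_degenerate_error", "rh_error")))
}

abort_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("rh_io_error", "rh_error")))
}

# Run an expression under a fixed RNG state without disturbing the caller's
# random stream.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
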