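# Internal helpers shared across the package.

# Classed conditions so that callers (and the CLI) can map failures to exit
# codes: configuration/usage problems vs. data problems vs. parameter misuse.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("epifd_config_error", "epifd_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("epifd_data_error", "epifd_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("epifd_param_error", "epifd_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that library calls never disturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

is_pow2 <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
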