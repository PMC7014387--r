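# Internal helpers shared across modules.

abort_escbn <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "escbn_error"), ...)
}

# Run code with a locally seeded RNG, restoring global state afterwards.
# All randomness in the package funnels through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_escbn("`seed` must be a single integer.", "escbn_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed below 2^31 from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  offsets <- c(
    sample_records = 104729L, missingness = 130363L, experts = 15485863L %% 99991L,
    em_init = 32452843L %% 99991L, noise = 49979687L %% 99991L
  )
  off <- offsets[[stream]] %||% (sum(utf8ToInt(stream)) * 131L)
  as.integer((as.numeric(seed) * 2654435761 + off) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort_escbn(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "escbn_config_error"
    )
  }
  invisible(x)
}
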