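# Internal helpers: validation, seeded evaluation, hashing.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, integer = FALSE,
                             allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L &&
    (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok) stop_invalid(field, "must be a single finite number")
  if (integer && x != round(x)) stop_invalid(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) stop_invalid(field, sprintf("must be > %g", lower))
  } else if (x < lower) stop_invalid(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_invalid(field, sprintf("must be <= %g", upper))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage child seed from a global seed; stays below 2^31 - 1.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stage) %% 2147483647)
}

# Stable md5 of an R object via its canonical JSON serialization.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
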