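# internal helpers: validation and seed scoping

.assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

.assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

.assert_scalar <- function(x, name) {
  if (length(x) != 1L) stop(sprintf("`%s` must be a single value", name), call. = FALSE)
  invisible(x)
}

# unit conversions (centralized: mixed-unit formulas are easy to get wrong)
.uL_min_to_m3_s <- function(q) q * 1e-9 / 60
.um_to_m <- function(x) x * 1e-6

# Run `code` under a fixed RNG seed without touching the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a `seed` must be supplied", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
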