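#' @importFrom rlang .data
#' @importFrom stats rnorm runif sd var pf pt qt lm coef predict cor complete.cases
#' @importFrom utils write.csv read.csv head
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a base seed; keeps results in 32-bit
# integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict_min && x < min) stopf("`%s` must be >= %g", name, min)
  invisible(x)
}
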