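#' @importFrom rlang abort warn %||% .data
#' @importFrom stats quantile rnorm runif var predict
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a top-level seed and a stage label.
# Keeps every derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict && x <= min) || (!strict && x < min)) {
    abort(sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", format(min)))
  }
  invisible(x)
}
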