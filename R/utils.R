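# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Generators must not leak global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_field(field, sprintf("must be a single integer >= %s", min))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min) {
    stop_field(field, sprintf("must be a single number >= %s", min))
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
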