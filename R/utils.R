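# Internal helpers: condition constructors and seeded evaluation.

gg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gg_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "gg_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All seeded operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    gg_stop("seed must be a single non-missing number", "gg_invalid_parameter")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a base seed, staying within 32-bit range.
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271 + as.integer(k)) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, arg = "image") {
  if (!is_image(x)) {
    gg_stop(sprintf("%s must be a 2-D numeric matrix", arg), "gg_invalid_input")
  }
  invisible(x)
}
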