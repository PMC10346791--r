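# Internal helpers shared across modules.

#' @useDynLib eegwave, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps simulation streams independent
# of any RNG use by the surrounding session.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_eegwave <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "eegwave_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
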