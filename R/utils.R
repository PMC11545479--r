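#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Run code with a temporarily-seeded RNG, restoring global RNG state after.
# All generators route their randomness through this so that a given seed
# yields the same object regardless of what the session did before.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("%s contains non-finite values", what), class = "rbcnano_format_error")
  }
  invisible(x)
}

abort_param <- function(msg) abort(msg, class = "rbcnano_parameter_error")
abort_format <- function(msg) abort(msg, class = "rbcnano_format_error")
abort_data <- function(msg) abort(msg, class = "rbcnano_insufficient_data")
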