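#' @keywords internal
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom nnet nnet class.ind
#' @importFrom glmnet glmnet
#' @importFrom signal cheby2 butter filtfilt
#' @importFrom jsonlite write_json read_json
"_PACKAGE"

# Run code with a local, restorable RNG state. All stochastic entry points
# funnel through this so nothing leaks into (or depends on) the global stream.
with_seed <- function(seed, code) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive independent sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

rms <- function(x) sqrt(mean(x^2))
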