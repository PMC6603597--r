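#' @keywords internal
#' @useDynLib slrmech, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run code under a temporary RNG state so callers' streams are untouched.
# All stochastic entry points funnel through this for reproducibility.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

# canonical channel layout: rows 1-8 sEMG, 9-11 accelerometer, 12-14 gyroscope
N_CHANNELS <- 14L
SEMG_ROWS <- 1:8
ACC_ROWS <- 9:11
GYR_ROWS <- 12:14
IMU_ROWS <- 9:14

channel_roles <- function() {
  c(rep("sEMG", 8L), rep("ACC", 3L), rep("GYR", 3L))
}
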