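#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions can be deterministic without clobbering
#' the session's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Structured log message
#'
#' Simple INFO-level logger used across the pipeline; suppress with
#' `options(blebkit.quiet = TRUE)`.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values for `fmt`.
#' @keywords internal
bk_log <- function(fmt, ...) {
  if (isTRUE(getOption("blebkit.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[blebkit] %s", sprintf(fmt, ...)))
}

# clip numeric values into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stopifnot with a formatted message
assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
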