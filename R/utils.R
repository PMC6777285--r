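#' Round half away from zero
#'
#' Commercial-rounding helper used for reported percentages and summary
#' statistics, where exactly-half values round away from zero (so 91.525
#' becomes 91.53). [base::round()] uses round-half-to-even, which differs
#' at these ties.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(91.525, 2) # 91.53, where round() gives 91.52
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
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
  set.seed(seed)
  force(code)
}

# Timestamps are wall-clock ISO-8601 at second resolution. All devices are
# assumed NTP-synchronised, so a single fixed zone (UTC internally) is used
# and no zone arithmetic is ever applied to the readings themselves.
parse_timestamp <- function(x) {
  out <- as.POSIXct(sub("T", " ", x, fixed = TRUE),
                    tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
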