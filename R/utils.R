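`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## clamp that warns when it actually bites; used for probabilities that a
## policy multiplier or rounding pushed outside [0, 1]
clamp_prob <- function(x, what = "probability") {
  if (any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE)) {
    warning(sprintf("%s outside [0, 1]; clamped", what), call. = FALSE)
  }
  clamp(x, 0, 1)
}

stop_if_not_scalar_year <- function(year) {
  if (!is.numeric(year) || length(year) != 1L || is.na(year)) {
    stop("`year` must be a single calendar year", call. = FALSE)
  }
}

SEXES <- c("male", "female")
MAX_AGE <- 100L
AGES <- 0:100

## smallest age at which anyone may smoke in this model; below it every
## person is a never smoker (youth-access effects start at age 10)
MIN_SMOKING_AGE <- 10L
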