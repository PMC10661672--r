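#' Demography inputs
#'
#' Bundle the demographic surfaces needed to project a population by single
#' year of age (0 to 100, with 100 an open terminal band) and sex from a
#' base year to a horizon year.
#'
#' @param base_population Numeric matrix `[age 0:100, sex]` of persons in
#'   the base year.
#' @param death_rate Either a numeric matrix `[age, sex]` of annual death
#'   probabilities used for every year, or a function `f(year)` returning
#'   such a matrix.
#' @param births Either a single count of births per year, a named vector
#'   `c(male=, female=)`, or a function `f(year)` returning one of those.
#'   A scalar is split evenly between the sexes.
#' @param migration Net migrants per age and sex: matrix `[age, sex]`
#'   applied every year, or a function `f(year)`; may be negative.
#'   Default 0.
#' @param base_year,horizon_year Calendar years bounding the projection.
#' @return An object of class `demography_inputs`.
#' @export
demography_inputs <- function(base_population, death_rate, births,
                              migration = NULL,
                              base_year, horizon_year) {
  base_population <- as_age_sex_matrix(base_population, "base_population")
  if (any(base_population < 0)) stop("base_population must be >= 0")
  dr0 <- resolve_year_input(death_rate, base_year)
  if (any(dr0 < 0 | dr0 > 1)) stop("death_rate must lie in [0, 1]")
  if (horizon_year < base_year) stop("horizon_year must be >= base_year")
  structure(
    list(base_population = base_population, death_rate = death_rate,
         births = births, migration = migration,
         base_year = base_year, horizon_year = horizon_year),
    class = "demography_inputs"
  )
}

as_age_sex_matrix <- function(x, what = "value") {
  x <- as.matrix(x)
  if (nrow(x) != length(AGES) || ncol(x) != length(SEXES)) {
    stop(sprintf("%s must be a %d x %d matrix (ages 0-100 by male/female)",
                 what, length(AGES), length(SEXES)), call. = FALSE)
  }
  dimnames(x) <- list(age = AGES, sex = SEXES)
  x
}

resolve_year_input <- function(x, year) {
  if (is.function(x)) x <- x(year)
  if (is.null(x)) return(NULL)
  as_age_sex_matrix(x)
}

resolve_births <- function(births, year) {
  b <- if (is.function(births)) births(year) else births
  if (is.null(b)) b <- 0
  if (length(b) == 1L) b <- c(male = b / 2, female = b / 2)
  b <- b[SEXES]
  if (any(is.na(b)) || any(b < 0)) stop("births must be non-negative counts")
  b
}

## One demographic year step: age/survive -> migrate -> births (fixed order).
## `pop` is an [age, sex] matrix at year t; the result is the matrix at t+1.
step_demography <- function(pop, death_rate, migration, births) {
  surv <- pop * (1 - death_rate)
  nxt <- matrix(0, length(AGES), length(SEXES),
                dimnames = list(age = AGES, sex = SEXES))
  nxt[2:length(AGES), ] <- surv[1:(length(AGES) - 1L), ]
  ## terminal open band accumulates its own survivors
  nxt[length(AGES), ] <- nxt[length(AGES), ] + surv[length(AGES), ]
  if (!is.null(migration)) {
    nxt <- nxt + migration
    if (any(nxt < 0)) {
      warning("negative population after migration; clamped to 0",
              call. = FALSE)
      nxt[nxt < 0] <- 0
    }
  }
  nxt[1, ] <- nxt[1, ] + births
  nxt
}

#' Project a population to a given year
#'
#' Cohort-component projection: each year survivors age by one year (the
#' terminal band accumulates), net migration is added, and births enter at
#' age 0.
#'
#' @param inputs A [demography_inputs()] object.
#' @param year Target calendar year between the base and horizon year.
#' @return Matrix `[age, sex]` of persons at `year`.
#' @export
project_population <- function(inputs, year) {
  stopifnot(inherits(inputs, "demography_inputs"))
  stop_if_not_scalar_year(year)
  if (year < inputs$base_year || year > inputs$horizon_year) {
    stop(sprintf("year %s outside projection range [%s, %s]", year,
                 inputs$base_year, inputs$horizon_year), call. = FALSE)
  }
  pop <- inputs$base_population
  if (year == inputs$base_year) return(pop)
  for (t in inputs$base_year:(year - 1L)) {
    pop <- step_demography(
      pop,
      death_rate = resolve_year_input(inputs$death_rate, t),
      migration = resolve_year_input(inputs$migration, t),
      births = resolve_births(inputs$births, t)
    )
  }
  pop
}
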