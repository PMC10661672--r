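#' Configuration for a synthetic country
#'
#' Defines a self-consistent synthetic population with known ground
#' truth: a stable age pyramid, a single-peaked age profile of smoking
#' prevalence, initiation/cessation/relapse rates consistent with that
#' profile, and a survey design.  An injected vaping signal `g` makes the
#' survey world's current smoking decline an extra `g` per year
#' (relative) from `nvp_year` on, while the model world knows nothing of
#' it — exactly the situation the indirect inference method addresses.
#'
#' The distortion factors `true_init_factor`/`true_cess_factor` separate
#' the data-generating rates from the rates handed to the analyst, so the
#' calibration step has something real to recover.
#'
#' @param seed Integer seed; fixed seed gives identical bundles.
#' @param base_year,nvp_year,last_survey_year,horizon_year Calendar
#'   years: simulation start, start of the vaping era, last surveyed
#'   year, and projection horizon.
#' @param pop_size Total base-year population.
#' @param peak_age,peak_level,decline_slope Shape of the baseline
#'   current-smoking age profile (per sex peak level; linear relative
#'   decline per year of age past the peak).
#' @param never_floor Adult never-smoking prevalence floor.
#' @param cessation_rates Annual quit probabilities `c(young, mid, old)`
#'   for ages up to 34, 35-64, and 65+.
#' @param true_init_factor,true_cess_factor Multiplicative distortions
#'   defining the data-generating rates relative to the analyst's.
#' @param g Extra annual relative decline in current smoking from
#'   `nvp_year` (scalar, applied to all bands).
#' @param survey_n Sample size per band-year-sex cell:
#'   `c(adult = , sub = )` for the `15+`/`18+` bands and narrower bands.
#' @param bands Reporting bands for the synthetic survey.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 20120101,
                             base_year = 1999, nvp_year = 2012,
                             last_survey_year = 2020, horizon_year = 2040,
                             pop_size = 1e6,
                             peak_age = 22,
                             peak_level = c(male = 0.26, female = 0.21),
                             decline_slope = 0.008,
                             never_floor = 0.45,
                             cessation_rates = c(young = 0.055,
                                                 mid = 0.035, old = 0.05),
                             true_init_factor = 0.85,
                             true_cess_factor = 1.15,
                             g = 0,
                             survey_n = c(adult = 8000, sub = 2000),
                             bands = c("15+", "15-24", "25-44",
                                       "45-64", "65+")) {
  stopifnot(g >= 0, g < 1, pop_size > 0, all(survey_n > 0),
            base_year < nvp_year, nvp_year < last_survey_year)
  structure(as.list(environment()), class = "synthetic_config")
}

## baseline current-smoking prevalence by single-year age for one sex
synthetic_prevalence_curve <- function(cfg, sex) {
  peak <- cfg$peak_level[[sex]]
  p <- numeric(length(AGES))
  rise <- AGES >= MIN_SMOKING_AGE & AGES <= cfg$peak_age
  p[rise] <- peak * (AGES[rise] - MIN_SMOKING_AGE) /
    (cfg$peak_age - MIN_SMOKING_AGE)
  past <- AGES > cfg$peak_age
  p[past] <- peak * pmax(0.2, 1 - cfg$decline_slope * (AGES[past] - cfg$peak_age))
  p
}

## never-smoking prevalence consistent with the curve: 1 below the
## minimum smoking age, declining to the adult floor by age 30
synthetic_never_curve <- function(cfg) {
  nv <- rep(1, length(AGES))
  mid <- AGES > MIN_SMOKING_AGE & AGES < 30
  nv[mid] <- 1 - (1 - cfg$never_floor) * (AGES[mid] - MIN_SMOKING_AGE) / 20
  nv[AGES >= 30] <- cfg$never_floor
  nv
}

synthetic_death_rate <- function() {
  d <- pmin(0.5, 1e-4 * exp(0.078 * AGES))
  matrix(d, length(AGES), length(SEXES),
         dimnames = list(age = AGES, sex = SEXES))
}

#' Generate a synthetic input bundle
#'
#' Builds the base state, rates, and demography; runs the
#' data-generating ("truth") model to produce the true prevalence series;
#' overlays the injected vaping signal; and samples the survey.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_bundle`: `scenario` (the analyst's
#'   scenario, undistorted rates), `truth_scenario` (data-generating
#'   rates), `truth_prevalence` (data frame incl. the injected signal),
#'   `survey` (sampled series with Wilson CIs), `config`.
#' @export
generate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dr <- synthetic_death_rate()

  ## stable-ish pyramid: survivorship-weighted ages
  lx <- cumprod(c(1, 1 - dr[-length(AGES), 1]))
  pop_age <- cfg$pop_size * lx / sum(lx)
  base_pop <- cbind(male = pop_age / 2, female = pop_age / 2)

  never <- synthetic_never_curve(cfg)
  counts <- array(0, c(length(AGES), length(SEXES), length(STATUS)),
                  dimnames = list(age = AGES, sex = SEXES, status = STATUS))
  init <- matrix(0, length(AGES), length(SEXES),
                 dimnames = list(age = AGES, sex = SEXES))
  cess <- matrix(0, length(AGES), length(SEXES),
                 dimnames = list(age = AGES, sex = SEXES))
  a_init <- c(male = 20, female = 21)
  bin_w <- c(0.10, 0.15, 0.20, 0.25, 0.15, 0.15)

  for (s in SEXES) {
    cur <- synthetic_prevalence_curve(cfg, s)
    nv <- pmin(never, 1 - cur)
    former <- pmax(0, 1 - nv - cur)
    counts[, s, "never"] <- base_pop[, s] * nv
    counts[, s, "current"] <- base_pop[, s] * cur
    for (b in 1:N_BINS) {
      counts[, s, paste0("former", b)] <- base_pop[, s] * former * bin_w[b]
    }
    smoking_ages <- AGES >= MIN_SMOKING_AGE & AGES <= a_init[[s]]
    ii <- derive_net_initiation(cur[smoking_ages], nv[smoking_ages],
                                AGES[smoking_ages], a_init = a_init[[s]])
    init[smoking_ages, s][-1] <- ii[-1]
    cess[AGES > a_init[[s]] & AGES <= 34, s] <- cfg$cessation_rates[["young"]]
    cess[AGES >= 35 & AGES <= 64, s] <- cfg$cessation_rates[["mid"]]
    cess[AGES >= 65, s] <- cfg$cessation_rates[["old"]]
  }

  state <- population_state(cfg$base_year, counts)
  births <- sum(base_pop[1, ])
  rates <- transition_rates(init, cess)
  truth_rates <- transition_rates(
    clamp(init * cfg$true_init_factor, 0, 1),
    clamp(cess * cfg$true_cess_factor, 0, 1))

  scenario <- smoking_scenario(cfg$base_year, cfg$horizon_year, state,
                               rates, dr, births)
  truth_scenario <- smoking_scenario(cfg$base_year, cfg$horizon_year, state,
                                     truth_rates, dr, births)

  truth_run <- run_model(truth_scenario, end_year = cfg$last_survey_year,
                         bands = cfg$bands)
  tp <- truth_run$prevalence
  tp <- tp[tp$sex %in% SEXES, ]
  ## injected vaping signal: extra relative decline after nvp_year
  k <- pmax(0, tp$year - cfg$nvp_year)
  tp$prevalence <- tp$prevalence * (1 - cfg$g)^k
  truth_prevalence <- tp

  survey <- sample_survey(truth_prevalence, cfg$survey_n, cfg$seed)

  structure(list(scenario = scenario, truth_scenario = truth_scenario,
                 truth_prevalence = truth_prevalence, survey = survey,
                 config = cfg),
            class = "synthetic_bundle")
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  cbind(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' Sample a survey series from true prevalence
#'
#' Binomial sampling per (sex, band, year) cell with Wilson 95%
#' intervals, emulating design-based survey estimates.
#'
#' @param truth Data frame `sex`, `band`, `year`, `prevalence`
#'   (fractions in (0, 1)).
#' @param n Sample size per cell: scalar, or named vector
#'   `c(adult = , sub = )` where `adult` covers open-ended adult bands
#'   (`15+`, `18+`) and `sub` the narrower bands.
#' @param seed Integer seed.
#' @return Data frame `sex`, `band`, `year`, `n`, `prevalence`,
#'   `ci_low`, `ci_high`.
#' @export
sample_survey <- function(truth, n, seed) {
  stopifnot(all(truth$prevalence > 0 & truth$prevalence < 1))
  n_cell <- if (length(n) == 1L) rep(n, nrow(truth)) else {
    ifelse(truth$band %in% c("15+", "18+"), n[["adult"]], n[["sub"]])
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- stats::rbinom(nrow(truth), n_cell, truth$prevalence)
  phat <- x / n_cell
  ci <- wilson_ci(x, n_cell)
  data.frame(sex = truth$sex, band = truth$band, year = truth$year,
             n = n_cell, prevalence = phat,
             ci_low = ci[, "low"], ci_high = ci[, "high"],
             stringsAsFactors = FALSE, row.names = NULL)
}
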