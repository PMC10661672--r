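#' Build a simulation scenario
#'
#' Binds together everything one model run needs: the base-year
#' population and smoking-state mix, transition rates, demographic
#' surfaces, relative risks, an optional policy timeline, and an optional
#' vaping-era prevalence adjustment.
#'
#' @param base_year First simulated year; `end_year` the last.
#' @param initial_state A [population_state()] at `base_year`.
#' @param rates A [transition_rates()] object.
#' @param death_rate `[age, sex]` matrix of overall annual death
#'   probabilities, or a function of year.
#' @param births Births per year (scalar, named vector, or function of
#'   year).
#' @param migration Optional net migration `[age, sex]` matrix or function
#'   of year; migrants carry the resident status mix of their age/sex
#'   cell.
#' @param rr Relative-risk array `[age, sex, status]`
#'   (default [default_rr_table()]).
#' @param timeline Optional [policy_timeline()].
#' @param nvp_adjustment Optional list `list(alpha = , years = )` where
#'   `alpha` is a data frame (`sex`, `band`, `alpha`) of per-year relative
#'   reductions in current smoking applied via [apply_adjustment()] during
#'   `years`.
#' @return Object of class `smoking_scenario`.
#' @export
smoking_scenario <- function(base_year, end_year, initial_state, rates,
                             death_rate, births, migration = NULL,
                             rr = default_rr_table(), timeline = NULL,
                             nvp_adjustment = NULL) {
  stopifnot(inherits(initial_state, "population_state"),
            inherits(rates, "transition_rates"),
            end_year >= base_year,
            initial_state$year == base_year)
  structure(
    list(base_year = base_year, end_year = end_year,
         initial_state = initial_state, rates = rates,
         death_rate = death_rate, births = births, migration = migration,
         rr = rr, timeline = timeline, nvp_adjustment = nvp_adjustment),
    class = "smoking_scenario"
  )
}

## expand a (sex, band, alpha) data frame to an [age, sex] matrix;
## bands apply uniformly to their single-year ages
alpha_matrix <- function(alpha_df) {
  m <- matrix(0, length(AGES), length(SEXES),
              dimnames = list(age = AGES, sex = SEXES))
  for (j in seq_len(nrow(alpha_df))) {
    m[AGES %in% band_ages(alpha_df$band[j]), alpha_df$sex[j]] <-
      alpha_df$alpha[j]
  }
  m
}

#' Reallocate current smokers by a per-year adjustment
#'
#' Scales current smokers by `(1 - alpha)`; the removed mass returns to
#' never smokers at initiation ages and enters the `<1` year former bin
#' above them.  Total persons per age/sex cell are unchanged.
#'
#' @param state A [population_state()].
#' @param alpha Scalar, `[age, sex]` matrix, or data frame
#'   (`sex`, `band`, `alpha`) of annual relative reductions; must be `< 1`.
#' @param a_init Last initiation ages, `c(male=, female=)`.
#' @return Adjusted `population_state`.
#' @export
apply_adjustment <- function(state, alpha, a_init = c(male = 20, female = 21)) {
  if (is.data.frame(alpha)) alpha <- alpha_matrix(alpha)
  if (length(alpha) == 1L) alpha <- matrix(alpha, length(AGES), length(SEXES))
  alpha <- as_age_sex_matrix(alpha, "alpha")
  if (any(alpha >= 1)) stop("alpha must be < 1")
  x <- state$counts
  init_ages <- outer(AGES, a_init[SEXES], `<=`)
  removed <- pmax(alpha, 0) * x[, , "current"]
  x[, , "current"] <- x[, , "current"] - removed
  x[, , "never"] <- x[, , "never"] + removed * init_ages
  x[, , "former1"] <- x[, , "former1"] + removed * !init_ages
  ## negative adjustments (prevalence rising faster than the
  ## counterfactual) pull mass back into smoking, capped at the donor
  ## state's stock
  gain <- pmax(-alpha, 0) * x[, , "current"]
  if (any(gain > 0)) {
    take_n <- pmin(gain * init_ages, x[, , "never"])
    take_f <- pmin(gain * !init_ages, x[, , "former1"])
    x[, , "never"] <- x[, , "never"] - take_n
    x[, , "former1"] <- x[, , "former1"] - take_f
    x[, , "current"] <- x[, , "current"] + take_n + take_f
  }
  population_state(state$year, x)
}

## demographic year step for a full smoking state: survive with
## status-specific rates, age, migrate (resident status mix), births
step_state_demography <- function(state, d_status, migration, births) {
  x <- state$counts * (1 - d_status)
  nxt <- array(0, dim(x), dimnames = dimnames(x))
  nxt[2:length(AGES), , ] <- x[1:(length(AGES) - 1L), , ]
  nxt[length(AGES), , ] <- nxt[length(AGES), , ] + x[length(AGES), , ]
  if (!is.null(migration)) {
    tot <- apply(nxt, c(1, 2), sum)
    share <- nxt / ifelse(c(tot) == 0, 1, c(tot))
    ## cells with no residents receive migrants as never smokers
    empty <- tot == 0
    if (any(empty)) share[, , "never"][empty] <- 1
    nxt <- nxt + share * c(migration)
    if (any(nxt < 0)) {
      warning("negative cell after migration; clamped to 0", call. = FALSE)
      nxt[nxt < 0] <- 0
    }
  }
  nxt[1, , "never"] <- nxt[1, , "never"] + births
  population_state(state$year + 1L, nxt)
}

#' Run the simulation
#'
#' Advances the scenario year by year.  Within each year: smoking-state
#' transitions under that year's policy multipliers, then the optional
#' vaping-era adjustment, then mortality (status-specific rates derived
#' from overall mortality and relative risks, with smoking-attributable
#' deaths recorded), ageing, migration, and births.  Prevalence is
#' recorded from the start-of-year state.
#'
#' @param scenario A [smoking_scenario()].
#' @param end_year Last year to simulate (default the scenario's).
#' @param bands Age bands for the prevalence series (default the two
#'   survey conventions' reporting bands).
#' @return List of class `smokesim_run` with elements `prevalence`
#'   (data frame: `year`, `sex`, `band`, `prevalence`), `sads` (data
#'   frame: `year`, `sex`, `sads`), `final_state`, and `states` (start-of-
#'   year states, kept only if `keep_states = TRUE`).
#' @param keep_states Keep every start-of-year state (memory-heavier).
#' @export
run_model <- function(scenario, end_year = scenario$end_year,
                      bands = c("15+", "15-24", "25-44", "45-64", "65+",
                                "18+", "18-24"),
                      keep_states = FALSE) {
  stopifnot(inherits(scenario, "smoking_scenario"))
  years <- scenario$base_year:end_year
  mult <- if (!is.null(scenario$timeline)) {
    build_policy_multipliers(scenario$timeline, years)
  } else NULL
  nvp <- scenario$nvp_adjustment
  nvp_alpha <- if (!is.null(nvp)) {
    if (is.data.frame(nvp$alpha)) alpha_matrix(nvp$alpha) else
      as_age_sex_matrix(nvp$alpha, "alpha")
  }

  st <- scenario$initial_state
  nb <- length(bands)
  band_idx <- lapply(bands, function(b) band_ages(b) + 1L)  # row indices
  prev_arr <- array(NA_real_, c(nb, 3, length(years)))      # band, sex, year
  sads <- matrix(0, length(years), length(SEXES),
                 dimnames = list(year = years, sex = SEXES))
  states <- if (keep_states) vector("list", length(years))

  for (k in seq_along(years)) {
    t <- years[k]
    if (keep_states) states[[k]] <- st
    cur <- st$counts[, , "current"]
    tot <- rowSums(st$counts, dims = 2)
    for (bi in seq_len(nb)) {
      idx <- band_idx[[bi]]
      cs <- colSums(cur[idx, , drop = FALSE])
      ts <- colSums(tot[idx, , drop = FALSE])
      prev_arr[bi, 1:2, k] <- ifelse(ts == 0, NA, cs / ts)
      prev_arr[bi, 3, k] <- if (sum(ts) == 0) NA else sum(cs) / sum(ts)
    }

    m <- if (!is.null(mult)) {
      lapply(mult[[as.character(t)]], function(v)
        matrix(v, length(AGES), length(SEXES)))
    } else list()
    st2 <- step_states(st, scenario$rates, m)
    if (!is.null(nvp) && t %in% nvp$years) {
      st2 <- apply_adjustment(st2, nvp_alpha, scenario$rates$a_init)
    }

    total_rate <- resolve_year_input(scenario$death_rate, t)
    d_status <- status_death_rates(st2, total_rate, scenario$rr)
    ex <- excess_deaths(st2, d_status)
    sads[k, ] <- colSums(ex$current + ex$former)

    if (t < end_year) {
      st <- step_state_demography(
        st2, d_status,
        migration = resolve_year_input(scenario$migration, t),
        births = resolve_births(scenario$births, t)
      )
    } else st <- st2
  }

  sex_lab <- c(SEXES, "both")
  prevalence <- data.frame(
    year = rep(years, each = nb * 3),
    sex = rep(rep(sex_lab, each = nb), times = length(years)),
    band = rep(bands, times = 3 * length(years)),
    prevalence = c(prev_arr),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(
    prevalence = prevalence,
    sads = data.frame(year = rep(years, times = length(SEXES)),
                      sex = rep(SEXES, each = length(years)),
                      sads = c(sads), row.names = NULL,
                      stringsAsFactors = FALSE),
    final_state = st,
    states = states,
    years = years
  ), class = "smokesim_run")
}

#' Extract a prevalence series from a run
#'
#' @param run A `smokesim_run` from [run_model()].
#' @param sex,band Filters.
#' @return Data frame `year`, `prevalence`, ordered by year.
#' @export
prevalence_series <- function(run, sex, band) {
  d <- run$prevalence
  d <- d[d$sex == sex & d$band == band, c("year", "prevalence")]
  d[order(d$year), , drop = FALSE]
}

#' @export
print.smokesim_run <- function(x, ...) {
  yr <- range(x$years)
  cat(sprintf("<smokesim_run> %d-%d, %d band-series, total SADs %.0f\n",
              yr[1], yr[2], length(unique(x$prevalence$band)),
              sum(x$sads$sads)))
  invisible(x)
}
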