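#' Years-quit bins for former smokers
#'
#' Former smokers are tracked by duration since quitting in six contiguous
#' bins.  Bin widths drive both annual bin ageing (a fraction `1/width`
#' advances to the next bin each year) and the decay of relapse rates and
#' relative risks with time quit.
#'
#' @return Data frame with columns `bin`, `label`, `width` (`Inf` for the
#'   terminal bin).
#' @export
years_quit_bins <- function() {
  data.frame(
    bin = 1:6,
    label = c("<1", "1-2", "3-5", "6-10", "11-15", "16+"),
    width = c(1, 2, 3, 5, 5, Inf),
    stringsAsFactors = FALSE
  )
}

STATUS <- c("never", "current", paste0("former", 1:6))
N_BINS <- 6L

#' Population state by age, sex and smoking status
#'
#' @param year Calendar year of the snapshot.
#' @param counts Numeric array `[age 0:100, sex, status]` with status
#'   `never`, `current`, `former1` ... `former6` (years-quit bins of
#'   [years_quit_bins()]).
#' @return Object of class `population_state`.
#' @export
population_state <- function(year, counts) {
  stop_if_not_scalar_year(year)
  counts <- as_state_array(counts)
  if (any(counts < -1e-9)) stop("counts must be >= 0")
  counts[counts < 0] <- 0
  ## below the minimum smoking age everyone is a never smoker
  young <- AGES < MIN_SMOKING_AGE
  if (any(counts[young, , setdiff(STATUS, "never")] > 1e-9)) {
    stop(sprintf("ages below %d must be never smokers", MIN_SMOKING_AGE))
  }
  structure(list(year = year, counts = counts), class = "population_state")
}

as_state_array <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L ||
      !all(dim(x) == c(length(AGES), length(SEXES), length(STATUS)))) {
    stop(sprintf("counts must be a %d x %d x %d array (age, sex, status)",
                 length(AGES), length(SEXES), length(STATUS)), call. = FALSE)
  }
  dimnames(x) <- list(age = AGES, sex = SEXES, status = STATUS)
  x
}

#' Total persons by age and sex
#' @param state A [population_state()].
#' @return `[age, sex]` matrix.
#' @export
state_totals <- function(state) {
  rowSums(state$counts, dims = 2)
}

#' Current-smoking prevalence within an age band
#'
#' @param state A [population_state()].
#' @param band Age band label (see [age_band_registry()]).
#' @param sex `"male"`, `"female"`, or `"both"`.
#' @return Fraction of the band population currently smoking.
#' @export
band_prevalence <- function(state, band, sex = "both") {
  ages <- as.character(band_ages(band))
  s <- if (identical(sex, "both")) SEXES else match.arg(sex, SEXES)
  num <- sum(state$counts[ages, s, "current"])
  den <- sum(state$counts[ages, s, ])
  if (den == 0) return(NA_real_)
  num / den
}

#' Transition rates for the smoking-state Markov process
#'
#' Net initiation applies through the last initiation age (`a_init`, male
#' 20 / female 21 by default); cessation applies above it; relapse applies
#' to former smokers by years-quit bin.
#'
#' @param initiation Matrix `[age, sex]` of net initiation probabilities
#'   (used only at ages `<= a_init` for each sex).
#' @param cessation Matrix `[age, sex]` of annual quit probabilities (used
#'   only above `a_init`).
#' @param relapse Either a length-6 vector of annual relapse probabilities
#'   by years-quit bin (recycled over age and sex) or an array
#'   `[age, sex, bin]`.
#' @param a_init Named vector `c(male=, female=)` of last initiation ages.
#' @return Object of class `transition_rates`.
#' @export
transition_rates <- function(initiation, cessation,
                             relapse = default_relapse_rates(),
                             a_init = c(male = 20, female = 21)) {
  initiation <- as_age_sex_matrix(initiation, "initiation")
  cessation <- as_age_sex_matrix(cessation, "cessation")
  if (is.null(dim(relapse))) {
    stopifnot(length(relapse) == N_BINS)
    relapse <- aperm(array(relapse, c(N_BINS, length(AGES), length(SEXES))),
                     c(2, 3, 1))
  }
  dimnames(relapse) <- list(age = AGES, sex = SEXES,
                            bin = years_quit_bins()$label)
  for (nm in c("initiation", "cessation")) {
    v <- get(nm)
    if (any(v < 0 | v > 1)) stop(nm, " probabilities must lie in [0, 1]")
  }
  if (any(relapse < 0 | relapse > 1)) stop("relapse must lie in [0, 1]")
  a_init <- a_init[SEXES]
  structure(list(initiation = initiation, cessation = cessation,
                 relapse = relapse, a_init = a_init),
            class = "transition_rates")
}

#' Default annual relapse rates by years-quit bin
#'
#' Relapse declines steeply with time quit; the shipped default falls from
#' 10%/year in the first year off cigarettes to 0.5%/year after 16+ years.
#' These are replaceable inputs: any study-specific table can be passed to
#' [transition_rates()].
#'
#' @return Length-6 numeric vector, one rate per bin of [years_quit_bins()].
#' @export
default_relapse_rates <- function() {
  c(0.10, 0.06, 0.03, 0.015, 0.008, 0.005)
}

#' Derive net initiation rates from a prevalence profile
#'
#' Net initiation at age `a` is the age-on-age increase in current-smoking
#' prevalence relative to never-smoking prevalence at the previous age,
#' floored at zero.  Rates are defined only through the last initiation
#' age.
#'
#' @param prevalence Numeric vector of current-smoking prevalence by age
#'   (consecutive single-year ages).
#' @param never_prevalence Never-smoking prevalence at the same ages.
#' @param ages Integer ages matching the vectors.
#' @param a_init Last initiation age; rates beyond it are set to 0.
#' @return Named vector of initiation probabilities by age (first age NA:
#'   no previous age to difference against).
#' @export
derive_net_initiation <- function(prevalence, never_prevalence, ages,
                                  a_init = max(ages)) {
  stopifnot(length(prevalence) == length(ages),
            length(never_prevalence) == length(ages))
  if (any(diff(ages) != 1L)) stop("ages must be consecutive")
  if (any(prevalence < 0 | prevalence > 1) ||
      any(never_prevalence < 0 | never_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(ages))
  names(out) <- ages
  for (i in seq_along(ages)[-1]) {
    if (ages[i] > a_init) { out[i] <- 0; next }
    if (never_prevalence[i - 1] == 0) {
      stop(sprintf(
        "never-smoking prevalence is 0 at age %d; initiation undefined",
        ages[i - 1]), call. = FALSE)
    }
    out[i] <- max(0, (prevalence[i] - prevalence[i - 1]) /
                    never_prevalence[i - 1])
  }
  out
}

#' Derive an annual cessation rate
#'
#' The quit rate is the share of the population that quit within the last
#' year relative to smoking prevalence one year earlier, clamped to
#' `[0, 1]`.
#'
#' @param former_lt1yr Prevalence of former smokers quit `<` 1 year.
#' @param current_prev_year Current-smoking prevalence in the previous
#'   year; must be positive.
#' @return Annual cessation probability.
#' @export
derive_cessation <- function(former_lt1yr, current_prev_year) {
  if (any(current_prev_year <= 0)) {
    stop("previous-year smoking prevalence must be > 0", call. = FALSE)
  }
  clamp_prob(former_lt1yr / current_prev_year, "cessation rate")
}

## expand scalar-or-vector policy multipliers to an [age, sex] matrix
as_multiplier_matrix <- function(m) {
  if (is.null(m)) m <- 1
  if (length(m) == 1L) {
    m <- matrix(m, length(AGES), length(SEXES))
  } else if (is.null(dim(m)) && length(m) == length(AGES)) {
    m <- matrix(m, length(AGES), length(SEXES))
  }
  as_age_sex_matrix(m, "policy multiplier")
}

#' One year of smoking-state transitions
#'
#' Applies, in fixed order: the first-year prevalence multiplier (mass
#' displaced from current smokers goes to never smokers at initiation ages
#' and to the `<1` year former bin above them), cessation, net initiation,
#' relapse, then years-quit bin ageing.  Cessation and relapse flows are
#' computed from start-of-year stocks; fresh quitters enter the `<1` bin
#' after bin ageing so they spend a full year there.  Mass is conserved
#' within every age/sex cell (mortality is applied separately).
#'
#' @param state A [population_state()].
#' @param rates A [transition_rates()] object.
#' @param multipliers List with elements `prevalence`, `initiation`,
#'   `cessation`, each a scalar or `[age, sex]` matrix (default all 1).
#' @return A new `population_state` for the same year, post-transition.
#' @export
step_states <- function(state, rates, multipliers = list()) {
  stopifnot(inherits(state, "population_state"),
            inherits(rates, "transition_rates"))
  m_prev <- as_multiplier_matrix(multipliers$prevalence)
  m_init <- as_multiplier_matrix(multipliers$initiation)
  m_cess <- as_multiplier_matrix(multipliers$cessation)

  x <- state$counts
  bins <- years_quit_bins()
  init_ages <- outer(AGES, rates$a_init, `<=`)   # [age, sex] logical
  adult_ages <- !init_ages

  ## --- first-year prevalence effect (policy level changes this year) ---
  shock_quit <- matrix(0, length(AGES), length(SEXES))
  if (any(m_prev != 1)) {
    cur <- x[, , "current"]
    newcur <- cur * pmin(m_prev, 1)
    displaced <- cur - newcur
    ## multipliers > 1 (tax cuts) pull mass back into smoking, capped at
    ## what the source state holds
    gain <- cur * (pmax(m_prev, 1) - 1)
    x[, , "current"] <- newcur
    x[, , "never"] <- x[, , "never"] + displaced * init_ages
    shock_quit <- displaced * adult_ages
    if (any(gain > 0)) {
      src_n <- pmin(gain * init_ages, x[, , "never"])
      src_f <- pmin(gain * adult_ages, x[, , "former1"])
      x[, , "never"] <- x[, , "never"] - src_n
      x[, , "former1"] <- x[, , "former1"] - src_f
      x[, , "current"] <- x[, , "current"] + src_n + src_f
    }
  }

  ## --- flows from post-shock, start-of-year stocks ---
  q <- clamp_prob(rates$cessation * m_cess, "cessation probability")
  q[init_ages] <- 0
  quit_flow <- x[, , "current"] * q

  i <- clamp_prob(rates$initiation * m_init, "initiation probability")
  i[adult_ages] <- 0
  i[AGES < MIN_SMOKING_AGE, ] <- 0
  init_flow <- x[, , "never"] * i

  former <- x[, , paste0("former", 1:6), drop = FALSE]
  rel_flow <- former * rates$relapse          # [age, sex, bin]
  former <- former - rel_flow

  ## --- apply flows ---
  x[, , "never"] <- x[, , "never"] - init_flow
  x[, , "current"] <- x[, , "current"] + init_flow - quit_flow +
    rowSums(rel_flow, dims = 2)

  ## --- years-quit bin ageing: fraction 1/width advances each year ---
  out_frac <- 1 / bins$width                  # terminal bin: 0
  moved <- sweep(former, 3, out_frac, `*`)
  former <- former - moved
  for (b in 1:(N_BINS - 1L)) {
    former[, , b + 1L] <- former[, , b + 1L] + moved[, , b]
  }
  former[, , 1L] <- former[, , 1L] + quit_flow + shock_quit
  x[, , paste0("former", 1:6)] <- former

  population_state(state$year, x)
}
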