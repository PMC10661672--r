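#' Policy effect-size registry
#'
#' Effect sizes for the tobacco-control policy set, in the printed
#' convention: `pes_prevalence` and `pes_initiation` are signed fractions
#' (negative = smoking-reducing) applied as `(1 + PES)`; `pes_cessation`
#' is the fractional increase in the quit rate (positive), applied as a
#' `(1 + PES)` multiplier on cessation.  `age_lo`/`age_hi` restrict
#' age-banded policies (youth access); `NA` means all ages.  Cigarette
#' taxes are not listed here: their effects derive from price changes via
#' [tax_elasticities()] and [tax_effect()].
#'
#' The four cessation-treatment components do not compound exactly to the
#' combined full-implementation row; the combined row is authoritative and
#' is used whenever all four components are fully in place.
#'
#' @return Data frame with columns `policy`, `level`, `pes_prevalence`,
#'   `pes_initiation`, `pes_cessation`, `age_lo`, `age_hi`,
#'   `enforcement_scaled`.
#' @export
policy_registry <- function() {
  r <- function(policy, level, p, i, c, lo = NA, hi = NA, enf = FALSE) {
    data.frame(policy = policy, level = level, pes_prevalence = p,
               pes_initiation = i, pes_cessation = c,
               age_lo = lo, age_hi = hi, enforcement_scaled = enf,
               stringsAsFactors = FALSE)
  }
  rbind(
    r("smokefree_worksite",   "full", -0.06, -0.06, 0.06, enf = TRUE),
    r("smokefree_restaurant", "full", -0.02, -0.02, 0.02, enf = TRUE),
    r("smokefree_pubs_bars",  "full", -0.01, -0.01, 0.01, enf = TRUE),
    r("smokefree_other",      "full", -0.01, -0.01, 0.01, enf = TRUE),
    r("marketing", "complete", -0.05, -0.08, 0.04, enf = TRUE),
    r("marketing", "moderate", -0.03, -0.04, 0.02, enf = TRUE),
    r("marketing", "minimal",  -0.01, -0.01, 0.00, enf = TRUE),
    r("pos_display", "full", 0.00, -0.12, 0.10),
    r("health_warnings", "high",     -0.04, -0.06, 0.10),
    r("health_warnings", "moderate", -0.02, -0.02, 0.04),
    r("health_warnings", "low",      -0.01, -0.01, 0.02),
    r("plain_packaging", "full", -0.02, -0.02, 0.02),
    r("media_campaign", "high",     -0.065,  -0.065,  0.065),
    r("media_campaign", "moderate", -0.0325, -0.0325, 0.0325),
    r("media_campaign", "low",      -0.0163, -0.0163, 0.0163),
    r("cessation_pharmacotherapy", "full", -0.0100, 0, 0.040),
    r("cessation_coverage",        "full", -0.0225, 0, 0.080),
    r("cessation_quitline",        "full", -0.0100, 0, 0.060),
    r("cessation_brief_advice",    "full", -0.0100, 0, 0.060),
    r("cessation_combined",        "full", -0.0568, 0, 0.294),
    r("youth_access", "strong",   -0.16, -0.16, 0, lo = 16, hi = 17),
    r("youth_access", "strong",   -0.24, -0.24, 0, lo = 10, hi = 15),
    r("youth_access", "moderate", -0.08, -0.08, 0, lo = 16, hi = 17),
    r("youth_access", "moderate", -0.12, -0.12, 0, lo = 10, hi = 15),
    r("youth_access", "low",      -0.02, -0.02, 0, lo = 16, hi = 17),
    r("youth_access", "low",      -0.03, -0.03, 0, lo = 10, hi = 15),
    r("menthol_ban", "full", -0.005, -0.02, 0)
  )
}

#' Prevalence elasticities of cigarette demand by age band
#'
#' Used to convert relative price changes into policy effect sizes:
#' `PES = elasticity * %change in price`.
#'
#' @return Data frame with columns `band`, `elasticity`.
#' @export
tax_elasticities <- function() {
  data.frame(band = c("15-20", "21-34", "35-64", "65+"),
             elasticity = c(-0.6, -0.2, -0.1, -0.2),
             stringsAsFactors = FALSE)
}

#' Tax effect size from a price change
#'
#' @param p_t,p_prev Real (inflation-adjusted) cigarette prices; must be
#'   positive.
#' @param elasticity Prevalence elasticity (<= 0).
#' @return Signed effect size `elasticity * (p_t - p_prev) / p_prev`.
#' @export
tax_effect <- function(p_t, p_prev, elasticity) {
  if (any(c(p_t, p_prev) <= 0)) stop("prices must be positive")
  elasticity * (p_t - p_prev) / p_prev
}

#' Scale an effect size for coverage, enforcement and venue allowances
#'
#' The full effect requires complete coverage and fully enforced,
#' publicized laws; with no enforcement or publicity the effect halves,
#' scaling linearly in between: `PES * w * (0.5 + 0.5 * E / 10)`.
#' Worksite bans that still allow smoking in ventilated areas keep 2/3 of
#' the effect; allowing common areas keeps 1/3.
#'
#' @param pes Base effect size (any channel).
#' @param coverage Share of the population covered, in `[0, 1]`.
#' @param enforcement Enforcement score on a 0-10 scale.
#' @param allowance `"none"`, `"ventilated"`, or `"common"`.
#' @return Scaled effect size.
#' @export
scale_effect <- function(pes, coverage = 1, enforcement = 10,
                         allowance = c("none", "ventilated", "common")) {
  allowance <- match.arg(allowance)
  if (any(coverage < 0 | coverage > 1)) stop("coverage must be in [0, 1]")
  if (any(enforcement < 0 | enforcement > 10)) {
    stop("enforcement must be in [0, 10]")
  }
  fac <- switch(allowance, none = 1, ventilated = 2 / 3, common = 1 / 3)
  pes * coverage * (0.5 + 0.5 * enforcement / 10) * fac
}

#' Mix policy levels by share
#'
#' When a policy sits between levels (e.g. warnings 50% moderate / 50%
#' strong), the effect triple is the share-weighted combination of the
#' level triples.
#'
#' @param shares Named numeric vector `level -> share`, summing to 1.
#' @param policy Policy id in [policy_registry()].
#' @param registry Registry data frame (default [policy_registry()]).
#' @param ages Optional ages for age-banded policies; rows not covering
#'   them are dropped.
#' @return Named vector `c(prevalence=, initiation=, cessation=)`.
#' @export
mix_levels <- function(shares, policy, registry = policy_registry(),
                       ages = NULL) {
  if (abs(sum(shares) - 1) > 1e-9) stop("level shares must sum to 1")
  rows <- registry[registry$policy == policy, ]
  if (nrow(rows) == 0) stop("unknown policy: ", policy)
  out <- c(prevalence = 0, initiation = 0, cessation = 0)
  for (lv in names(shares)) {
    sel <- rows[rows$level == lv, ]
    if (nrow(sel) == 0) stop("unknown level '", lv, "' for ", policy)
    if (!is.null(ages) && any(!is.na(sel$age_lo))) {
      keep <- vapply(seq_len(nrow(sel)), function(j) {
        any(ages >= sel$age_lo[j] & ages <= sel$age_hi[j])
      }, logical(1))
      sel <- sel[keep, , drop = FALSE]
      if (nrow(sel) == 0) next
    }
    if (nrow(sel) > 1) {
      stop("level '", lv, "' for ", policy,
           " is age-banded; pass `ages` selecting a single band")
    }
    out <- out + shares[[lv]] * c(prevalence = sel$pes_prevalence,
                                  initiation = sel$pes_initiation,
                                  cessation = sel$pes_cessation)
  }
  out
}

#' Combine concurrent policy effect sizes into one multiplier
#'
#' Policies combine multiplicatively, `prod(1 + PES)`, so simultaneous
#' policies have independent relative effects.  For the cessation channel
#' the input is expected in the signed smoking-reducing convention
#' (`PES <= 0` increases quitting) and the multiplier is `prod(1 - PES)`.
#'
#' @param pes Numeric vector of signed effect sizes (empty gives 1).
#' @param channel `"prevalence"`, `"initiation"`, or `"cessation"`.
#' @return Single multiplier.
#' @export
combine_policies <- function(pes,
                             channel = c("prevalence", "initiation",
                                         "cessation")) {
  channel <- match.arg(channel)
  if (length(pes) == 0) return(1)
  f <- if (channel == "cessation") 1 - pes else 1 + pes
  if (any(f <= 0)) {
    stop("combined effect size of -100% or beyond is not meaningful")
  }
  prod(f)
}

#' Youth-access effect sizes by enforcement level
#'
#' Retail compliance enforcement reduces initiation and prevalence among
#' minors, more strongly at ages 10-15 than 16-17.
#'
#' @param level `"low"`, `"moderate"`, or `"strong"`.
#' @return Data frame with columns `band`, `pes_initiation`,
#'   `pes_prevalence`.
#' @export
youth_access_effect <- function(level) {
  if (!level %in% c("low", "moderate", "strong")) {
    stop("youth-access level must be low, moderate or strong")
  }
  reg <- policy_registry()
  rows <- reg[reg$policy == "youth_access" & reg$level == level, ]
  data.frame(band = paste0(rows$age_lo, "-", rows$age_hi),
             pes_initiation = rows$pes_initiation,
             pes_prevalence = rows$pes_prevalence,
             stringsAsFactors = FALSE)
}

#' Menthol-ban effect sizes weighted by covered population
#'
#' A ban reduces prevalence 0.5% in its first covered year and initiation
#' 2% on an ongoing basis, weighted linearly by the share of the
#' population living in covered provinces.
#'
#' @param share Covered population share in `[0, 1]`.
#' @return Named vector `c(prevalence=, initiation=)`.
#' @export
menthol_effect <- function(share) {
  if (any(share < 0 | share > 1)) stop("share must be in [0, 1]")
  c(prevalence = -0.005 * share, initiation = -0.02 * share)
}

#' First-year versus ongoing application of a policy change
#'
#' A level change produces a one-off prevalence reduction in the change
#' year (current smokers move to the `<1` former bin above initiation
#' ages, or back to never smokers at initiation ages), while the
#' initiation and cessation channels remain active every year the policy
#' stays at its level.
#'
#' @param change_year Year of the level change (`NA` if the policy never
#'   changes).
#' @param query_year Year being simulated.
#' @return Character vector of active channels at `query_year`.
#' @export
active_channels <- function(change_year, query_year) {
  if (is.na(change_year) || query_year < change_year) return(character(0))
  if (query_year == change_year) {
    c("prevalence", "initiation", "cessation")
  } else {
    c("initiation", "cessation")
  }
}
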