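#' Relative reduction in prevalence over a period
#'
#' `(p_start - p_end) / p_start`; negative when prevalence rises.
#'
#' @param p_start Starting prevalence (must be positive).
#' @param p_end Ending prevalence.
#' @return Fractional relative reduction.
#' @export
relative_reduction <- function(p_start, p_end) {
  if (any(p_start <= 0)) stop("starting prevalence must be positive")
  (p_start - p_end) / p_start
}

#' Annualize a relative reduction
#'
#' Spreads a period reduction evenly over its years on the relative
#' scale: `1 - (1 - reduction)^(1/n)`.  A 25% reduction over 8 years is a
#' 3.5% average annual reduction.
#'
#' @param rel_reduction Fractional reduction over the period (`< 1`).
#' @param n_years Period length in years (`>= 1`).
#' @return Average annual relative reduction.
#' @export
annualize <- function(rel_reduction, n_years) {
  if (any(rel_reduction >= 1)) stop("relative reduction must be < 1")
  if (any(n_years < 1)) stop("n_years must be >= 1")
  1 - (1 - rel_reduction)^(1 / n_years)
}

#' Vaping-implied annual prevalence adjustment
#'
#' The per-year relative smoking reduction attributable to nicotine
#' vaping products, inferred indirectly as the difference between the
#' annualized survey reduction and the annualized no-vaping counterfactual
#' reduction:
#' `alpha = (1 - r_model)^(1/n) - (1 - r_survey)^(1/n)`.
#' Positive when the survey declined faster than the counterfactual.
#'
#' @param rel_model Counterfactual relative reduction over the window.
#' @param rel_survey Survey relative reduction over the same window.
#' @param n_years Window length in years.
#' @return Annual adjustment `alpha` (fraction per year).
#' @export
nvp_annual_adjustment <- function(rel_model, rel_survey, n_years) {
  if (any(rel_model >= 1) || any(rel_survey >= 1)) {
    stop("relative reductions must be < 1")
  }
  (1 - rel_model)^(1 / n_years) - (1 - rel_survey)^(1 / n_years)
}

#' Reduction bounds from the endpoint confidence interval
#'
#' Confidence bounds on a period reduction are driven by the endpoint
#' survey estimate's 95% CI: the upper reduction bound comes from the
#' lower prevalence bound and vice versa, so that
#' `low <= point <= high` whenever the endpoint estimate lies inside its
#' interval.
#'
#' @param p_start Starting prevalence (positive point estimate).
#' @param ci_low_end,ci_high_end Endpoint prevalence 95% CI bounds.
#' @return Named vector `c(low=, high=)` of reduction bounds.
#' @export
ci_bounds_on_reduction <- function(p_start, ci_low_end, ci_high_end) {
  if (any(p_start <= 0)) stop("starting prevalence must be positive")
  if (any(ci_low_end > ci_high_end)) stop("ci_low_end must be <= ci_high_end")
  c(low = (p_start - ci_high_end) / p_start,
    high = (p_start - ci_low_end) / p_start)
}

#' Analysis periods for a survey series
#'
#' The full vaping-era window plus a pre/post split at the year retail
#' vaping sales were legalized.  The two survey conventions pivot at
#' different years: the monitoring-survey series ("ctums") compares
#' 2012-2017 with 2017-2020, the community-health series ("cchs")
#' 2012-2018 with 2018-2020.
#'
#' @param convention `"ctums"` or `"cchs"`.
#' @param start,end Full-window years (defaults 2012 and 2020).
#' @return Data frame `period`, `start`, `end`, `n` (years in period).
#' @export
period_split <- function(convention = c("ctums", "cchs"),
                         start = 2012, end = 2020) {
  convention <- match.arg(convention)
  mid <- if (convention == "ctums") 2017 else 2018
  if (mid <= start || mid >= end) {
    return(data.frame(period = "full", start = start, end = end,
                      n = end - start, stringsAsFactors = FALSE))
  }
  data.frame(
    period = c("full", "pre", "post"),
    start = c(start, start, mid),
    end = c(end, mid, end),
    n = c(end - start, mid - start, end - mid),
    stringsAsFactors = FALSE
  )
}

## annual gain + CI for one (sex, band, period): survey and model
## prevalence at the period endpoints; CI bounds propagate the endpoint
## survey CI through the same arithmetic
gain_row <- function(sp_start, sp_end, sp_end_lo, sp_end_hi,
                     mp_start, mp_end, n) {
  r_s <- relative_reduction(sp_start, sp_end)
  r_m <- relative_reduction(mp_start, mp_end)
  a <- nvp_annual_adjustment(r_m, r_s, n)
  if (is.na(sp_end_lo) || is.na(sp_end_hi)) {
    a_lo <- a_hi <- NA_real_
    r_lo <- r_hi <- NA_real_
  } else {
    b <- ci_bounds_on_reduction(sp_start, sp_end_lo, sp_end_hi)
    r_lo <- b[["low"]]; r_hi <- b[["high"]]
    a_lo <- nvp_annual_adjustment(r_m, r_lo, n)
    a_hi <- nvp_annual_adjustment(r_m, r_hi, n)
  }
  data.frame(rel_model = r_m, rel_survey = r_s,
             rel_survey_lo = r_lo, rel_survey_hi = r_hi,
             diff = r_s - r_m, annual_gain = a,
             annual_gain_lo = a_lo, annual_gain_hi = a_hi)
}

#' Vaping-implied gains from matched model and survey prevalence points
#'
#' The arithmetic core of the indirect method, applied band by band to a
#' tidy table of matched counterfactual-model and survey prevalence
#' points: per (survey, sex, band, period) it computes the relative
#' reductions, their difference, and the annualized vaping-implied gain
#' with CI bounds propagated from the endpoint survey interval.
#'
#' @param points Data frame with columns `survey` (`"ctums"`/`"cchs"`),
#'   `sex`, `band`, `source` (`"model"` or `"survey"`), `year`,
#'   `prevalence`, and (survey rows) `ci_low`, `ci_high`; prevalences as
#'   fractions.
#' @return Data frame with one row per (survey, sex, band, period) and
#'   the derived columns of [gain_row()].
#' @export
nvp_gain_table <- function(points) {
  out <- list()
  for (sv in unique(points$survey)) {
    periods <- period_split(sv)
    d_sv <- points[points$survey == sv, ]
    for (sx in unique(d_sv$sex)) {
      for (bd in unique(d_sv$band[d_sv$sex == sx])) {
        d <- d_sv[d_sv$sex == sx & d_sv$band == bd, ]
        pick <- function(src, yr, col = "prevalence") {
          v <- d[[col]][d$source == src & d$year == yr]
          if (length(v) == 0) NA_real_ else v[1]
        }
        for (j in seq_len(nrow(periods))) {
          y0 <- periods$start[j]; y1 <- periods$end[j]
          row <- gain_row(
            sp_start = pick("survey", y0), sp_end = pick("survey", y1),
            sp_end_lo = pick("survey", y1, "ci_low"),
            sp_end_hi = pick("survey", y1, "ci_high"),
            mp_start = pick("model", y0), mp_end = pick("model", y1),
            n = periods$n[j])
          out[[length(out) + 1L]] <- cbind(
            data.frame(survey = sv, sex = sx, band = bd,
                       period = periods$period[j],
                       start = y0, end = y1, n = periods$n[j],
                       stringsAsFactors = FALSE),
            row)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Full vaping-impact report for a scenario
#'
#' Runs the indirect method end to end: compares a counterfactual run to
#' a survey series over the vaping window, annualizes the gap into
#' per-band adjustments, reruns the engine with the adjustment applied,
#' and differences smoking-attributable deaths to the horizon (the
#' adjustment is held at zero after the last survey year).
#'
#' @param scenario The counterfactual [smoking_scenario()] (calibrated,
#'   no vaping influence).
#' @param survey Data frame `sex`, `band`, `year`, `prevalence`,
#'   `ci_low`, `ci_high` (fractions).
#' @param window `c(start, end)` of the vaping era (default 2012-2020).
#' @param convention Survey period convention for [period_split()].
#' @param horizon_year Final year for the deaths-averted difference.
#' @param bands Bands to adjust (default: the survey's bands).
#' @return List of class `nvp_impact_report`: `gains` (the
#'   [nvp_gain_table()] augmented with periods), `alpha` (per sex/band
#'   full-window adjustment), `counterfactual`, `adjusted` (runs),
#'   `sads_averted` (total), `sads_averted_by_sex`.
#' @export
build_report <- function(scenario, survey, window = c(2012, 2020),
                         convention = c("ctums", "cchs"),
                         horizon_year = scenario$end_year,
                         bands = NULL) {
  convention <- match.arg(convention)
  bands <- bands %||% unique(survey$band)
  cf <- run_model(scenario, end_year = horizon_year, bands = bands)

  ## matched points table over the window endpoints
  periods <- period_split(convention, window[1], window[2])
  yrs <- sort(unique(c(periods$start, periods$end)))
  pts <- list()
  for (sx in unique(survey$sex)) for (bd in bands) {
    mod <- prevalence_series(cf, sx, bd)
    sv <- survey[survey$sex == sx & survey$band == bd, ]
    if (nrow(sv) == 0) next
    for (y in yrs) {
      pm <- mod$prevalence[mod$year == y]
      ps <- sv[sv$year == y, ]
      if (length(pm) == 0 || nrow(ps) == 0) next
      pts[[length(pts) + 1L]] <- data.frame(
        survey = convention, sex = sx, band = bd, source = "model",
        year = y, prevalence = pm, ci_low = NA_real_, ci_high = NA_real_,
        stringsAsFactors = FALSE)
      pts[[length(pts) + 1L]] <- data.frame(
        survey = convention, sex = sx, band = bd, source = "survey",
        year = y, prevalence = ps$prevalence[1], ci_low = ps$ci_low[1],
        ci_high = ps$ci_high[1], stringsAsFactors = FALSE)
    }
  }
  pts <- do.call(rbind, pts)
  gains <- nvp_gain_table(pts)

  full <- gains[gains$period == "full", ]
  alpha <- data.frame(sex = full$sex, band = full$band,
                      alpha = full$annual_gain, stringsAsFactors = FALSE)

  adj_scenario <- scenario
  adj_scenario$nvp_adjustment <- list(alpha = alpha,
                                      years = window[1]:(window[2] - 1L))
  adj <- run_model(adj_scenario, end_year = horizon_year, bands = bands)

  structure(list(
    gains = gains, alpha = alpha, counterfactual = cf, adjusted = adj,
    sads_averted = sads_averted(cf$sads, adj$sads,
                                years = window[1]:horizon_year),
    sads_averted_by_sex = sads_averted(cf$sads, adj$sads,
                                       years = window[1]:horizon_year,
                                       by = "sex")
  ), class = "nvp_impact_report")
}

#' @export
print.nvp_impact_report <- function(x, ...) {
  cat("<nvp_impact_report>\n")
  full <- x$gains[x$gains$period == "full", ]
  cat(sprintf("  %d band series; mean annual gain %.2f%%\n",
              nrow(full), 100 * mean(full$annual_gain, na.rm = TRUE)))
  cat(sprintf("  smoking-attributable deaths averted: %.0f\n",
              x$sads_averted))
  invisible(x)
}
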