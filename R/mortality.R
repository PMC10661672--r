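#' Default relative risks of death by smoking status
#'
#' Current-smoker all-cause relative risk rises with age from 1 at young
#' ages toward roughly 3 at older ages; former-smoker risk decays toward 1
#' with years quit.  These are documented defaults standing in for
#' study-specific risk tables and are fully replaceable: supply any array
#' of the same shape to the engine.
#'
#' @return Array `[age, sex, status]` of relative risks (never = 1).
#' @export
default_rr_table <- function() {
  rr <- array(1, c(length(AGES), length(SEXES), length(STATUS)),
              dimnames = list(age = AGES, sex = SEXES, status = STATUS))
  rr_cur <- 1 + 2 * clamp((AGES - 30) / 40, 0, 1)   # 1 below 30, 3 at 70+
  decay <- c(0.9, 0.7, 0.5, 0.3, 0.15, 0.05)        # by years-quit bin
  for (s in SEXES) {
    rr[, s, "current"] <- rr_cur
    for (b in 1:N_BINS) {
      rr[, s, paste0("former", b)] <- 1 + (rr_cur - 1) * decay[b]
    }
  }
  rr
}

#' Decompose an overall death rate into status-specific rates
#'
#' Given the total death probability for an age/sex cell, the smoking
#' status mix, and relative risks, solve for the never-smoker rate so that
#' the prevalence-weighted mean over statuses reproduces the total:
#' `D_never = total / sum(prev * RR)`, `D_status = RR * D_never`.
#'
#' @param total_rate Overall death probability in `[0, 1]`.
#' @param prevalence Named numeric vector of status shares summing to 1
#'   (names drawn from `never`, `current`, `former1`..`former6`).
#' @param rr Named numeric vector of relative risks for the same statuses
#'   (never = 1).
#' @return Named vector of death probabilities per status.
#' @export
decompose_death_rates <- function(total_rate, prevalence, rr) {
  if (total_rate < 0 || total_rate > 1) stop("total_rate must be in [0, 1]")
  if (abs(sum(prevalence) - 1) > 1e-6) {
    stop("prevalence shares must sum to 1")
  }
  rr <- rr[names(prevalence)]
  denom <- sum(prevalence * rr)
  if (denom <= 0) stop("degenerate prevalence/relative-risk mix")
  d_never <- total_rate / denom
  out <- d_never * rr
  names(out) <- names(prevalence)
  out
}

## status-specific death-rate array for a whole state: decompose the
## overall [age, sex] rate cell by cell using the cell's status mix
status_death_rates <- function(state, total_rate, rr) {
  counts <- state$counts
  tot <- rowSums(counts, dims = 2)
  share <- counts / ifelse(c(tot) == 0, 1, c(tot))  # recycled over status
  denom <- rowSums(share * rr, dims = 2)
  d_never <- total_rate / ifelse(denom == 0, 1, denom)
  sweep(rr, c(1, 2), d_never, `*`)
}

#' Smoking-attributable deaths for one state
#'
#' Excess deaths of current and former smokers relative to never smokers:
#' counts times the excess death rate (status rate minus never rate),
#' summed within status of origin.
#'
#' @param state A [population_state()].
#' @param rates Array `[age, sex, status]` of status-specific death
#'   probabilities (e.g. from decomposing overall mortality).
#' @return List with matrices `current` and `former` (`[age, sex]` excess
#'   deaths) and scalar `total`.
#' @export
excess_deaths <- function(state, rates) {
  counts <- state$counts
  ex_cur <- counts[, , "current"] *
    pmax(0, rates[, , "current"] - rates[, , "never"])
  ex_for <- matrix(0, length(AGES), length(SEXES),
                   dimnames = list(age = AGES, sex = SEXES))
  for (b in 1:N_BINS) {
    st <- paste0("former", b)
    ex_for <- ex_for + counts[, , st] *
      pmax(0, rates[, , st] - rates[, , "never"])
  }
  list(current = ex_cur, former = ex_for, total = sum(ex_cur) + sum(ex_for))
}

#' Smoking-attributable deaths averted between two scenarios
#'
#' @param ledger_counterfactual,ledger_adjusted Data frames with columns
#'   `year`, `sex`, `sads` (as produced by [run_model()]), covering the
#'   requested years on identical grids.
#' @param years Year range to sum over (default: all shared years).
#' @param by Optional grouping: `"total"` (default), `"sex"`, or `"year"`.
#' @return Deaths averted (counterfactual minus adjusted), as a scalar or
#'   a data frame when grouped.
#' @export
sads_averted <- function(ledger_counterfactual, ledger_adjusted,
                         years = NULL, by = c("total", "sex", "year")) {
  by <- match.arg(by)
  years <- years %||% intersect(ledger_counterfactual$year,
                                ledger_adjusted$year)
  cf <- ledger_counterfactual[ledger_counterfactual$year %in% years, ]
  ad <- ledger_adjusted[ledger_adjusted$year %in% years, ]
  key <- function(d) paste(d$year, d$sex)
  if (!identical(sort(key(cf)), sort(key(ad)))) {
    stop("ledgers do not cover identical year/sex grids", call. = FALSE)
  }
  ad <- ad[match(key(cf), key(ad)), ]
  diff <- cf$sads - ad$sads
  switch(by,
    total = sum(diff),
    sex = stats::aggregate(list(averted = diff), list(sex = cf$sex), sum),
    year = stats::aggregate(list(averted = diff), list(year = cf$year), sum)
  )
}
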