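#' Policy timeline
#'
#' A tidy table of policy change points.  Each row sets (part of) a
#' policy's level from `year` onward, until the next row for the same
#' policy.  Multiple rows for one policy/year carry `share`s that must sum
#' to 1 (mixed levels).  Taxes are encoded as yearly rows of the policy
#' `"tax"` with a `price` (real, inflation-adjusted); their effect comes
#' from price changes and [tax_elasticities()], not from the registry.
#'
#' @param df Data frame with columns `policy`, `year`, `level`; optional
#'   `share` (default 1), `coverage` (default 1), `enforcement`
#'   (default 10), `price` (taxes), `allowance` (worksite bans).
#' @return Validated timeline data frame of class `policy_timeline`.
#' @export
policy_timeline <- function(df) {
  need <- c("policy", "year", "level")
  if (!all(need %in% names(df))) {
    stop("timeline needs columns: ", paste(need, collapse = ", "))
  }
  df$share <- df$share %||% 1
  df$coverage <- df$coverage %||% 1
  df$enforcement <- df$enforcement %||% 10
  df$price <- df$price %||% NA_real_
  df$allowance <- df$allowance %||% "none"
  ok <- stats::aggregate(share ~ policy + year, df, sum)
  if (any(abs(ok$share - 1) > 1e-9)) {
    stop("level shares must sum to 1 within each policy/year")
  }
  class(df) <- c("policy_timeline", "data.frame")
  df
}

## rows describing `policy` as of year t (latest change year <= t), or NULL
timeline_rows_at <- function(timeline, policy, t) {
  rows <- timeline[timeline$policy == policy & timeline$year <= t, ]
  if (nrow(rows) == 0) return(NULL)
  rows[rows$year == max(rows$year), , drop = FALSE]
}

## effect triple by single-year age for one non-tax policy as of year t:
## matrix [age, channel]; zero rows where the policy does not apply
policy_triple_at <- function(timeline, policy, t, registry) {
  rows <- timeline_rows_at(timeline, policy, t)
  out <- matrix(0, length(AGES), 3,
                dimnames = list(age = AGES,
                                channel = c("prevalence", "initiation",
                                            "cessation")))
  if (is.null(rows)) return(out)
  reg <- registry[registry$policy == policy, ]
  banded <- any(!is.na(reg$age_lo))
  for (j in seq_len(nrow(rows))) {
    lv <- reg[reg$level == rows$level[j], , drop = FALSE]
    if (nrow(lv) == 0) stop("unknown level '", rows$level[j],
                            "' for policy ", policy)
    for (k in seq_len(nrow(lv))) {
      ages_k <- if (banded) {
        AGES >= lv$age_lo[k] & AGES <= lv$age_hi[k]
      } else rep(TRUE, length(AGES))
      enf <- if (lv$enforcement_scaled[k]) rows$enforcement[j] else 10
      triple <- c(lv$pes_prevalence[k], lv$pes_initiation[k],
                  lv$pes_cessation[k])
      triple <- scale_effect(triple, coverage = rows$coverage[j],
                             enforcement = enf,
                             allowance = rows$allowance[j])
      out[ages_k, ] <- out[ages_k, ] +
        rep(rows$share[j] * triple, each = sum(ages_k))
    }
  }
  out
}

## elasticity by single-year age (0 below 15: no direct tax response)
elasticity_by_age <- function(elasticities = tax_elasticities()) {
  e <- numeric(length(AGES))
  for (j in seq_len(nrow(elasticities))) {
    e[AGES %in% band_ages(elasticities$band[j])] <- elasticities$elasticity[j]
  }
  e
}

#' Yearly policy multipliers from a timeline
#'
#' Converts a [policy_timeline()] into per-year, per-age multipliers on
#' the three channels.  Prevalence multipliers capture only the
#' first-year effect of level changes, as the ratio
#' `(1 + PES_t) / (1 + PES_(t-1))` per policy (1 in years without a
#' change); initiation and cessation multipliers reflect the levels in
#' force each year.  Tax prevalence effects use year-over-year real price
#' changes; tax initiation/cessation effects persist while the real price
#' stays above its level in the timeline's first tax year.
#'
#' @param timeline A [policy_timeline()].
#' @param years Calendar years to cover.
#' @param registry Effect-size registry (default [policy_registry()]).
#' @param elasticities Tax elasticity table (default [tax_elasticities()]).
#' @return Named list (by year) of lists with elements `prevalence`,
#'   `initiation`, `cessation`, each a length-101 vector over ages.
#' @export
build_policy_multipliers <- function(timeline, years,
                                     registry = policy_registry(),
                                     elasticities = tax_elasticities()) {
  policies <- setdiff(unique(timeline$policy), "tax")
  has_tax <- "tax" %in% timeline$policy
  if (has_tax) {
    taxrows <- timeline[timeline$policy == "tax", ]
    taxrows <- taxrows[order(taxrows$year), ]
    if (any(taxrows$price <= 0, na.rm = TRUE) || anyNA(taxrows$price)) {
      stop("tax rows need positive prices")
    }
    price_at <- function(t) {
      i <- findInterval(t, taxrows$year)
      if (i == 0) NA_real_ else taxrows$price[i]
    }
    p_base <- taxrows$price[1]
    eps <- elasticity_by_age(elasticities)
  }

  out <- vector("list", length(years))
  names(out) <- years
  ## levels in force in the first year are pre-existing: no first-year
  ## prevalence shock at simulation start
  prev_triple <- lapply(policies, function(p) {
    policy_triple_at(timeline, p, years[1], registry)
  })
  names(prev_triple) <- policies

  for (t in years) {
    m_prev <- rep(1, length(AGES))
    m_init <- rep(1, length(AGES))
    m_cess <- rep(1, length(AGES))
    for (p in policies) {
      cur <- policy_triple_at(timeline, p, t, registry)
      m_prev <- m_prev * (1 + cur[, "prevalence"]) /
        (1 + prev_triple[[p]][, "prevalence"])
      m_init <- m_init * (1 + cur[, "initiation"])
      ## cessation stored as printed positive increase -> (1 + PES)
      m_cess <- m_cess * (1 + cur[, "cessation"])
      prev_triple[[p]] <- cur
    }
    if (has_tax) {
      p_t <- price_at(t); p_tm1 <- price_at(t - 1L)
      if (!is.na(p_t) && !is.na(p_tm1)) {
        m_prev <- m_prev * (1 + tax_effect(p_t, p_tm1, eps))
      }
      if (!is.na(p_t) && p_t > p_base) {
        pes_tax <- tax_effect(p_t, p_base, eps)   # negative when price up
        m_init <- m_init * (1 + pes_tax)
        m_cess <- m_cess * (1 - pes_tax)
      }
    }
    out[[as.character(t)]] <- list(prevalence = unname(m_prev),
                                   initiation = unname(m_init),
                                   cessation = unname(m_cess))
  }
  out
}
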