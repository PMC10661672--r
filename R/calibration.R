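#' Default calibration blocks
#'
#' One multiplicative factor per sex and channel (initiation, cessation),
#' applied over all smoking ages.  Finer blocks (age-band-specific) can be
#' supplied by adding rows with `age_lo`/`age_hi`.
#'
#' @return Data frame `sex`, `channel`, `age_lo`, `age_hi`.
#' @export
default_calibration_blocks <- function() {
  data.frame(
    sex = rep(SEXES, each = 2),
    channel = rep(c("initiation", "cessation"), 2),
    age_lo = 0, age_hi = MAX_AGE,
    stringsAsFactors = FALSE
  )
}

## apply block factors to a transition_rates object
scale_rates <- function(rates, blocks, factors) {
  stopifnot(length(factors) == nrow(blocks))
  init <- rates$initiation
  cess <- rates$cessation
  for (j in seq_len(nrow(blocks))) {
    rows <- AGES >= blocks$age_lo[j] & AGES <= blocks$age_hi[j]
    s <- blocks$sex[j]
    if (blocks$channel[j] == "initiation") {
      init[rows, s] <- clamp(init[rows, s] * factors[j], 0, 1)
    } else {
      cess[rows, s] <- clamp(cess[rows, s] * factors[j], 0, 1)
    }
  }
  transition_rates(init, cess, rates$relapse, rates$a_init)
}

## inverse-variance weights from survey CIs (uniform when absent)
survey_weights <- function(survey) {
  if (all(c("ci_low", "ci_high") %in% names(survey)) &&
      !all(is.na(survey$ci_low))) {
    sd <- (survey$ci_high - survey$ci_low) / (2 * stats::qnorm(0.975))
    w <- 1 / pmax(sd, 1e-4)^2
    w / mean(w)
  } else rep(1, nrow(survey))
}

#' Calibrate transition rates to a survey series
#'
#' Fits multiplicative block factors on initiation and cessation so the
#' modelled band prevalence tracks the survey over a pre-vaping window.
#' The loss is the CI-weighted squared relative error over all survey
#' cells in the window; optimization is derivative-free (Nelder-Mead on
#' log factors) with factors bounded to `[0.25, 4]`.
#'
#' @param scenario A [smoking_scenario()] whose rates are to be scaled.
#' @param survey Data frame `sex`, `band`, `year`, `prevalence` and
#'   optionally `ci_low`, `ci_high` (fractions), covering the window.
#' @param window `c(first, last)` calendar years of the calibration
#'   window.
#' @param blocks Adjustable blocks (default
#'   [default_calibration_blocks()]).
#' @param bounds Factor bounds (default `c(0.25, 4)`).
#' @param control Passed to [stats::optim()] (default `maxit = 400`).
#' @return List of class `smokesim_calibration`: `factors` (named by
#'   `sex:channel`), `scenario` (with calibrated rates), `loss`,
#'   `loss_at_unity`, `converged`, `report` (modelled vs survey window
#'   reductions per band).
#' @export
calibrate <- function(scenario, survey, window,
                      blocks = default_calibration_blocks(),
                      bounds = c(0.25, 4),
                      control = list(maxit = 400)) {
  stopifnot(inherits(scenario, "smoking_scenario"), nrow(blocks) >= 1)
  sv <- survey[survey$year >= window[1] & survey$year <= window[2], ]
  if (nrow(sv) == 0) stop("survey has no rows inside the window")
  sv$w <- survey_weights(sv)
  bands <- unique(sv$band)

  ## model output row order is deterministic; align survey cells once
  base_run <- run_model(scenario, end_year = window[2], bands = bands)
  key <- function(d) paste(d$year, d$sex, d$band)
  idx <- match(key(sv), key(base_run$prevalence))
  if (anyNA(idx)) stop("survey cells not covered by the model run")

  objective <- function(logf) {
    f <- clamp(exp(logf), bounds[1], bounds[2])
    pen <- sum((logf - log(f))^2)    # soft wall outside the bounds
    sc <- scenario
    sc$rates <- scale_rates(scenario$rates, blocks, f)
    run <- run_model(sc, end_year = window[2], bands = bands)
    pm <- run$prevalence$prevalence[idx]
    sum(sv$w * ((pm - sv$prevalence) / sv$prevalence)^2) + 100 * pen
  }

  loss_at_unity <- objective(rep(0, nrow(blocks)))
  opt <- stats::optim(rep(0, nrow(blocks)), objective,
                      method = "Nelder-Mead", control = control)
  factors <- clamp(exp(opt$par), bounds[1], bounds[2])
  names(factors) <- paste(blocks$sex, blocks$channel, sep = ":")
  ## never return a fit worse than no calibration
  if (opt$value > loss_at_unity) {
    factors[] <- 1
    opt$value <- loss_at_unity
  }

  sc <- scenario
  sc$rates <- scale_rates(scenario$rates, blocks, factors)
  run <- run_model(sc, end_year = window[2], bands = bands)
  report <- do.call(rbind, lapply(unique(sv$sex), function(sx) {
    do.call(rbind, lapply(bands, function(bd) {
      mod <- prevalence_series(run, sx, bd)
      s <- sv[sv$sex == sx & sv$band == bd, ]
      s <- s[order(s$year), ]
      if (nrow(s) < 2) return(NULL)
      y0 <- min(s$year); y1 <- max(s$year)
      m0 <- mod$prevalence[mod$year == y0]
      m1 <- mod$prevalence[mod$year == y1]
      data.frame(sex = sx, band = bd, start = y0, end = y1,
                 model_reduction = relative_reduction(m0, m1),
                 survey_reduction = relative_reduction(
                   s$prevalence[s$year == y0], s$prevalence[s$year == y1]),
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(factors = factors, scenario = sc, loss = opt$value,
                 loss_at_unity = loss_at_unity,
                 converged = opt$convergence == 0, report = report),
            class = "smokesim_calibration")
}

#' @export
print.smokesim_calibration <- function(x, ...) {
  cat("<smokesim_calibration>\n  factors:\n")
  print(round(x$factors, 3))
  cat(sprintf("  loss %.4g (unity %.4g), converged: %s\n",
              x$loss, x$loss_at_unity, x$converged))
  invisible(x)
}
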