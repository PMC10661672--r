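test_that("tax effects follow elasticity times relative price change", {
  expect_equal(tax_effect(110, 100, -0.6), -0.06, tolerance = 1e-12)
  expect_equal(tax_effect(100, 100, -0.2), 0)
  expect_equal(tax_effect(95, 100, -0.1), 0.005, tolerance = 1e-12)
  expect_error(tax_effect(0, 100, -0.6), "positive")
  expect_equal(tax_elasticities()$elasticity, c(-0.6, -0.2, -0.1, -0.2))
})

test_that("effects scale with coverage, enforcement and venue allowances", {
  expect_equal(scale_effect(-0.06), -0.06)
  expect_equal(scale_effect(-0.06, enforcement = 0), -0.03)  # halved
  expect_equal(scale_effect(-0.06, coverage = 0.6), -0.036)
  expect_equal(scale_effect(-0.06, allowance = "ventilated"), -0.04)
  expect_equal(scale_effect(-0.06, allowance = "common"), -0.02)
  expect_error(scale_effect(-0.06, coverage = 1.2), "\\[0, 1\\]")
  expect_error(scale_effect(-0.06, enforcement = 11), "\\[0, 10\\]")
})

test_that("level mixing is the share-weighted combination of triples", {
  strong <- mix_levels(c(high = 1), "health_warnings")
  expect_equal(unname(strong), c(-0.04, -0.06, 0.10))
  mixed <- mix_levels(c(moderate = 0.5, high = 0.5), "health_warnings")
  expect_equal(unname(mixed), c(-0.03, -0.04, 0.07))
  none <- mix_levels(c(minimal = 1), "marketing")
  expect_equal(unname(none["cessation"]), 0)
  expect_error(mix_levels(c(high = 0.6), "health_warnings"), "sum to 1")
})

test_that("policies combine multiplicatively and order-independently", {
  expect_equal(combine_policies(c(-0.06, -0.02)), 0.94 * 0.98,
               tolerance = 1e-15)
  expect_equal(combine_policies(numeric(0)), 1)
  expect_equal(combine_policies(-0.05, channel = "cessation"), 1.05)
  set.seed(11)
  pes <- runif(6, -0.2, 0)
  for (ch in c("prevalence", "initiation", "cessation")) {
    expect_identical(combine_policies(pes, ch),
                     combine_policies(rev(pes), ch))
    expect_identical(combine_policies(pes, ch),
                     combine_policies(sample(pes), ch))
  }
  expect_error(combine_policies(-1), "not meaningful")
})

test_that("youth-access effects are age-banded by enforcement level", {
  strong <- youth_access_effect("strong")
  expect_equal(strong$pes_initiation[strong$band == "16-17"], -0.16)
  expect_equal(strong$pes_initiation[strong$band == "10-15"], -0.24)
  low <- youth_access_effect("low")
  expect_equal(low$pes_initiation[low$band == "16-17"], -0.02)
  expect_equal(low$pes_initiation[low$band == "10-15"], -0.03)
  expect_error(youth_access_effect("extreme"), "low, moderate or strong")
})

test_that("menthol effects weight linearly by covered population", {
  expect_equal(menthol_effect(1), c(prevalence = -0.005, initiation = -0.02))
  expect_equal(menthol_effect(0), c(prevalence = 0, initiation = 0))
  expect_equal(menthol_effect(0.4),
               c(prevalence = -0.002, initiation = -0.008),
               tolerance = 1e-12)
})

test_that("prevalence channel fires only in the change year", {
  expect_setequal(active_channels(2001, 2001),
                  c("prevalence", "initiation", "cessation"))
  expect_setequal(active_channels(2001, 2005), c("initiation", "cessation"))
  expect_length(active_channels(NA, 2005), 0)

  tl <- policy_timeline(data.frame(
    policy = "health_warnings", year = c(1999, 2001), level = c("moderate", "high")))
  m <- build_policy_multipliers(tl, 1999:2005)
  expect_equal(m[["1999"]]$prevalence[20], 1)          # pre-existing level
  expect_equal(m[["2001"]]$prevalence[20], 0.96 / 0.98, tolerance = 1e-12)
  expect_equal(m[["2005"]]$prevalence[20], 1)
  expect_equal(m[["2005"]]$initiation[20], 0.94)       # ongoing channel
  expect_equal(m[["2005"]]$cessation[20], 1.10)
})

test_that("timeline multipliers match a hand-evaluated oracle", {
  ## four concurrent policies over 8 years, evaluated by explicit
  ## arithmetic: warnings moderate->high in 2001, worksite ban (enf 9)
  ## from 2001, media low->moderate in 2003, tax +10% in 2002
  tl <- policy_timeline(data.frame(
    policy = c("health_warnings", "health_warnings", "smokefree_worksite",
               "media_campaign", "media_campaign", "tax", "tax", "tax"),
    year = c(1999, 2001, 2001, 1999, 2003, 1999, 2001, 2002),
    level = c("moderate", "high", "full", "low", "moderate",
              "price", "price", "price"),
    enforcement = c(10, 10, 9, 10, 10, 10, 10, 10),
    price = c(NA, NA, NA, NA, NA, 100, 100, 110)))
  m <- build_policy_multipliers(tl, 1999:2006)

  wk <- -0.06 * (0.5 + 0.5 * 9 / 10)   # worksite, enforcement 9
  eps <- c(rep(0, 15), rep(-0.6, 6), rep(-0.2, 14), rep(-0.1, 30),
           rep(-0.2, 36))              # elasticity by age 0..100
  for (a in c(16, 25, 40, 70)) {
    i <- a + 1
    ## 2002: only the tax changes; prevalence shock = 1 + eps * 10%
    expect_equal(m[["2002"]]$prevalence[i], 1 + eps[i] * 0.1,
                 tolerance = 1e-12)
    ## 2003: media moderate replaces low -> ratio of (1+PES)
    expect_equal(m[["2003"]]$prevalence[i], (1 - 0.0325) / (1 - 0.0163),
                 tolerance = 1e-12)
    ## 2006 ongoing initiation: warnings high x worksite x media moderate
    ## x tax (price 10% above baseline)
    expect_equal(m[["2006"]]$initiation[i],
                 (1 - 0.06) * (1 + wk) * (1 - 0.0325) * (1 + eps[i] * 0.1),
                 tolerance = 1e-12)
    ## 2006 ongoing cessation: (1 + printed) for registry policies,
    ## (1 - PES) for the tax
    expect_equal(m[["2006"]]$cessation[i],
                 (1 + 0.10) * (1 - wk) * (1 + 0.0325) * (1 - eps[i] * 0.1),
                 tolerance = 1e-12)
  }
  ## 2001: warnings upgrade and worksite introduction shock together
  expect_equal(m[["2001"]]$prevalence[41],
               (0.96 / 0.98) * (1 + wk), tolerance = 1e-12)
})

test_that("strengthening a policy never raises projected prevalence", {
  base_tl <- policy_timeline(data.frame(
    policy = "health_warnings", year = 1999, level = "low"))
  strong_tl <- policy_timeline(data.frame(
    policy = "health_warnings", year = c(1999, 2003),
    level = c("low", "high")))
  cfg <- fast_config()
  b <- generate_scenario(cfg)
  sc1 <- b$scenario; sc1$timeline <- base_tl
  sc2 <- b$scenario; sc2$timeline <- strong_tl
  r1 <- run_model(sc1, end_year = 2015)
  r2 <- run_model(sc2, end_year = 2015)
  p1 <- prevalence_series(r1, "both", "15+")
  p2 <- prevalence_series(r2, "both", "15+")
  expect_true(all(p2$prevalence <= p1$prevalence + 1e-12))
  expect_true(any(p2$prevalence < p1$prevalence))
})

test_that("the registry covers every policy family with printed triples", {
  reg <- policy_registry()
  triple <- function(policy, level) {
    r <- reg[reg$policy == policy & reg$level == level & is.na(reg$age_lo), ]
    c(r$pes_prevalence, r$pes_initiation, r$pes_cessation)
  }
  expect_equal(triple("smokefree_worksite", "full"), c(-0.06, -0.06, 0.06))
  expect_equal(triple("smokefree_restaurant", "full"), c(-0.02, -0.02, 0.02))
  expect_equal(triple("smokefree_pubs_bars", "full"), c(-0.01, -0.01, 0.01))
  expect_equal(triple("smokefree_other", "full"), c(-0.01, -0.01, 0.01))
  expect_equal(triple("marketing", "complete"), c(-0.05, -0.08, 0.04))
  expect_equal(triple("marketing", "moderate"), c(-0.03, -0.04, 0.02))
  expect_equal(triple("marketing", "minimal"), c(-0.01, -0.01, 0))
  expect_equal(triple("pos_display", "full"), c(0, -0.12, 0.10))
  expect_equal(triple("health_warnings", "high"), c(-0.04, -0.06, 0.10))
  expect_equal(triple("health_warnings", "moderate"), c(-0.02, -0.02, 0.04))
  expect_equal(triple("health_warnings", "low"), c(-0.01, -0.01, 0.02))
  expect_equal(triple("plain_packaging", "full"), c(-0.02, -0.02, 0.02))
  expect_equal(triple("media_campaign", "high"), c(-0.065, -0.065, 0.065))
  expect_equal(triple("media_campaign", "moderate"),
               c(-0.0325, -0.0325, 0.0325))
  expect_equal(triple("media_campaign", "low"), c(-0.0163, -0.0163, 0.0163))
  expect_equal(triple("cessation_pharmacotherapy", "full"),
               c(-0.01, 0, 0.04))
  expect_equal(triple("cessation_coverage", "full"), c(-0.0225, 0, 0.08))
  expect_equal(triple("cessation_quitline", "full"), c(-0.01, 0, 0.06))
  expect_equal(triple("cessation_brief_advice", "full"), c(-0.01, 0, 0.06))
  expect_equal(triple("cessation_combined", "full"), c(-0.0568, 0, 0.294))
  expect_equal(triple("menthol_ban", "full"), c(-0.005, -0.02, 0))
  ## youth access: three levels, two age bands each
  ya <- reg[reg$policy == "youth_access", ]
  expect_equal(nrow(ya), 6)
  expect_setequal(ya$level, c("strong", "moderate", "low"))
})
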