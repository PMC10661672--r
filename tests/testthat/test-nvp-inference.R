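test_that("relative reduction is the fractional decrease from the start", {
  expect_equal(relative_reduction(0.20, 0.15), 0.25)
  expect_equal(relative_reduction(0.13, 0.13), 0)
  expect_equal(relative_reduction(0.084, 0.125), -0.4880952,
               tolerance = 1e-6)
  expect_error(relative_reduction(0, 0.1), "positive")
})

test_that("annualization matches the log-space closed form", {
  expect_equal(round(100 * annualize(0.25, 8), 1), 3.5)
  expect_equal(annualize(0, 13), 0)
  for (r in c(-0.3, 0.05, 0.343, 0.9)) {
    for (n in c(1, 3, 8)) {
      expect_equal(annualize(r, n), 1 - exp(log1p(-r) / n),
                   tolerance = 1e-12)
    }
  }
  expect_error(annualize(1, 8), "< 1")
})

test_that("the annual adjustment is the annualized-reduction difference", {
  expect_equal(nvp_annual_adjustment(0.2, 0.2, 8), 0)
  ## slower survey decline gives a negative adjustment
  expect_equal(nvp_annual_adjustment(0.20, 0.10, 8),
               (0.8)^(1 / 8) - (0.9)^(1 / 8), tolerance = 1e-15)
  expect_lt(nvp_annual_adjustment(0.20, 0.10, 8), 0)
  ## algebraic identity with annualize, over a grid
  set.seed(3)
  for (k in 1:50) {
    rm <- runif(1, -0.5, 0.9); rs <- runif(1, -0.5, 0.9)
    n <- sample(1:10, 1)
    expect_equal(nvp_annual_adjustment(rm, rs, n),
                 annualize(rs, n) - annualize(rm, n), tolerance = 1e-12)
  }
})

test_that("reduction bounds come from the endpoint interval, ordered", {
  b <- ci_bounds_on_reduction(0.178, 0.104, 0.131)
  expect_equal(unname(b), c((0.178 - 0.131) / 0.178,
                            (0.178 - 0.104) / 0.178), tolerance = 1e-12)
  expect_equal(ci_bounds_on_reduction(0.2, 0.2, 0.2),
               c(low = 0, high = 0))
  set.seed(9)
  for (k in 1:50) {
    p0 <- runif(1, 0.05, 0.4)
    p1 <- runif(1, 0.01, 0.4)
    half <- runif(1, 0, 0.05)
    b <- ci_bounds_on_reduction(p0, p1 - half, p1 + half)
    point <- relative_reduction(p0, p1)
    expect_true(b[["low"]] <= point && point <= b[["high"]])
  }
})

test_that("period splits follow each survey convention", {
  ct <- period_split("ctums")
  expect_equal(ct$n[ct$period == "pre"], 5)
  expect_equal(ct$start[ct$period == "post"], 2017)
  expect_equal(ct$n[ct$period == "post"], 3)
  cc <- period_split("cchs")
  expect_equal(cc$n, c(8, 6, 2))
  expect_equal(cc$start[cc$period == "post"], 2018)
  one <- period_split("ctums", start = 2016, end = 2017)
  expect_equal(one$period, "full")
})

test_that("the adjustment reallocates by initiation age and conserves mass", {
  st18 <- cell_state(2012, 18, "male", "current", 1000)
  out <- apply_adjustment(st18, 0.05)
  expect_equal(out$counts["18", "male", "current"], 950)
  expect_equal(out$counts["18", "male", "never"], 50)

  st40 <- cell_state(2012, 40, "male", "current", 1000)
  out40 <- apply_adjustment(st40, 0.05)
  expect_equal(out40$counts["40", "male", "former1"], 50)

  ## unchanged at zero, compounding over repeated years
  expect_equal(apply_adjustment(st40, 0)$counts, st40$counts)
  st <- st40
  for (k in 1:8) st <- apply_adjustment(st, 0.025)
  expect_equal(st$counts["40", "male", "current"], 1000 * 0.975^8,
               tolerance = 1e-12)

  ## exact conservation for random states and signed alphas
  set.seed(21)
  for (k in 1:5) {
    stx <- uniform_state()
    a <- matrix(runif(202, -0.1, 0.2), 101, 2)
    outx <- apply_adjustment(stx, a)
    expect_equal(rowSums(outx$counts, dims = 2),
                 rowSums(stx$counts, dims = 2), tolerance = 1e-12)
    expect_true(all(outx$counts >= 0))
  }
  expect_error(apply_adjustment(st40, 1), "< 1")
})

test_that("compounding the derived alpha reproduces the survey endpoint", {
  ## with all other flows frozen the counterfactual is flat, so the
  ## adjusted trajectory p0 * (1 - alpha)^n must land on the survey end
  p0 <- 0.2
  for (p_end in c(0.15, 0.19, 0.08)) {
    n <- 8
    a <- nvp_annual_adjustment(0, relative_reduction(p0, p_end), n)
    st <- cell_state(2012, 40, "male", "current", 1000)
    for (k in 1:n) st <- apply_adjustment(st, a)
    ## remaining current share times p0 is the adjusted prevalence
    expect_equal(p0 * st$counts["40", "male", "current"] / 1000,
                 p_end, tolerance = 1e-9)
  }
})

test_that("gain tables satisfy the difference identity on every row", {
  g <- nvp_gain_table(canada_prevalence_fixture())
  expect_equal(g$diff, g$rel_survey - g$rel_model, tolerance = 1e-12)
  expect_true(all(g$annual_gain_lo <= g$annual_gain + 1e-12 &
                    g$annual_gain <= g$annual_gain_hi + 1e-12))
})

test_that("a survey identical to the counterfactual yields a null report", {
  cfg <- fast_config()
  b <- generate_scenario(cfg)
  cf <- run_model(b$scenario, end_year = 2020, bands = c("15+", "15-24"))
  survey <- cf$prevalence[cf$prevalence$sex %in% c("male", "female") &
                            cf$prevalence$year >= 2012, ]
  survey$ci_low <- survey$prevalence
  survey$ci_high <- survey$prevalence
  rep <- build_report(b$scenario, survey, window = c(2012, 2020),
                      convention = "ctums", horizon_year = 2025,
                      bands = c("15+", "15-24"))
  expect_true(all(abs(rep$gains$diff) < 1e-12))
  expect_true(all(abs(rep$alpha$alpha) < 1e-12))
  expect_equal(rep$sads_averted, 0, tolerance = 1e-9)
})
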