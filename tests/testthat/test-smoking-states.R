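test_that("net initiation is the prevalence increment over never prevalence", {
  ii <- derive_net_initiation(prevalence = c(0.05, 0.10),
                              never_prevalence = c(0.90, 0.85),
                              ages = 15:16)
  expect_equal(ii[["16"]], (0.10 - 0.05) / 0.90, tolerance = 1e-12)
  expect_equal(round(ii[["16"]], 4), 0.0556)

  flat <- derive_net_initiation(c(0.1, 0.1), c(0.8, 0.8), 15:16)
  expect_equal(flat[["16"]], 0)

  declining <- derive_net_initiation(c(0.05, 0.04), c(0.9, 0.9), 15:16)
  expect_equal(declining[["16"]], 0)   # floored, never negative

  expect_error(derive_net_initiation(c(0.1, 0.2), c(0, 0.8), 15:16),
               "undefined")
})

test_that("cessation is last-year quitting over lagged prevalence, clamped", {
  expect_equal(derive_cessation(0.01, 0.20), 0.05)
  expect_equal(derive_cessation(0, 0.20), 0)
  expect_warning(c1 <- derive_cessation(0.25, 0.20), "clamped")
  expect_equal(c1, 1)
  expect_error(derive_cessation(0.01, 0), "> 0")
})

test_that("zero rates leave the state unchanged", {
  st <- uniform_state()
  out <- step_states(st, zero_rates())
  ## bin ageing still advances former-smoker durations; everything else fixed
  expect_equal(out$counts[, , "never"], st$counts[, , "never"])
  expect_equal(out$counts[, , "current"], st$counts[, , "current"])
  expect_equal(rowSums(out$counts, dims = 2), rowSums(st$counts, dims = 2))
})

test_that("cessation and relapse flows match direct arithmetic", {
  st <- cell_state(2000, 40, "male", "current", 1000)
  rates <- flat_rates(cess = 0.04)
  out <- step_states(st, rates, multipliers = list(cessation = 1.1))
  expect_equal(out$counts["40", "male", "former1"], 1000 * 0.044,
               tolerance = 1e-12)
  expect_equal(out$counts["40", "male", "current"], 1000 * (1 - 0.044))

  st2 <- cell_state(2000, 50, "female", "former2", 100)
  rates2 <- flat_rates(relapse = c(0, 0.10, 0, 0, 0, 0))
  out2 <- step_states(st2, rates2)
  expect_equal(out2$counts["50", "female", "current"], 10)
})

test_that("initiation applies only through the last initiation age", {
  x <- empty_counts()
  x[c("18", "30"), "male", "never"] <- 1000
  x[c("19", "30"), "female", "never"] <- 1000
  st <- population_state(2000, x)
  out <- step_states(st, flat_rates(init = 0.05))
  expect_equal(out$counts["18", "male", "current"], 50)
  expect_equal(out$counts["19", "female", "current"], 50)
  expect_equal(out$counts["30", "male", "current"], 0)   # past a_init
  expect_equal(out$counts["30", "female", "current"], 0)
})

test_that("mass is conserved within every age/sex cell across transitions", {
  set.seed(7)
  for (rep in 1:10) {
    x <- empty_counts()
    adult <- AGES >= 12
    for (s in SEXES) {
      x[adult, s, "never"] <- runif(sum(adult), 0, 1000)
      x[adult, s, "current"] <- runif(sum(adult), 0, 500)
      for (b in 1:6) x[adult, s, paste0("former", b)] <-
        runif(sum(adult), 0, 100)
    }
    x[AGES < 12, , ] <- 0
    x[AGES < 12, , "never"] <- 500
    st <- population_state(2000, x)
    rates <- flat_rates(init = runif(1, 0, 0.1), cess = runif(1, 0, 0.1),
                        relapse = runif(6, 0, 0.2))
    mult <- list(prevalence = runif(1, 0.9, 1),
                 initiation = runif(1, 0.5, 1.5),
                 cessation = runif(1, 0.5, 1.5))
    out <- step_states(st, rates, mult)
    expect_equal(rowSums(out$counts, dims = 2),
                 rowSums(st$counts, dims = 2), tolerance = 1e-9)
    expect_true(all(out$counts >= 0))
  }
})

test_that("two-state chain matches a brute-force Markov oracle", {
  ## never/current only (no relapse, cessation off): prevalence among a
  ## fixed cohort follows p_{k+1} = p_k + (1-p_k) * I
  i_rate <- 0.08
  oracle <- function(p0, k) {
    p <- p0
    for (j in seq_len(k)) p <- p + (1 - p) * i_rate
    p
  }
  x <- empty_counts()
  x["15", "male", "never"] <- 900
  x["15", "male", "current"] <- 100
  st <- population_state(2000, x)
  rates <- flat_rates(init = i_rate, a_init = c(male = 60, female = 60))
  for (k in 1:5) st <- step_states(st, rates)
  p_model <- st$counts["15", "male", "current"] / 1000
  expect_equal(p_model, oracle(0.1, 5), tolerance = 1e-12)
})

test_that("a first-year prevalence shock reallocates by initiation age", {
  x <- empty_counts()
  x["18", "male", "current"] <- 1000
  x["40", "male", "current"] <- 1000
  st <- population_state(2000, x)
  out <- step_states(st, zero_rates(),
                     multipliers = list(prevalence = 0.94))
  expect_equal(out$counts["18", "male", "current"], 940)
  expect_equal(out$counts["18", "male", "never"], 60)    # initiation ages
  expect_equal(out$counts["40", "male", "former1"], 60)  # adult ages
  expect_equal(rowSums(out$counts, dims = 2), rowSums(st$counts, dims = 2))
})

test_that("probabilities pushed outside [0,1] by multipliers clamp with warning", {
  st <- cell_state(2000, 40, "male", "current", 100)
  rates <- flat_rates(cess = 0.8)
  expect_warning(out <- step_states(st, rates,
                                    multipliers = list(cessation = 2)),
                 "clamped")
  expect_equal(out$counts["40", "male", "former1"], 100)
})

test_that("young children cannot hold smoking states", {
  x <- empty_counts()
  x["5", "male", "current"] <- 10
  expect_error(population_state(2000, x), "never smokers")
})
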