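## ---- small builders used across tests ----

AGES <- 0:100
SEXES <- c("male", "female")
STATUS <- c("never", "current", paste0("former", 1:6))

empty_counts <- function() {
  array(0, c(101, 2, 8),
        dimnames = list(age = AGES, sex = SEXES, status = STATUS))
}

## a population with `n` persons in one age/sex/status cell
cell_state <- function(year, age, sex, status, n) {
  x <- empty_counts()
  x[as.character(age), sex, status] <- n
  population_state(year, x)
}

## uniform adult population with given current/former prevalence
uniform_state <- function(year = 2000, n_per_age = 1000,
                          p_current = 0.2, p_former = 0.1) {
  x <- empty_counts()
  for (s in SEXES) {
    x[, s, "never"] <- n_per_age
    adult <- AGES >= 15
    x[adult, s, "never"] <- n_per_age * (1 - p_current - p_former)
    x[adult, s, "current"] <- n_per_age * p_current
    for (b in 1:6) x[adult, s, paste0("former", b)] <- n_per_age * p_former / 6
  }
  population_state(year, x)
}

zero_rates <- function(a_init = c(male = 20, female = 21)) {
  z <- matrix(0, 101, 2)
  transition_rates(z, z, relapse = rep(0, 6), a_init = a_init)
}

flat_rates <- function(init = 0, cess = 0, relapse = rep(0, 6),
                       a_init = c(male = 20, female = 21)) {
  transition_rates(matrix(init, 101, 2), matrix(cess, 101, 2),
                   relapse = relapse, a_init = a_init)
}

flat_matrix <- function(v) matrix(v, 101, 2, dimnames = list(AGES, SEXES))

## small deterministic synthetic config for fast tests
fast_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, pop_size = 2e5, horizon_year = 2030)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}
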