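#' Read an age/sex surface from tidy CSV
#'
#' Reads tables in the long layout `sex, age, value` (year-invariant) or
#' `year, sex, age, value` (one surface per year) into the matrix form
#' the engines take: a `[age 0:100, sex]` matrix, or a function of year
#' returning one.  Ages listed once cover that single year of age; the
#' value for the highest listed age is carried to the end of the open
#' terminal band.
#'
#' @param path CSV file path.
#' @param default Value for ages not listed (default 0).
#' @return A matrix `[age, sex]`, or (with a `year` column) a function
#'   `f(year)` returning one; years outside the table take the nearest
#'   covered year's surface.
#' @export
read_age_sex_csv <- function(path, default = 0) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "value")
  if (!all(need %in% names(d))) {
    stop("need columns sex, age, value (optionally year)", call. = FALSE)
  }
  if (!all(d$sex %in% SEXES)) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  build <- function(dd) {
    m <- matrix(default, length(AGES), length(SEXES),
                dimnames = list(age = AGES, sex = SEXES))
    for (s in SEXES) {
      ds <- dd[dd$sex == s, ]
      if (nrow(ds) == 0) next
      m[as.character(ds$age), s] <- ds$value
      top <- max(ds$age)
      if (top < MAX_AGE) {
        m[AGES > top, s] <- ds$value[which.max(ds$age)]
      }
    }
    m
  }
  if (!"year" %in% names(d)) return(build(d))
  yrs <- sort(unique(d$year))
  surfaces <- lapply(yrs, function(y) build(d[d$year == y, ]))
  names(surfaces) <- yrs
  function(year) {
    i <- findInterval(year, yrs)
    surfaces[[max(1L, i)]]
  }
}
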