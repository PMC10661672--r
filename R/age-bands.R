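#' Age band registry
#'
#' Reporting and survey comparison use a fixed set of age bands.  The two
#' national survey conventions report adults as 15+ (with 15-24 youth) and
#' as 18+ (with 18-24); policy effect sizes use additional bands (youth
#' access 10-15 and 16-17, tax elasticities 15-20 / 21-34 / 35-64 / 65+).
#' Open-ended bands use `Inf` as upper edge.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (inclusive ages).
#' @export
age_band_registry <- function() {
  data.frame(
    band = c("15+", "15-24", "25-44", "45-64", "65+",
             "18+", "18-24", "35-54", "55+",
             "10-15", "16-17", "15-20", "21-34", "35-64"),
    lo = c(15, 15, 25, 45, 65, 18, 18, 35, 55, 10, 16, 15, 21, 35),
    hi = c(Inf, 24, 44, 64, Inf, Inf, 24, 54, Inf, 15, 17, 20, 34, 64),
    stringsAsFactors = FALSE
  )
}

#' Single-year ages covered by a band
#'
#' @param band Band label from [age_band_registry()], or a string of the
#'   form `"lo-hi"` / `"lo+"`.
#' @return Integer vector of ages.
#' @export
band_ages <- function(band) {
  reg <- age_band_registry()
  i <- match(band, reg$band)
  if (is.na(i)) {
    if (grepl("^[0-9]+\\+$", band)) {
      lo <- as.integer(sub("\\+$", "", band))
      hi <- Inf
    } else if (grepl("^[0-9]+-[0-9]+$", band)) {
      parts <- as.integer(strsplit(band, "-")[[1]])
      lo <- parts[1]; hi <- parts[2]
    } else {
      stop("unknown age band: ", band, call. = FALSE)
    }
  } else {
    lo <- reg$lo[i]; hi <- reg$hi[i]
  }
  seq.int(lo, min(hi, MAX_AGE))
}
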