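#' Canadian prevalence fixture
#'
#' Packaged prevalence point estimates for Canada over the vaping era:
#' the two national survey series — the sequential tobacco monitoring
#' surveys (CTUMS/CTADS/CTNS, labelled `ctums`) and the community health
#' survey (`cchs`) — with 95% confidence intervals, alongside matched
#' no-vaping counterfactual model projections, by sex and age band at the
#' analysis anchor years (2012, the pre/post pivot, 2020).
#'
#' @param survey `"ctums"`, `"cchs"`, or `"both"`.
#' @return Data frame `survey`, `sex`, `band`, `source`
#'   (`model`/`survey`), `year`, `prevalence`, `ci_low`, `ci_high`, all
#'   prevalences as fractions.
#' @export
canada_prevalence_fixture <- function(survey = c("both", "ctums", "cchs")) {
  survey <- match.arg(survey)
  read_one <- function(name) {
    path <- system.file("extdata", name, package = "smokesim",
                        mustWork = TRUE)
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (col in c("prevalence", "ci_low", "ci_high")) {
      d[[col]] <- d[[col]] / 100        # stored as printed percentages
    }
    d
  }
  out <- switch(survey,
    ctums = read_one("ctums_comparison.csv"),
    cchs = read_one("cchs_comparison.csv"),
    both = rbind(read_one("ctums_comparison.csv"),
                 read_one("cchs_comparison.csv"))
  )
  out
}
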