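#' Published kin-cohort estimates for the two lifespan sentinel variants
#'
#' Transcription of the published per-stratum Cox estimates for rs429358
#' (*APOE* epsilon-4 tag, chr19:45411941, C allele) and rs10519203
#' (*CHRNA3/5* locus, chr15:78814046, G allele) from a large biobank
#' kin-cohort analysis of parental lifespan: per-parent-sex discovery
#' estimates, the three replication cohorts, the age-window (40-75 vs 75+)
#' stratified estimates, and the printed meta-analytic combinations. Betas
#' are log hazard ratios on the parental allele scale; `years` is the printed
#' per-allele life-year reduction. Rows with `combined = TRUE` are printed
#' derived quantities (meta-analyses, contrast p-values) that the package's
#' own arithmetic should reproduce from the `combined = FALSE` input rows.
#'
#' @return data.frame of the published estimates.
#' @export
kin_published_estimates <- function() {
  path <- system.file("extdata", "sentinel_lifespan_estimates.tsv",
                      package = "kinspan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
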