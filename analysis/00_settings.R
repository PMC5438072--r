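# Shared settings for the analysis drivers. The study cohort emulates the
# structure behind a biobank kin-cohort lifespan GWAS: two causal loci whose
# configured parental log-HRs are the published age-window estimates -- an
# APOE-like longevity locus (mother-dominated, effect growing after 75) and a
# CHRNA3/5-like frailty locus (father-dominated, effect waning after 75) --
# plus 500 null variants for calibration.

library(kinspan)

out_dir <- "results/kin_study"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

study_seed <- 2024L
sentinels <- c("apoe_like", "chrna35_like")

study_config <- function(n_subjects = 100000L, seed = study_seed) {
  n_null <- 500L
  eff <- causal_effect_table(
    father = c(0.0752, 0.0924, rep(0, n_null)),
    father_75plus = c(0.1147, 0.0321, rep(0, n_null)),
    mother = c(0.0858, 0.0565, rep(0, n_null)),
    mother_75plus = c(0.1847, 0.0292, rep(0, n_null)))
  rownames(eff) <- c(sentinels, sprintf("null_%02d", seq_len(n_null)))
  sim_config(n_subjects = n_subjects,
             n_variants = nrow(eff),
             allele_freqs = c(0.15, 0.35, rep(0.3, n_null)),
             causal_effects = eff,
             seed = seed)
}
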