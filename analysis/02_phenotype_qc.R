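#!/usr/bin/env Rscript
# Phenotype quality control: drop adopted subjects, subjects without usable
# parental data, implausible parent ages and missing covariates; drop
# individual parent records for deaths before 40. Emits the clean table and
# the exclusion tally.

source("analysis/00_settings.R")

pheno <- read_cohort_tsv(file.path(out_dir, "cohort_raw.tsv"))
qc <- apply_exclusions(pheno)
print(qc$tally)
write_cohort_tsv(qc$clean, file.path(out_dir, "cohort_clean.tsv"))
jsonlite::write_json(unclass(qc$tally),
                     file.path(out_dir, "exclusion_tally.json"),
                     auto_unbox = TRUE)
cat("wrote cohort_clean.tsv and exclusion_tally.json to", out_dir, "\n")
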