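# Phenotype quality control: exclusion rules for questionnaire-reported
# parental lifespans, with an auditable tally. Subject-level rules are applied
# in a fixed precedence order (adopted -> no usable parental data -> invalid
# parent age -> missing covariate), each subject counted once under the first
# rule it triggers; pre-40 parental deaths are then removed record by record.

#' Apply phenotype exclusion rules
#'
#' Removes (in precedence order) subjects who were adopted, subjects with no
#' usable parental record (no parental ages recorded, or every recorded parent
#' dead before 40), subjects with an implausible parent age (> 115 years), and
#' subjects with a missing covariate. Among retained subjects, individual
#' parent records with observed age <= 40 (deaths before 40, or no follow-up
#' beyond entry) are dropped, as are single missing parent records. The
#' analysis phenotype is thus survival from age 40.
#'
#' @param pheno long phenotype table: one row per parent record with columns
#'   `subject_id`, `parent`, `entry`, `observed_age`, `event`, `adopted` and
#'   any number of `covariate_*` columns.
#' @return list with `clean` (the retained records, columns unchanged) and
#'   `tally` (class `kin_exclusion_tally`), which reconciles exactly:
#'   subjects in = subjects remaining + sum of subject-level exclusions.
#' @export
apply_exclusions <- function(pheno) {
  covcols <- .check_pheno_schema(pheno)
  if (nrow(pheno) == 0) {
    tally <- .exclusion_tally(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
    return(list(clean = pheno, tally = tally))
  }
  sid <- factor(pheno$subject_id, levels = unique(pheno$subject_id))
  n_subj <- nlevels(sid)

  usable <- !is.na(pheno$observed_age) & pheno$observed_age > 40
  by_subj <- function(x) as.vector(tapply(x, sid, any))
  s_adopted <- by_subj(pheno$adopted)
  s_no_data <- !as.vector(tapply(usable, sid, any))
  s_invalid <- by_subj(!is.na(pheno$observed_age) & pheno$observed_age > 115)
  if (length(covcols)) {
    cov_na <- rowSums(is.na(pheno[, covcols, drop = FALSE])) > 0
    s_misscov <- by_subj(cov_na)
  } else s_misscov <- rep(FALSE, n_subj)

  # first triggered rule wins: assign in reverse precedence
  reason <- rep(NA_character_, n_subj)
  reason[s_misscov] <- "missing_covariate"
  reason[s_invalid] <- "invalid_age"
  reason[s_no_data] <- "no_parental_data"
  reason[s_adopted] <- "adopted"
  keep_subj <- is.na(reason)

  rec_kept_subject <- keep_subj[as.integer(sid)]
  rec_missing <- rec_kept_subject & is.na(pheno$observed_age)
  rec_pre40 <- rec_kept_subject & !is.na(pheno$observed_age) & !usable
  keep_rec <- rec_kept_subject & usable

  tally <- .exclusion_tally(
    n_subjects_in = n_subj,
    adopted = sum(reason == "adopted", na.rm = TRUE),
    no_parental_data = sum(reason == "no_parental_data", na.rm = TRUE),
    invalid_age = sum(reason == "invalid_age", na.rm = TRUE),
    missing_covariate = sum(reason == "missing_covariate", na.rm = TRUE),
    subjects_remaining = sum(keep_subj),
    pre40_parent_records = sum(rec_pre40),
    missing_parent_records = sum(rec_missing),
    records_in = nrow(pheno),
    records_remaining = sum(keep_rec))
  clean <- pheno[keep_rec, , drop = FALSE]
  rownames(clean) <- NULL
  list(clean = clean, tally = tally)
}

.exclusion_tally <- function(n_subjects_in, adopted, no_parental_data,
                             invalid_age, missing_covariate,
                             subjects_remaining, pre40_parent_records,
                             missing_parent_records, records_in,
                             records_remaining) {
  x <- list(n_subjects_in = n_subjects_in, adopted = adopted,
            no_parental_data = no_parental_data, invalid_age = invalid_age,
            missing_covariate = missing_covariate,
            subjects_remaining = subjects_remaining,
            pre40_parent_records = pre40_parent_records,
            missing_parent_records = missing_parent_records,
            records_in = records_in, records_remaining = records_remaining)
  stopifnot(x$n_subjects_in == x$subjects_remaining + x$adopted +
              x$no_parental_data + x$invalid_age + x$missing_covariate)
  structure(x, class = "kin_exclusion_tally")
}

#' @export
print.kin_exclusion_tally <- function(x, ...) {
  cat("Phenotype exclusions (subjects):\n")
  cat(sprintf("  input                %d\n", x$n_subjects_in))
  cat(sprintf("  adopted              %d\n", x$adopted))
  cat(sprintf("  no parental data     %d\n", x$no_parental_data))
  cat(sprintf("  invalid parent age   %d\n", x$invalid_age))
  cat(sprintf("  missing covariate    %d\n", x$missing_covariate))
  cat(sprintf("  remaining            %d\n", x$subjects_remaining))
  cat("Parent records:\n")
  cat(sprintf("  input                %d\n", x$records_in))
  cat(sprintf("  pre-40 / no exposure %d\n", x$pre40_parent_records))
  cat(sprintf("  missing (single)     %d\n", x$missing_parent_records))
  cat(sprintf("  remaining            %d\n", x$records_remaining))
  invisible(x)
}

#' @export
format.kin_exclusion_tally <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE)
}
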