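# Pipeline orchestration: simulate (or ingest) -> phenotype QC -> per-sex
# Cox stage -> Martingale residuals -> rank-normal scores -> per-variant
# scan -> conditional scan -> full-Cox verification on sentinels ->
# parental-scale rescaling -> meta-analysis and contrasts. Mirrors the
# discovery -> verification -> replication -> meta workflow of kin-cohort
# lifespan GWAS.

.align_dosage <- function(geno, subject_ids) {
  D <- geno$dosage
  idx <- match(as.character(subject_ids), rownames(D))
  if (all(is.na(idx)))
    stop("alignment error: no overlap between phenotype and genotype subject ids")
  if (anyNA(idx))
    stop("alignment error: ", sum(is.na(idx)),
         " phenotype subject ids missing from the genotype matrix")
  D[idx, , drop = FALSE]
}

#' Two-stage residual scan for one stratum
#'
#' Stage 1 fits the covariate-only Cox model to the stratum's survival
#' records and extracts Breslow-baseline Martingale residuals; stage 2
#' rank-normalises the residuals and scans them against offspring dosage,
#' reporting the score-scale slope, its p-value, and the one-step
#' hazard-scale estimate on the offspring and (doubled) parental scales.
#'
#' @param records survival records for one parent-sex stratum (post-QC).
#' @param geno a `kin_genotypes` object; rows matched to
#'   `records$subject_id`.
#' @param covariates covariate column names; defaults to all `covariate_*`
#'   columns.
#' @param ties tie handling for the Cox stage.
#' @param offset rank-normal offset (default Blom 3/8).
#' @param sentinels optional variant ids for an additional conditional scan.
#' @return list with `fit` (stage-1 `kin_cox_fit`), `assoc` (scan table),
#'   `conditional` (or NULL), `scores` and `residuals`.
#' @export
two_stage_scan <- function(records, geno, covariates = NULL,
                           ties = "efron", offset = 3/8, sentinels = NULL) {
  covariates <- covariates %||% grep("^covariate_", names(records), value = TRUE)
  fit <- fit_cox(records, covariates = covariates, ties = ties)
  m <- martingale_residuals(fit)
  sc <- rank_normal(m, offset = offset)
  D <- .align_dosage(geno, records$subject_id)
  G <- kin_genotypes(D, geno$info)
  assoc <- scan_variants(sc, G, residuals = m, n_events = fit$nevent)
  cond <- if (!is.null(sentinels))
    conditional_scan(sc, G, sentinels, residuals = m, n_events = fit$nevent)
  list(fit = fit, assoc = assoc, conditional = cond,
       scores = sc, residuals = m)
}

#' Full-Cox verification fit for sentinel variants
#'
#' Fits genotype dosage simultaneously with the covariates (single variant,
#' or several at once for a multi-variant fit), the direct route to log
#' hazard ratios that the two-stage scan approximates.
#'
#' @inheritParams two_stage_scan
#' @param variants variant ids to fit.
#' @param joint fit all `variants` simultaneously (TRUE) or one at a time.
#' @return For `joint = TRUE` a single `kin_cox_fit`; otherwise a named list
#'   of fits, one per variant.
#' @export
verify_full_cox <- function(records, geno, variants, covariates = NULL,
                            ties = "efron", joint = FALSE) {
  covariates <- covariates %||% grep("^covariate_", names(records), value = TRUE)
  D <- .align_dosage(geno, records$subject_id)
  idx <- match(variants, geno$info$snp)
  if (anyNA(idx)) stop("unknown variant id(s): ",
                       paste(variants[is.na(idx)], collapse = ", "))
  if (joint) {
    fit_cox(records, covariates = covariates,
            genotype = D[, idx, drop = FALSE], ties = ties)
  } else {
    out <- lapply(idx, function(i)
      fit_cox(records, covariates = covariates,
              genotype = D[, i, drop = FALSE], ties = ties))
    names(out) <- variants
    out
  }
}

#' Run the full kin-cohort pipeline
#'
#' Executes: synthetic-cohort generation (or phenotype/genotype ingestion)
#' -> phenotype QC -> per-parent-sex two-stage residual scan (optionally
#' conditional on sentinels) -> full-Cox verification at the sentinels ->
#' parental-scale rescaling -> father+mother inverse-variance meta-analysis
#' with a sex contrast per variant -> age-window (40-75 / 75+) verification
#' fits with frailty-versus-longevity contrasts. All artifacts are written
#' under `outdir` and stamped with the seed and a config checksum.
#'
#' @param config list with either `sim` (a [sim_config()]) or `pheno_path` +
#'   `geno_path`/`geno_format`; optional `sentinels` (variant ids; default:
#'   all variants with a configured nonzero effect, else none), `windows`
#'   (default `c("40-75", "75+")`), `ties`, `rank_offset`, `outdir`.
#' @return (invisibly) a result bundle: `tally`, per-sex `scans`,
#'   `verification`, `meta` (per-variant meta/contrast table), `windows`
#'   (age-window fits and contrasts), `files` (paths written), `log`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  outdir <- config$outdir %||% tempfile("kinspan_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ties <- config$ties %||% "efron"
  offset <- config$rank_offset %||% 3/8

  if (!is.null(config$sim)) {
    if (config$sim$n_variants < 1) stop("genotype stage: zero variants configured")
    say("simulating cohort: %d subjects, %d variants, seed %d",
        config$sim$n_subjects, config$sim$n_variants, config$sim$seed)
    cohort <- generate_cohort(config$sim)
    pheno <- cohort$pheno
    geno <- cohort$geno
    truth <- cohort$truth
  } else {
    if (is.null(config$pheno_path) || is.null(config$geno_path))
      stop("config needs either a sim block or pheno_path + geno_path")
    say("reading phenotypes from %s", config$pheno_path)
    pheno <- read_cohort_tsv(config$pheno_path)
    geno <- read_genotypes(config$geno_path, config$geno_format %||% "tsv")
    if (attr(geno, "n_imputed") %||% 0 > 0)
      say("mean-imputed %d missing dosages", attr(geno, "n_imputed"))
    truth <- NULL
  }
  if (ncol(geno$dosage) < 1) stop("genotype stage: zero variants in input")

  qc <- apply_exclusions(pheno)
  say("QC: %d of %d subjects retained (%d parent records)",
      qc$tally$subjects_remaining, qc$tally$n_subjects_in,
      qc$tally$records_remaining)
  clean <- qc$clean

  sentinels <- config$sentinels
  if (is.null(sentinels) && !is.null(truth)) {
    nz <- rowSums(abs(truth$effects)) > 0
    if (any(nz)) sentinels <- geno$info$snp[nz]
  }

  scans <- list()
  vfits <- list()
  for (sex in c("father", "mother")) {
    rec <- clean[clean$parent == sex, , drop = FALSE]
    say("stratum %s: %d records, %d deaths", sex, nrow(rec), sum(rec$event))
    scans[[sex]] <- two_stage_scan(rec, geno, ties = ties, offset = offset,
                                   sentinels = sentinels)
    if (!is.null(sentinels))
      vfits[[sex]] <- verify_full_cox(rec, geno, sentinels, ties = ties)
  }

  # per-variant father+mother meta on the doubled hazard-scale estimates,
  # plus the sex contrast
  af <- scans$father$assoc
  am <- scans$mother$assoc
  meta <- do.call(rbind, lapply(seq_len(nrow(af)), function(i) {
    if (is.na(af$beta_parent[i]) || is.na(am$beta_parent[i]))
      return(data.frame(snp = af$snp[i], beta_father = NA_real_,
                        se_father = NA_real_, beta_mother = NA_real_,
                        se_mother = NA_real_, beta_meta = NA_real_,
                        se_meta = NA_real_, hr_meta = NA_real_,
                        p_meta = NA_real_, p_sex_contrast = NA_real_))
    mm <- ivw_meta(c(af$beta_parent[i], am$beta_parent[i]),
                   c(af$se_parent[i], am$se_parent[i]),
                   labels = c("father", "mother"))
    ct <- contrast_test(af$beta_parent[i], af$se_parent[i],
                        am$beta_parent[i], am$se_parent[i])
    data.frame(snp = af$snp[i],
               beta_father = af$beta_parent[i], se_father = af$se_parent[i],
               beta_mother = am$beta_parent[i], se_mother = am$se_parent[i],
               beta_meta = mm$beta, se_meta = mm$se, hr_meta = mm$hr,
               p_meta = mm$p, p_sex_contrast = ct$p)
  }))

  windows <- NULL
  if (!is.null(sentinels) && isTRUE(config$do_windows %||% TRUE)) {
    windows <- list()
    for (sex in c("father", "mother")) {
      rec <- clean[clean$parent == sex, , drop = FALSE]
      wfit <- lapply(c(young = "40-75", old = "75+"), function(w)
        verify_full_cox(truncate_age_window(rec, w), geno, sentinels,
                        ties = ties))
      for (s in sentinels) {
        by <- wfit$young[[s]]$coefficients[[s]]
        bo <- wfit$old[[s]]$coefficients[[s]]
        sy <- sqrt(wfit$young[[s]]$vcov[s, s])
        so <- sqrt(wfit$old[[s]]$vcov[s, s])
        ct <- age_window_contrast(2 * by, 2 * sy, 2 * bo, 2 * so)
        windows[[paste(sex, s, sep = ".")]] <-
          data.frame(parent = sex, snp = s,
                     beta_young = 2 * by, se_young = 2 * sy,
                     beta_old = 2 * bo, se_old = 2 * so,
                     p_window_contrast = ct$p)
      }
    }
    windows <- do.call(rbind, windows)
    rownames(windows) <- NULL
  }

  files <- list()
  files$pheno <- write_cohort_tsv(pheno, file.path(outdir, "cohort_raw.tsv"))
  files$tally <- file.path(outdir, "exclusion_tally.json")
  jsonlite::write_json(unclass(qc$tally), files$tally, auto_unbox = TRUE)
  for (sex in names(scans)) {
    files[[paste0("assoc_", sex)]] <-
      write_assoc_tsv(scans[[sex]]$assoc,
                      file.path(outdir, paste0("assoc_", sex, ".tsv")))
    files[[paste0("qq_", sex)]] <-
      write_qq_manhattan_tsv(scans[[sex]]$assoc,
                             file.path(outdir, paste0("qq_", sex, ".tsv")))
    if (!is.null(scans[[sex]]$conditional))
      files[[paste0("cond_", sex)]] <-
        write_assoc_tsv(scans[[sex]]$conditional,
                        file.path(outdir, paste0("assoc_conditional_", sex, ".tsv")))
  }
  for (sex in names(vfits))
    for (s in names(vfits[[sex]]))
      files[[paste0("verify_", sex, "_", s)]] <-
        write_cox_json(vfits[[sex]][[s]],
                       file.path(outdir, paste0("verify_", sex, "_", s, ".json")))
  files$meta <- file.path(outdir, "meta.tsv")
  utils::write.table(meta, files$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(windows)) {
    files$windows <- file.path(outdir, "age_windows.tsv")
    utils::write.table(windows, files$windows, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(truth)) {
    files$truth <- file.path(outdir, "truth.json")
    jsonlite::write_json(list(effects = truth$effects,
                              allele_freqs = truth$config$allele_freqs,
                              seed = truth$config$seed,
                              contamination = truth$contamination),
                         files$truth, auto_unbox = TRUE, digits = NA)
  }
  cfg_path <- file.path(outdir, "config.json")
  cfg_echo <- config
  cfg_echo$sim <- if (!is.null(config$sim)) unclass(config$sim)
  jsonlite::write_json(cfg_echo, cfg_path, auto_unbox = TRUE, force = TRUE)
  files$config <- cfg_path
  say("config checksum %s", unname(tools::md5sum(cfg_path)))
  say("done in %.1f s; artifacts in %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), outdir)
  files$log <- file.path(outdir, "run.log")
  writeLines(log, files$log)

  invisible(list(tally = qc$tally, scans = scans, verification = vfits,
                 meta = meta, windows = windows, files = files, log = log,
                 clean = clean, geno = geno, truth = truth))
}
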