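# File I/O for the pipeline: phenotype TSV, dosage TSV (variants x subjects,
# explicit counted-allele column), minimal VCF (counted allele = ALT), fixed
# column-order association TSV, and a YAML pipeline configuration.

#' Write / read a phenotype table as TSV
#'
#' @param pheno long phenotype table (see [generate_cohort()]).
#' @param path file path.
#' @return the path ([write_cohort_tsv()]) or the table ([read_cohort_tsv()]).
#' @export
write_cohort_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  pheno <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_pheno_schema(pheno)
  pheno
}

#' Write genotypes as a dosage TSV (variants x subjects)
#'
#' Metadata columns `snp`, `chr`, `bp`, `a1` (counted allele), `a0`, `freq`
#' are followed by one column per subject.
#'
#' @param geno a `kin_genotypes` object.
#' @param path file path.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "kin_genotypes"))
  info <- geno$info
  if (is.null(info$a0)) info$a0 <- NA_character_
  if (is.null(info$freq)) info$freq <- NA_real_
  tab <- cbind(info[, c("snp", "chr", "bp", "a1", "a0", "freq")],
               as.data.frame(t(geno$dosage), check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Dosages must be hard calls (0/1/2 or NA). The counted allele is written as
#' ALT, matching the convention that the scan counts the non-reference
#' allele.
#'
#' @param geno a `kin_genotypes` object with integer dosages.
#' @param path file path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "kin_genotypes"))
  D <- geno$dosage
  if (any(!(D %in% c(0, 1, 2)) & !is.na(D)))
    stop("VCF output needs hard-call dosages (0/1/2 or NA)")
  info <- geno$info
  ref <- info$a0 %||% rep("G", nrow(info))
  gt_map <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  body <- vapply(seq_len(ncol(D)), function(v) {
    gt <- ifelse(is.na(D[, v]), "./.", gt_map[D[, v] + 1L])
    paste(c(info$chr[v], info$bp[v], info$snp[v], ref[v], info$a1[v],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix from dosage TSV or VCF
#'
#' TSV input follows the layout of [write_genotypes_tsv()] (variants x
#' subjects, counted allele in column `a1`). VCF input takes the ALT allele
#' as the counted allele and converts GT fields to ALT-allele counts; missing
#' genotypes are mean-imputed per variant and the imputation count recorded
#' in the `n_imputed` attribute.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a `kin_genotypes` object (dosage subjects x variants).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("snp", "chr", "bp", "a1", "a0", "freq")
    miss <- setdiff(c("snp", "chr", "bp", "a1"), names(tab))
    if (length(miss)) stop("malformed dosage TSV, missing column(s): ",
                           paste(miss, collapse = ", "))
    subj <- setdiff(names(tab), meta_cols)
    D <- t(as.matrix(tab[, subj, drop = FALSE]))
    if (!is.numeric(D)) stop("malformed dosage TSV: non-numeric dosages")
    rownames(D) <- subj
    info <- tab[, intersect(meta_cols, names(tab)), drop = FALSE]
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    cnt <- function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_real_, length(x))
      out[x == "0/0"] <- 0; out[x %in% c("0/1", "1/0")] <- 1; out[x == "1/1"] <- 2
      out
    }
    D <- t(matrix(cnt(gt), nrow = nrow(gt), dimnames = dimnames(gt)))
    fx <- vcfR::getFIX(vcf)
    if (is.null(dim(fx)))
      fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
    info <- data.frame(snp = fx[, "ID"],
                       chr = fx[, "CHROM"],
                       bp = as.integer(fx[, "POS"]),
                       a1 = fx[, "ALT"], a0 = fx[, "REF"],
                       stringsAsFactors = FALSE)
  }
  n_imp <- sum(is.na(D))
  if (n_imp > 0) D <- .impute_dosage(D)$G
  g <- kin_genotypes(D, info)
  attr(g, "n_imputed") <- n_imp
  g
}

#' Write association results in the fixed scan-output column order
#'
#' Columns, in order: CHR, SNP, BP, A1, N, BETA_OFF, SE_OFF, BETA_PARENT,
#' SE_PARENT, P, R2, NOTE.
#'
#' @param assoc a [scan_variants()] result.
#' @param path file path.
#' @export
write_assoc_tsv <- function(assoc, path) {
  out <- data.frame(CHR = assoc$chr, SNP = assoc$snp, BP = assoc$bp,
                    A1 = assoc$a1, N = assoc$n,
                    BETA_OFF = assoc$beta_off, SE_OFF = assoc$se_off,
                    BETA_PARENT = assoc$beta_parent,
                    SE_PARENT = assoc$se_parent,
                    P = assoc$p, R2 = assoc$r2, NOTE = assoc$note)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export QQ / Manhattan plotting data
#'
#' One row per scanned variant: id, chromosome, cumulative position and
#' -log10 p, ready for any plotting front end.
#'
#' @param assoc a [scan_variants()] result.
#' @param path file path.
#' @export
write_qq_manhattan_tsv <- function(assoc, path) {
  ord <- order(assoc$chr, assoc$bp)
  a <- assoc[ord, ]
  out <- data.frame(SNP = a$snp, CHR = a$chr, BP = a$bp,
                    CUMPOS = seq_len(nrow(a)),
                    NEGLOG10P = -log10(a$p))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised fields mirror the arguments of [run_pipeline()]; a `sim` block
#' is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    if (!is.null(sim$causal_effects))
      sim$causal_effects <- do.call(causal_effect_table, sim$causal_effects)
    cfg$sim <- do.call(sim_config, sim)
  }
  cfg
}
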