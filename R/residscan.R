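# Stage-2 scan: rank-normalised Martingale residuals regressed on offspring
# dosage, one variant at a time. The score-scale slope and its t-test p-value
# are the scan statistic; alongside it, a one-step hazard-scale estimate is
# reported (slope of the raw residuals times n/d, i.e. the Cox score
# statistic over the null information d*Var(x)), which reads directly as a
# log hazard ratio per offspring allele and is doubled for the parental scale.

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles `qnorm((rank - c) / (n - 2c + 1))` with
#' the Blom offset `c = 3/8` by default; ties get average ranks, NAs are
#' preserved.
#'
#' @param values numeric vector with at least two finite, non-identical
#'   values.
#' @param offset rank offset `c` (default 3/8).
#' @return normalized scores, same length as the input.
#' @export
rank_normal <- function(values, offset = 3/8) {
  ok <- is.finite(values)
  n <- sum(ok)
  if (n < 2) stop("rank_normal needs at least 2 finite values")
  if (length(unique(values[ok])) < 2)
    stop("degenerate input: all values identical")
  r <- rank(values, ties.method = "average", na.last = "keep")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

.dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "kin_genotypes")) genotypes$dosage
  else as.matrix(genotypes)
}

.variant_info <- function(genotypes, V) {
  if (inherits(genotypes, "kin_genotypes")) genotypes$info
  else data.frame(snp = colnames(.dosage_matrix(genotypes)) %||%
                    paste0("v", seq_len(V)),
                  chr = NA_integer_, bp = NA_integer_, a1 = NA_character_)
}

# mean-impute sporadic missing dosages; returns matrix + count imputed
.impute_dosage <- function(G) {
  n_imp <- 0L
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
    n_imp <- nrow(idx)
  }
  list(G = G, n_imputed = n_imp)
}

#' Per-variant association scan of survival scores
#'
#' Simple linear regression of the rank-normalised survival score on dosage,
#' per variant (covariates were already absorbed into the Cox stage).
#' Variants with missingness above `max_missing` are dropped to NA rows;
#' sporadic missing dosages below that are mean-imputed; monomorphic or
#' ultra-rare (MAF < `min_maf`) variants are emitted as NA rows rather than
#' errors, preserving row count.
#'
#' @param scores rank-normalised survival scores, one per subject.
#' @param genotypes a `kin_genotypes` object or dosage matrix (subjects x
#'   variants), row-aligned with `scores`.
#' @param residuals optional raw Martingale residuals (same subjects). When
#'   given, together with `n_events`, the hazard-scale one-step estimate
#'   `beta_off = slope(resid ~ dosage) * n / n_events` is reported;
#'   otherwise `beta_off` falls back to the score-scale slope.
#' @param n_events number of deaths in the Cox stage (required with
#'   `residuals`).
#' @param max_missing per-variant missingness threshold (default 0.05).
#' @param min_maf minimum minor-allele frequency (default 0.001).
#' @return data.frame, one row per variant, columns `snp`, `chr`, `bp`, `a1`,
#'   `n`, `beta_score`, `se_score`, `beta_off`, `se_off`, `beta_parent`,
#'   `se_parent` (doubled offspring-scale values), `p` (two-sided, from the
#'   score regression t statistic), `r2` (fraction of score variance
#'   explained) and `note`.
#' @export
scan_variants <- function(scores, genotypes, residuals = NULL, n_events = NULL,
                          max_missing = 0.05, min_maf = 0.001) {
  G <- .dosage_matrix(genotypes)
  V <- ncol(G)
  if (length(scores) != nrow(G))
    stop("scores and genotype rows are not aligned (",
         length(scores), " vs ", nrow(G), ")")
  if (!is.null(residuals)) {
    stopifnot(length(residuals) == nrow(G))
    if (is.null(n_events)) stop("n_events is required with residuals")
  }
  info <- .variant_info(genotypes, V)
  n <- nrow(G)
  note <- rep("", V)

  mfrac <- colMeans(is.na(G))
  drop_miss <- mfrac > max_missing
  note[drop_miss] <- "missingness_above_threshold"
  imp <- .impute_dosage(G)
  G <- imp$G
  cm <- colMeans(G)
  maf <- pmax(pmin(cm / 2, 1 - cm / 2), 0)
  sdx <- apply(G, 2, stats::sd)
  mono <- sdx == 0 | (min_maf > 0 & maf < min_maf)
  note[mono & note == ""] <- "monomorphic_or_rare"
  bad <- drop_miss | mono

  y <- scores - mean(scores)
  syy <- sum(y^2)
  Gc <- sweep(G, 2, cm)
  sxx <- colSums(Gc^2)
  sxy <- as.numeric(crossprod(Gc, y))
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  r2 <- sxy^2 / (sxx * syy)

  if (!is.null(residuals)) {
    m <- residuals - mean(residuals)
    smm <- sum(m^2)
    smy <- as.numeric(crossprod(Gc, m))
    bM <- smy / sxx
    seM <- sqrt(pmax(smm - bM * smy, 0) / (n - 2) / sxx)
    fac <- n / n_events
    beta_off <- bM * fac
    se_off <- seM * fac
  } else {
    beta_off <- beta
    se_off <- se
  }

  out <- data.frame(snp = info$snp, chr = info$chr, bp = info$bp, a1 = info$a1,
                    n = n,
                    beta_score = beta, se_score = se,
                    beta_off = beta_off, se_off = se_off,
                    beta_parent = 2 * beta_off, se_parent = 2 * se_off,
                    p = p, r2 = r2, note = note,
                    stringsAsFactors = FALSE)
  num <- c("beta_score", "se_score", "beta_off", "se_off",
           "beta_parent", "se_parent", "p", "r2")
  out[bad, num] <- NA_real_
  attr(out, "n_imputed") <- imp$n_imputed
  out
}

#' Conditional association scan on sentinel variants
#'
#' Re-runs the per-variant scan with the sentinel dosages included as
#' covariates (scores and dosages are residualised on the sentinels plus an
#' intercept, which is equivalent to the joint regression). A variant
#' collinear with the sentinels -- including a sentinel scanned against
#' itself -- is reported as an NA row with a note rather than an error.
#'
#' @inheritParams scan_variants
#' @param sentinel_ids variant ids (matching `info$snp` / column names) to
#'   condition on.
#' @return as [scan_variants()].
#' @export
conditional_scan <- function(scores, genotypes, sentinel_ids,
                             residuals = NULL, n_events = NULL,
                             max_missing = 0.05, min_maf = 0.001) {
  G <- .dosage_matrix(genotypes)
  info <- .variant_info(genotypes, ncol(G))
  sidx <- match(sentinel_ids, info$snp)
  if (anyNA(sidx)) stop("sentinel id(s) not in the genotype matrix: ",
                        paste(sentinel_ids[is.na(sidx)], collapse = ", "))
  S <- .impute_dosage(G[, sidx, drop = FALSE])$G
  if (any(apply(S, 2, stats::sd) == 0))
    stop("sentinel variant is monomorphic: cannot condition on it")
  n <- nrow(G)
  qrS <- qr(cbind(1, S))
  y_r <- qr.resid(qrS, scores)
  Gi <- .impute_dosage(G)$G
  var0 <- apply(Gi, 2, stats::var)
  G_r <- qr.resid(qrS, Gi)
  var_r <- apply(G_r, 2, stats::var)
  collin <- var0 > 0 & var_r / var0 < 1e-10
  m_r <- if (!is.null(residuals)) qr.resid(qrS, residuals) else NULL

  base <- scan_variants(y_r, `colnames<-`(G_r, info$snp),
                        residuals = m_r, n_events = n_events,
                        max_missing = 1, min_maf = 0)
  # restore metadata lost by passing a plain residualised matrix
  base$chr <- info$chr; base$bp <- info$bp; base$a1 <- info$a1
  # adjust dof for the sentinels absorbed by the projection
  dof <- n - 2 - ncol(S)
  scale_se <- sqrt((n - 2) / dof)
  for (cc in c("se_score", "se_off", "se_parent"))
    base[[cc]] <- base[[cc]] * scale_se
  base$p <- 2 * stats::pt(-abs(base$beta_score / base$se_score), df = dof)
  num <- c("beta_score", "se_score", "beta_off", "se_off",
           "beta_parent", "se_parent", "p", "r2")
  base[collin, num] <- NA_real_
  base$note[collin] <- "collinear_with_sentinel"
  # re-apply missingness/MAF screens of the ORIGINAL dosages
  mfrac <- colMeans(is.na(G))
  cm <- colMeans(Gi)
  maf <- pmin(cm / 2, 1 - cm / 2)
  bad <- mfrac > max_missing | maf < min_maf | apply(Gi, 2, stats::sd) == 0
  base[bad & !collin, num] <- NA_real_
  base$note[bad & !collin] <- "monomorphic_rare_or_missing"
  base
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364`, the median association
#' chi-square over its null expectation; values near 1 indicate no systematic
#' confounding.
#'
#' @param pvals vector of at least 100 p-values.
#' @return lambda (scalar).
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[is.finite(pvals)]
  if (length(pvals) < 100) stop("at least 100 p-values are required")
  chi <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Fraction of score variance explained by a variant
#'
#' @param scores survival scores.
#' @param dosage dosage vector for one variant.
#' @return squared correlation in [0,1].
#' @export
variance_explained <- function(scores, dosage) {
  stopifnot(length(scores) == length(dosage))
  if (stats::var(scores) == 0 || stats::var(dosage) == 0)
    stop("degenerate input: zero variance")
  stats::cor(scores, dosage)^2
}
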