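# Fixed-effect inverse-variance meta-analysis of log hazard ratios, with the
# normal-approximation contrast tests used for sex differences and for the
# frailty-versus-longevity (age-window) comparison, and the additive
# life-year arithmetic for multi-locus homozygote predictions.

#' Inverse-variance fixed-effect meta-analysis of log hazard ratios
#'
#' Weights are `1/se^2`; the combined estimate is the weighted mean with
#' standard error `1/sqrt(sum(w))`. The p-value uses the normal
#' approximation, two-sided by default; the one-sided option (half the
#' two-sided p, in the direction of the combined estimate) exists because
#' published replication p-values are sometimes reported that way. Cochran's
#' Q is reported for information only; no random-effects model is fitted.
#'
#' @param beta per-study log hazard ratios (parental scale).
#' @param se per-study standard errors, all > 0.
#' @param labels optional study labels.
#' @param alternative `"two.sided"` (default) or `"one.sided"`.
#' @return object of class `kin_meta`: `beta`, `se`, `hr`, `z`, `p`,
#'   normalized `weights`, `Q`, `Q_df`, `Q_p`.
#' @export
ivw_meta <- function(beta, se, labels = NULL,
                     alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (length(beta) < 1) stop("at least one study estimate is required")
  if (length(se) != length(beta)) stop("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    stop("all estimates must be finite with se > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(-abs(z))
  k <- length(beta)
  Q <- sum(w * (beta - b)^2)
  structure(list(beta = b, se = s, hr = exp(b), z = z, p = p,
                 weights = w / sum(w), Q = Q, Q_df = k - 1,
                 Q_p = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_,
                 k = k, labels = labels, alternative = alternative),
            class = "kin_meta")
}

#' @export
print.kin_meta <- function(x, ...) {
  cat(sprintf("IVW fixed-effect meta-analysis of %d estimates (%s)\n",
              x$k, x$alternative))
  cat(sprintf("  log-HR %.4f  (se %.4f)   HR %.3f   z %.3f   p %.3g\n",
              x$beta, x$se, x$hr, x$z, x$p))
  if (x$k > 1)
    cat(sprintf("  Cochran Q %.3f on %d df (p %.3g)\n", x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

#' Normal-approximation contrast between two stratum estimates
#'
#' Tests `beta2 - beta1 = 0` with standard error `sqrt(se1^2 + se2^2)` and a
#' two-sided normal p-value, as used for the father-versus-mother hazard
#' ratio comparison. With tens of thousands of deaths per stratum the
#' distinction between the normal and t references is immaterial.
#'
#' @param beta1,se1 first stratum estimate and standard error.
#' @param beta2,se2 second stratum estimate and standard error.
#' @return object of class `kin_contrast`: `diff` (beta2 - beta1), `se`,
#'   `z`, `p`.
#' @export
contrast_test <- function(beta1, se1, beta2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be > 0")
  d <- beta2 - beta1
  s <- sqrt(se1^2 + se2^2)
  z <- d / s
  structure(list(diff = d, se = s, z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "kin_contrast")
}

#' @export
print.kin_contrast <- function(x, ...) {
  cat(sprintf("contrast: diff %.4f (se %.4f), z %.3f, p %.4g\n",
              x$diff, x$se, x$z, x$p))
  invisible(x)
}

#' Contrast between younger and older age-window estimates
#'
#' Identical machinery to [contrast_test()], applied to the 40-75 and 75+
#' fits of the same stratum: a significant contrast with the larger effect
#' below 75 indicates a frailty locus, above 75 a longevity locus.
#'
#' @param beta_young,se_young estimate for the 40-75 window.
#' @param beta_old,se_old estimate for the 75+ window.
#' @return a `kin_contrast` (difference is old minus young).
#' @export
age_window_contrast <- function(beta_young, se_young, beta_old, se_old) {
  contrast_test(beta_young, se_young, beta_old, se_old)
}

#' Predicted life-year gap between double-risk and double-protective homozygotes
#'
#' Life-year effects are treated as additive across alleles and loci, so a
#' carrier of two risk alleles at each of the given loci differs from a
#' double-protective homozygote by twice the summed per-allele effects.
#'
#' @param per_allele_years per-locus, per-allele life-year reductions for one
#'   sex (positive values = years lost per allele).
#' @return years difference (scalar).
#' @export
combined_homozygote_years <- function(per_allele_years) {
  stopifnot(is.numeric(per_allele_years))
  2 * sum(per_allele_years)
}
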