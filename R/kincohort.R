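# The kin-cohort dosage expectation: what one offspring allele implies about
# the ungenotyped parent. Under random mating at allele frequency p, the
# non-transmitted parental allele is an independent Bernoulli(p) draw, so the
# expected parental dosage rises by exactly 1/2 per offspring allele, and
# effects measured on offspring dosage are half the per-parental-allele
# effects.

#' Expected parental dosage given offspring genotype
#'
#' For a counted allele with population frequency `p`: an offspring
#' homozygous for the other allele implies an expected parental dosage of `p`
#' (the chance the non-transmitted allele is the counted one); a counted-allele
#' homozygote implies `1 + p`; a heterozygote the average of the two,
#' `1/2 + p`.
#'
#' @param offspring_dose offspring dosage(s) in \{0,1,2\}.
#' @param p counted-allele frequency, strictly in (0,1).
#' @return expected parental dosage (alleles).
#' @export
expected_parent_dosage <- function(offspring_dose, p) {
  if (any(p <= 0 | p >= 1)) stop("allele frequency p must lie strictly inside (0, 1)")
  if (any(!offspring_dose %in% 0:2)) stop("offspring_dose must be 0, 1 or 2")
  out <- numeric(length(offspring_dose))
  out[offspring_dose == 0] <- p
  out[offspring_dose == 1] <- 0.5 + p
  out[offspring_dose == 2] <- 1 + p
  out
}

#' Analytic attenuation slope of parental on offspring dosage
#'
#' Least-squares slope of the expected parental dosage on offspring dosage,
#' with offspring genotypes weighted by their Hardy-Weinberg probabilities at
#' frequency `p`. Equals exactly 1/2 for every `p`: the kin-cohort
#' attenuation factor.
#'
#' @param p counted-allele frequency in (0,1).
#' @return the regression slope (dimensionless).
#' @export
attenuation_slope <- function(p) {
  d <- 0:2
  w <- stats::dbinom(d, 2, p)
  y <- expected_parent_dosage(d, p)
  xbar <- sum(w * d)
  ybar <- sum(w * y)
  sum(w * (d - xbar) * (y - ybar)) / sum(w * (d - xbar)^2)
}

#' Rescale an offspring-scale estimate to the parental allele scale
#'
#' Offspring dosage carries half a parental allele in expectation, so
#' estimates per offspring allele are doubled (point estimate and standard
#' error alike) to read per parental allele; z statistics and p-values are
#' unchanged. Applied at reporting time only; internal scans stay on the
#' offspring scale.
#'
#' @param beta_offspring log-HR (or score-scale effect) per offspring allele.
#' @param se its standard error, > 0.
#' @return list with `beta_parent` and `se_parent`.
#' @export
rescale_to_parent_scale <- function(beta_offspring, se) {
  if (any(se <= 0)) stop("standard errors must be > 0")
  list(beta_parent = 2 * beta_offspring, se_parent = 2 * se)
}
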