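# Synthetic trio-structured lifespan cohorts: HWE parental genotypes,
# Mendelian transmission to offspring, Gompertz mortality from age 40 with
# sex- and age-window-specific genotype effects, censoring of living parents
# at the offspring's interview, and contamination records for QC testing.

#' Per-variant causal effect table
#'
#' Builds the matrix of log hazard ratios per PARENTAL allele used by
#' [generate_cohort()]. Effects are piecewise-constant in parental age with a
#' single switch at 75 years, so frailty-type (young-age) and longevity-type
#' (old-age) architectures can both be simulated.
#'
#' @param father,mother log-HR per parental allele below age 75.
#' @param father_75plus,mother_75plus log-HR per parental allele at 75+;
#'   default to the sub-75 values (age-constant effect).
#' @param n_variants recycle scalars to this many variants.
#' @return numeric matrix with columns `father_40_75`, `father_75plus`,
#'   `mother_40_75`, `mother_75plus`.
#' @export
causal_effect_table <- function(father = 0, mother = father,
                                father_75plus = father,
                                mother_75plus = mother,
                                n_variants = NULL) {
  n <- n_variants %||% max(length(father), length(mother),
                           length(father_75plus), length(mother_75plus))
  out <- cbind(father_40_75 = rep_len(father, n),
               father_75plus = rep_len(father_75plus, n),
               mother_40_75 = rep_len(mother, n),
               mother_75plus = rep_len(mother_75plus, n))
  rownames(out) <- paste0("v", seq_len(n))
  out
}

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic kin cohort. Defaults mirror a
#' middle-aged population cohort: offspring interviewed at ages 40-69, parents
#' 20-35 years older, parental mortality Gompertz from age 40 with hazard
#' `a * exp(b * (age - 40))` giving mean ages at death in the mid 70s, and
#' contamination rates (adopted subjects, missing parental data, implausible
#' ages, missing covariates, pre-40 parental deaths) loosely matching the
#' proportions such questionnaires produce.
#'
#' @param n_subjects number of genotyped offspring (each contributes a father
#'   and a mother record).
#' @param n_variants number of independent variants.
#' @param allele_freqs effect (counted) allele frequency per variant, in (0,1).
#' @param causal_effects matrix from [causal_effect_table()]: log-HR per
#'   parental allele, by parent sex and age window. NULL means all zero.
#' @param gompertz_a baseline hazard (1/year) at age 40, per parent sex
#'   (scalar recycled to both sexes).
#' @param gompertz_b log-hazard slope (1/year), per parent sex.
#' @param covariate_spec list with `n` (count of standard-normal subject-level
#'   covariates, standing in for assessment centre, batch, deprivation and
#'   principal components) and `effects` (their log-HRs on parental mortality).
#' @param interview_age_range offspring age at interview (years, uniform).
#' @param parent_offset_range parent age minus offspring age at interview
#'   (years, uniform, drawn independently per parent).
#' @param contamination_rates named fractions: `adopted`, `missing_parents`,
#'   `implausible_age`, `missing_covariate`, `pre40_death`.
#' @param seed integer global seed; identical configs give bit-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20000L,
                       n_variants = 2L,
                       allele_freqs = rep(0.3, n_variants),
                       causal_effects = NULL,
                       gompertz_a = c(father = 0.002, mother = 0.002),
                       gompertz_b = c(father = 0.095, mother = 0.095),
                       covariate_spec = list(n = 4L,
                                             effects = c(0.10, 0.10, -0.10, 0.05)),
                       interview_age_range = c(40, 69),
                       parent_offset_range = c(20, 35),
                       contamination_rates = c(adopted = 0.015,
                                               missing_parents = 0.02,
                                               implausible_age = 1e-4,
                                               missing_covariate = 0.0012,
                                               pre40_death = 0.01),
                       seed = 1L) {
  if (length(gompertz_a) == 1) gompertz_a <- c(father = gompertz_a, mother = gompertz_a)
  if (length(gompertz_b) == 1) gompertz_b <- c(father = gompertz_b, mother = gompertz_b)
  if (is.null(causal_effects))
    causal_effects <- causal_effect_table(0, n_variants = n_variants)
  if (n_subjects < 1 || n_variants < 1)
    stop("n_subjects and n_variants must be >= 1")
  if (length(allele_freqs) != n_variants)
    stop("allele_freqs must have one entry per variant (", n_variants, ")")
  if (any(allele_freqs <= 0) || any(allele_freqs >= 1))
    stop("all allele_freqs must lie strictly inside (0, 1)")
  if (any(gompertz_a <= 0)) stop("gompertz_a must be > 0")
  if (nrow(causal_effects) != n_variants)
    stop("causal_effects has ", nrow(causal_effects),
         " rows but n_variants is ", n_variants)
  if (length(covariate_spec$effects) != covariate_spec$n)
    stop("covariate_spec$effects must have length covariate_spec$n")
  rt <- c("adopted", "missing_parents", "implausible_age",
          "missing_covariate", "pre40_death")
  miss <- setdiff(rt, names(contamination_rates))
  if (length(miss)) contamination_rates[miss] <- 0
  structure(list(n_subjects = as.integer(n_subjects),
                 n_variants = as.integer(n_variants),
                 allele_freqs = allele_freqs,
                 causal_effects = causal_effects,
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 covariate_spec = covariate_spec,
                 interview_age_range = interview_age_range,
                 parent_offset_range = parent_offset_range,
                 contamination_rates = contamination_rates[rt],
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw parental genotypes under Hardy-Weinberg equilibrium
#'
#' @param n number of couples.
#' @param p counted-allele frequency, strictly in (0,1).
#' @return list with integer vectors `father` and `mother` (0/1/2), drawn
#'   i.i.d. Binomial(2, p), fathers independent of mothers.
#' @export
draw_parent_genotypes <- function(n, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("allele frequency p must lie strictly inside (0, 1)")
  list(father = stats::rbinom(n, 2L, p), mother = stats::rbinom(n, 2L, p))
}

#' Transmit one allele from each parent to the offspring
#'
#' One allele is drawn uniformly from each parent's two alleles and the
#' transmitted counted-allele copies are summed, so the offspring dosage is
#' always Mendelian-consistent with the parental genotypes.
#'
#' @param father,mother integer genotypes in \{0,1,2\} (vectors allowed).
#' @return integer offspring dosage in \{0,1,2\}.
#' @export
transmit_offspring_dosage <- function(father, mother) {
  if (any(!father %in% 0:2) || any(!mother %in% 0:2))
    stop("parental genotypes must be 0, 1 or 2")
  stats::rbinom(length(father), 1L, father / 2) +
    stats::rbinom(length(mother), 1L, mother / 2)
}

#' Sample a Gompertz death age by exact inverse-CDF
#'
#' The hazard from age `entry` is `a * exp(eta) * exp(b * (t - entry))`.
#' Inverting the survival function at `u` gives
#' `entry + log(1 - b*log(u)/(a*exp(eta)))/b`, with the exponential limit
#' `entry - log(u)/(a*exp(eta))` at `b = 0`.
#'
#' @param a hazard at `entry` (1/year), > 0.
#' @param b log-hazard slope (1/year).
#' @param eta linear predictor on the log-hazard scale.
#' @param u uniform(0,1) draw(s), strictly inside (0,1).
#' @param entry entry age in years (default 40).
#' @return death age(s) in years, > `entry`.
#' @export
sample_gompertz_lifespan <- function(a, b, eta = 0, u, entry = 40) {
  if (any(a <= 0)) stop("Gompertz scale a must be > 0")
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  h <- a * exp(eta)
  if (all(b == 0)) return(entry - log(u) / h)
  entry + log1p(-b * log(u) / h) / b
}

#' Analytic Gompertz CDF of the death age
#'
#' @inheritParams sample_gompertz_lifespan
#' @param t age in years.
#' @return P(death age <= t) for the hazard of [sample_gompertz_lifespan()].
#' @export
gompertz_cdf <- function(t, a, b, eta = 0, entry = 40) {
  h <- a * exp(eta)
  H <- if (b == 0) h * pmax(t - entry, 0) else
    (h / b) * (exp(b * pmax(t - entry, 0)) - 1)
  1 - exp(-H)
}

# Piecewise Gompertz sampler: log-HR eta_young below `split`, eta_old above.
# Exact inverse of the piecewise cumulative hazard.
piecewise_gompertz_lifespan <- function(a, b, eta_young, eta_old, u,
                                        entry = 40, split = 75) {
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly inside (0, 1)")
  E <- -log(u)
  hy <- a * exp(eta_young)
  ho <- a * exp(eta_old)
  if (b == 0) {
    H_split <- hy * (split - entry)
    t <- ifelse(E <= H_split,
                entry + E / hy,
                split + (E - H_split) / ho)
    return(t)
  }
  eb <- exp(b * (split - entry))
  H_split <- (hy / b) * (eb - 1)
  young <- E <= H_split
  t <- numeric(length(E))
  t[young] <- entry + log1p(b * E[young] / hy[young]) / b
  rem <- E[!young] - H_split[!young]
  t[!young] <- entry + log(eb + b * rem / ho[!young]) / b
  t
}

#' Censor a parental lifespan at the offspring's interview
#'
#' @param true_death_age latent death age (years).
#' @param parent_age_at_interview parent's age when the offspring was
#'   interviewed (years).
#' @return list with `observed_age` and `event` (1 = died before interview,
#'   0 = alive at interview and censored there).
#' @export
apply_interview_censoring <- function(true_death_age, parent_age_at_interview) {
  if (any(true_death_age < 0) || any(parent_age_at_interview < 0))
    stop("ages must be non-negative")
  dead <- true_death_age <= parent_age_at_interview
  list(observed_age = ifelse(dead, true_death_age, parent_age_at_interview),
       event = as.integer(dead))
}

#' Generate a synthetic kin cohort
#'
#' Draws parental genotypes under HWE, transmits alleles to offspring,
#' simulates parental lifespans from a sex-specific Gompertz hazard with
#' configured genotype and covariate effects (piecewise-constant in age,
#' switching at 75), censors living parents at the offspring interview, and
#' injects contamination records at the configured rates. Deterministic given
#' the config (including its seed); sub-streams are independently seeded via
#' [stream_seed()].
#'
#' @param config a [sim_config()].
#' @return A list of class `kin_cohort` with elements `pheno` (long phenotype
#'   table, one row per parent record), `geno` (a `kin_genotypes` object:
#'   offspring dosage matrix subjects x variants plus variant metadata) and
#'   `truth` (configured effects, latent parental genotypes and death ages,
#'   contamination indices).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_subjects
  V <- config$n_variants
  eff <- config$causal_effects

  set.seed(stream_seed(config$seed, "genotypes"))
  gf <- gm <- go <- matrix(0L, n, V)
  for (v in seq_len(V)) {
    gp <- draw_parent_genotypes(n, config$allele_freqs[v])
    gf[, v] <- gp$father
    gm[, v] <- gp$mother
    go[, v] <- transmit_offspring_dosage(gp$father, gp$mother)
  }

  set.seed(stream_seed(config$seed, "covariates"))
  k <- config$covariate_spec$n
  Z <- matrix(stats::rnorm(n * k), n, k)
  colnames(Z) <- paste0("covariate_", seq_len(k))

  set.seed(stream_seed(config$seed, "ages"))
  iage <- stats::runif(n, config$interview_age_range[1], config$interview_age_range[2])
  page_f <- iage + stats::runif(n, config$parent_offset_range[1], config$parent_offset_range[2])
  page_m <- iage + stats::runif(n, config$parent_offset_range[1], config$parent_offset_range[2])

  set.seed(stream_seed(config$seed, "lifespans"))
  zeff <- as.numeric(Z %*% config$covariate_spec$effects)
  death_f <- piecewise_gompertz_lifespan(
    config$gompertz_a[["father"]], config$gompertz_b[["father"]],
    zeff + as.numeric(gf %*% eff[, "father_40_75"]),
    zeff + as.numeric(gf %*% eff[, "father_75plus"]),
    stats::runif(n))
  death_m <- piecewise_gompertz_lifespan(
    config$gompertz_a[["mother"]], config$gompertz_b[["mother"]],
    zeff + as.numeric(gm %*% eff[, "mother_40_75"]),
    zeff + as.numeric(gm %*% eff[, "mother_75plus"]),
    stats::runif(n))
  cf <- apply_interview_censoring(death_f, page_f)
  cm <- apply_interview_censoring(death_m, page_m)
  obs_f <- cf$observed_age; ev_f <- cf$event
  obs_m <- cm$observed_age; ev_m <- cm$event

  set.seed(stream_seed(config$seed, "contamination"))
  r <- config$contamination_rates
  pick <- function(rate) which(stats::runif(n) < rate)
  adopted_idx <- pick(r[["adopted"]])
  missing_idx <- pick(r[["missing_parents"]])
  implaus_idx <- pick(r[["implausible_age"]])
  misscov_idx <- pick(r[["missing_covariate"]])
  pre40_idx <- pick(r[["pre40_death"]])

  adopted <- rep(FALSE, n)
  adopted[adopted_idx] <- TRUE
  if (length(missing_idx)) {
    obs_f[missing_idx] <- NA_real_; ev_f[missing_idx] <- NA_integer_
    obs_m[missing_idx] <- NA_real_; ev_m[missing_idx] <- NA_integer_
  }
  side <- function(idx) stats::runif(length(idx)) < 0.5  # father or mother hit
  if (length(implaus_idx)) {
    s <- side(implaus_idx)
    i_f <- implaus_idx[s]; i_m <- implaus_idx[!s]
    obs_f[i_f] <- stats::runif(length(i_f), 116, 130)
    obs_m[i_m] <- stats::runif(length(i_m), 116, 130)
  }
  if (length(pre40_idx)) {
    s <- side(pre40_idx)
    i_f <- pre40_idx[s]; i_m <- pre40_idx[!s]
    obs_f[i_f] <- stats::runif(length(i_f), 18, 39.5); ev_f[i_f] <- 1L
    obs_m[i_m] <- stats::runif(length(i_m), 18, 39.5); ev_m[i_m] <- 1L
  }
  if (length(misscov_idx))
    Z[cbind(misscov_idx, sample.int(k, length(misscov_idx), replace = TRUE))] <- NA_real_

  pheno <- data.frame(subject_id = rep.int(seq_len(n), 2L),
                      parent = rep(c("father", "mother"), each = n),
                      entry = 40,
                      observed_age = c(obs_f, obs_m),
                      event = c(ev_f, ev_m),
                      adopted = rep(adopted, 2L),
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(Z[rep.int(seq_len(n), 2L), , drop = FALSE]))
  rownames(pheno) <- NULL

  rownames(go) <- as.character(seq_len(n))
  info <- data.frame(snp = rownames(eff) %||% paste0("v", seq_len(V)),
                     chr = 1L, bp = 1000000L * seq_len(V),
                     a1 = "A", a0 = "G",
                     freq = config$allele_freqs,
                     stringsAsFactors = FALSE)
  geno <- kin_genotypes(go, info)

  truth <- list(config = config,
                effects = eff,
                parent_genotypes = list(father = gf, mother = gm),
                true_death_age = list(father = death_f, mother = death_m),
                parent_age_at_interview = list(father = page_f, mother = page_m),
                contamination = list(adopted = adopted_idx,
                                     missing_parents = missing_idx,
                                     implausible_age = implaus_idx,
                                     missing_covariate = misscov_idx,
                                     pre40_death = pre40_idx))
  structure(list(pheno = pheno, geno = geno, truth = truth),
            class = "kin_cohort")
}

#' Dosage matrix with variant metadata
#'
#' @param dosage numeric matrix, subjects x variants, values in [0,2];
#'   rownames are subject ids.
#' @param info data.frame with one row per variant: `snp`, `chr`, `bp`, `a1`
#'   (counted allele) and optionally `a0`, `freq`.
#' @return An object of class `kin_genotypes`.
#' @export
kin_genotypes <- function(dosage, info) {
  stopifnot(is.matrix(dosage), nrow(info) == ncol(dosage))
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- as.character(seq_len(nrow(dosage)))
  colnames(dosage) <- info$snp
  structure(list(dosage = dosage, info = info), class = "kin_genotypes")
}

#' @export
print.kin_genotypes <- function(x, ...) {
  cat("kin_genotypes:", nrow(x$dosage), "subjects x", ncol(x$dosage), "variants\n")
  invisible(x)
}

#' Generate a causal variant and a correlated proxy
#'
#' Haplotype-level generator for conditional-scan tests: each parental
#' haplotype carries the causal allele (Bernoulli `p`) and a proxy allele that
#' copies it with probability `rho` (else an independent Bernoulli `p` draw),
#' giving allelic and dosage correlation `rho`. One haplotype per parent is
#' transmitted, so the linkage survives into the offspring.
#'
#' @param n number of trios.
#' @param p shared allele frequency.
#' @param rho allele-level correlation between the pair, in [0,1].
#' @return list of 2-column dosage matrices (`causal`, `proxy` columns):
#'   `father`, `mother`, `offspring`.
#' @export
draw_ld_pair <- function(n, p, rho) {
  if (p <= 0 || p >= 1) stop("allele frequency p must lie strictly inside (0, 1)")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  hap <- function() {
    a <- stats::rbinom(n, 1L, p)
    b <- ifelse(stats::runif(n) < rho, a, stats::rbinom(n, 1L, p))
    cbind(a = a, b = b)
  }
  one_parent <- function() list(h1 = hap(), h2 = hap())
  fa <- one_parent(); mo <- one_parent()
  transmit <- function(par) {
    use1 <- stats::runif(n) < 0.5
    cbind(ifelse(use1, par$h1[, "a"], par$h2[, "a"]),
          ifelse(use1, par$h1[, "b"], par$h2[, "b"]))
  }
  off <- transmit(fa) + transmit(mo)
  geno <- function(par) par$h1 + par$h2
  dimnames(off) <- list(NULL, c("causal", "proxy"))
  list(father = `colnames<-`(geno(fa), c("causal", "proxy")),
       mother = `colnames<-`(geno(mo), c("causal", "proxy")),
       offspring = off)
}
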