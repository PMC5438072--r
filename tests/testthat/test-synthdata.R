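# Synthetic cohort generator: HWE sampling, Mendelian transmission, Gompertz
# lifespans, interview censoring, determinism.

test_that("parental genotype draws follow binomial HWE sampling", {
  expect_error(draw_parent_genotypes(10, 1.2), "inside")
  expect_error(draw_parent_genotypes(10, 0), "inside")

  set.seed(11)
  g0 <- draw_parent_genotypes(100, 1e-12)
  expect_true(all(g0$father == 0) && all(g0$mother == 0))

  set.seed(12)
  g <- draw_parent_genotypes(1e5, 0.5)
  prop <- tabulate(g$father + 1L, 3L) / 1e5
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(prop - c(0.25, 0.5, 0.25)) < 4 * se))

  set.seed(13)
  g <- draw_parent_genotypes(1e5, 0.3)
  expect_lt(abs(mean(g$mother) - 0.6), 4 * stats::sd(g$mother) / sqrt(1e5))
})

test_that("Mendelian transmission matches the gamete enumeration", {
  set.seed(21)
  expect_true(all(transmit_offspring_dosage(rep(0L, 50), rep(0L, 50)) == 0))
  expect_true(all(transmit_offspring_dosage(rep(2L, 50), rep(2L, 50)) == 2))
  expect_true(all(transmit_offspring_dosage(rep(2L, 50), rep(0L, 50)) == 1))
  expect_error(transmit_offspring_dosage(3, 1), "must be 0, 1 or 2")

  # 1 x 1 cross: four equiprobable gamete pairs give (1/4, 1/2, 1/4)
  set.seed(22)
  d <- transmit_offspring_dosage(rep(1L, 1e5), rep(1L, 1e5))
  prop <- tabulate(d + 1L, 3L) / 1e5
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(prop - c(0.25, 0.5, 0.25)) < 4 * se))
})

test_that("generated trios are Mendelian-consistent with matching allele frequency", {
  freqs <- c(0.3, 0.1)
  cfg <- sim_config(n_subjects = 20000, n_variants = 2, allele_freqs = freqs,
                    seed = 5)
  co <- generate_cohort(cfg)
  gf <- co$truth$parent_genotypes$father
  gm <- co$truth$parent_genotypes$mother
  go <- co$geno$dosage
  lo <- (gf == 2) + (gm == 2)
  hi <- 2 - ((gf == 0) + (gm == 0))
  expect_true(all(go >= lo & go <= hi))  # exhaustive Mendelian check
  for (v in 1:2) {
    p <- freqs[v]
    se_freq <- sqrt(2 * p * (1 - p)) / (2 * sqrt(nrow(go)))
    expect_lt(abs(mean(go[, v]) / 2 - p), 4 * se_freq)
  }
})

test_that("Gompertz sampler is the exact inverse CDF", {
  # exponential limit: 40 + 1/a at u = exp(-1)
  expect_equal(sample_gompertz_lifespan(0.05, 0, 0, exp(-1)), 60)
  # closed-form median against a numeric root of S(t) = 1/2
  med <- sample_gompertz_lifespan(0.01, 0.1, 0, 0.5)
  expect_equal(med, 40 + log(1 + 0.1 * log(2) / 0.01) / 0.1, tolerance = 1e-12)
  root <- stats::uniroot(function(t) gompertz_cdf(t, 0.01, 0.1) - 0.5,
                         c(40, 400), tol = 1e-12)$root
  expect_equal(med, root, tolerance = 1e-9)
  # huge hazard: death immediately after entry
  x <- sample_gompertz_lifespan(0.05, 0.1, 10, 0.5)
  expect_gt(x, 40); expect_lt(x, 40.1)
  expect_error(sample_gompertz_lifespan(0.05, 0.1, 0, 1.5), "inside")
  expect_error(sample_gompertz_lifespan(-1, 0.1, 0, 0.5), "> 0")
})

test_that("simulated death ages follow the analytic Gompertz CDF", {
  set.seed(31)
  x <- sample_gompertz_lifespan(0.002, 0.095, 0, stats::runif(1e4))
  ks <- suppressWarnings(
    stats::ks.test(x, function(t) gompertz_cdf(t, 0.002, 0.095)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e4))  # 1% critical value
})

test_that("piecewise lifespan sampler agrees with the single-window sampler", {
  set.seed(32)
  u <- stats::runif(200)
  eta <- stats::rnorm(200, 0, 0.3)
  expect_equal(
    kinspan:::piecewise_gompertz_lifespan(0.002, 0.095, eta, eta, u),
    sample_gompertz_lifespan(0.002, 0.095, eta, u),
    tolerance = 1e-10)
  # with a much higher old-age hazard, deaths beyond 75 are pulled toward 75
  lo <- kinspan:::piecewise_gompertz_lifespan(0.002, 0.095, eta * 0, eta * 0 + 3,
                                              u)
  hi <- sample_gompertz_lifespan(0.002, 0.095, 0, u)
  expect_true(all(lo <= hi + 1e-12))
  expect_true(all(lo[hi > 75] <= hi[hi > 75]))
})

test_that("interview censoring truncates and flags correctly", {
  c1 <- apply_interview_censoring(70, 65)
  expect_equal(c1$observed_age, 65); expect_equal(c1$event, 0L)
  c2 <- apply_interview_censoring(70, 80)
  expect_equal(c2$observed_age, 70); expect_equal(c2$event, 1L)
  expect_error(apply_interview_censoring(-1, 50), "non-negative")
})

test_that("marginal dead fraction matches an independent Monte-Carlo oracle", {
  cfg <- sim_config(n_subjects = 20000, n_variants = 1,
                    covariate_spec = list(n = 2, effects = c(0, 0)),
                    contamination_rates = c(adopted = 0, missing_parents = 0,
                                            implausible_age = 0,
                                            missing_covariate = 0,
                                            pre40_death = 0),
                    seed = 33)
  co <- generate_cohort(cfg)
  frac <- mean(co$pheno$event)
  # oracle: conditional death probability integrated over the age model
  set.seed(1234)
  page <- stats::runif(1e5, 40, 69) + stats::runif(1e5, 20, 35)
  oracle <- mean(gompertz_cdf(page, 0.002, 0.095))
  tol <- 4 * sqrt(0.25 / nrow(co$pheno)) + 3 * sqrt(0.25 / 1e5)
  expect_lt(abs(frac - oracle), tol)
})

test_that("identical config (including seed) gives bit-identical cohorts", {
  cfg <- sim_config(n_subjects = 500, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$truth$true_death_age, b$truth$true_death_age)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(allele_freqs = c(0, 0.5), n_variants = 2), "inside")
  expect_error(sim_config(n_variants = 2,
                          causal_effects = causal_effect_table(0.1, n_variants = 3)),
               "rows")
  expect_error(sim_config(gompertz_a = -1), "gompertz_a")
  expect_error(sim_config(n_subjects = 0), ">= 1")
})

test_that("correlated-pair generator hits the requested LD and stays Mendelian", {
  set.seed(44)
  ld <- draw_ld_pair(20000, 0.3, 0.9)
  expect_lt(abs(stats::cor(ld$father[, "causal"], ld$father[, "proxy"]) - 0.9), 0.03)
  expect_lt(abs(stats::cor(ld$offspring[, "causal"], ld$offspring[, "proxy"]) - 0.9), 0.03)
  for (v in c("causal", "proxy")) {
    lo <- (ld$father[, v] == 2) + (ld$mother[, v] == 2)
    hi <- 2 - ((ld$father[, v] == 0) + (ld$mother[, v] == 0))
    expect_true(all(ld$offspring[, v] >= lo & ld$offspring[, v] <= hi))
  }
})
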