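# Cox engine: baseline hazard, partial-likelihood fit against a brute-force
# oracle, Martingale residuals, restricted-mean life years, age windows.

library(survival)

test_that("constant covariate yields beta 0 and a Nelson-Aalen baseline", {
  set.seed(51)
  rec <- data.frame(entry = 40,
                    observed_age = 40 + rexp(200, 0.05),
                    event = rbinom(200, 1, 0.7),
                    z = 0)
  rec$event[1] <- 1L
  fit <- fit_cox(rec, covariates = "z")
  expect_equal(unname(fit$coefficients["z"]), 0)
  sf <- survfit(Surv(entry, observed_age, event) ~ 1, data = rec)
  na_ch <- sf$cumhaz[sf$n.event > 0]
  expect_equal(fit$basehaz$cumhaz, na_ch, tolerance = 1e-10)
})

test_that("fit_cox matches a brute-force partial-likelihood grid search", {
  rec <- make_six_records()
  fit <- fit_cox(rec, covariates = "x", ties = "breslow")
  grid <- seq(-5, 5, by = 1e-4)
  oracle <- grid[which.max(grid_partial_likelihood(rec, grid))]
  expect_lt(abs(unname(fit$coefficients["x"]) - oracle), 1e-3)
})

test_that("two-group exponential simulation recovers HR 2", {
  set.seed(52)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  death <- 40 + rexp(n, 0.05 * 2^x)
  cens <- 40 + runif(n, 5, 40)
  rec <- data.frame(entry = 40,
                    observed_age = pmin(death, cens),
                    event = as.integer(death <= cens),
                    x = x)
  fit <- fit_cox(rec, covariates = "x")
  se <- sqrt(fit$vcov["x", "x"])
  expect_lt(abs(fit$coefficients[["x"]] - log(2)), 3 * se)
})

test_that("degenerate survival inputs raise informative errors", {
  rec <- make_six_records()
  rec0 <- rec; rec0$event <- 0L
  expect_error(fit_cox(rec0, covariates = "x"), "no events")
  recbad <- rec; recbad$observed_age[1] <- 40
  expect_error(fit_cox(recbad, covariates = "x"), "exceed")
  expect_error(fit_cox(rec, covariates = "nope"), "nope")
})

test_that("all-censored data give a zero cumulative hazard (all residuals 0)", {
  bh <- breslow_cumhaz(rep(40, 5), 41:45, rep(0L, 5))
  expect_equal(nrow(bh), 0)
  expect_equal(kinspan:::.cumhaz_interval(bh, rep(40, 5), 41:45), rep(0, 5))
})

test_that("single death at the first event time gives the hand Breslow residuals", {
  rec <- data.frame(entry = 40,
                    observed_age = c(50, 60, 65, 70, 75),
                    event = c(1L, 0L, 0L, 0L, 0L))
  fit <- fit_cox(rec, covariates = NULL)
  m <- martingale_residuals(fit)
  expect_equal(m[1], 1 - 1/5)
  expect_equal(m[-1], rep(-1/5, 4))
})

test_that("Martingale residuals sum to zero and match the survival package", {
  for (seed in c(61, 62)) {
    cfg <- sim_config(n_subjects = 800, n_variants = 1, seed = seed)
    co <- generate_cohort(cfg)
    rec <- stratum_records(apply_exclusions(co$pheno)$clean, "father")
    for (ties in c("breslow", "efron")) {
      fit <- fit_cox(rec, covariates = paste0("covariate_", 1:4), ties = ties)
      m <- martingale_residuals(fit)
      expect_lt(abs(sum(m)), 1e-8)
      expect_true(all(m <= 1))
    }
    # dual route: survival's own martingale residuals, Breslow ties
    fitb <- fit_cox(rec, covariates = paste0("covariate_", 1:4), ties = "breslow")
    ref <- coxph(Surv(entry, observed_age, event) ~ covariate_1 + covariate_2 +
                   covariate_3 + covariate_4, data = rec, ties = "breslow")
    expect_equal(martingale_residuals(fitb),
                 unname(residuals(ref, type = "martingale")),
                 tolerance = 1e-8)
  }
})

test_that("residuals refuse records that do not match the fit", {
  rec <- make_six_records()
  fit <- fit_cox(rec, covariates = "x")
  other <- rec; other$observed_age[2] <- 56
  expect_error(martingale_residuals(fit, other), "do not match")
  expect_silent(martingale_residuals(fit, rec))
})

test_that("covariate effects are recovered within 3 s.e. on simulated cohorts", {
  cfg <- sim_config(n_subjects = 2500, n_variants = 1,
                    covariate_spec = list(n = 3, effects = c(0.2, -0.1, 0.15)),
                    seed = 63)
  co <- generate_cohort(cfg)
  rec <- apply_exclusions(co$pheno)$clean  # both parents: independent records
  fit <- fit_cox(rec, covariates = paste0("covariate_", 1:3))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$coefficients - c(0.2, -0.1, 0.15)) < 3 * se))
})

test_that("restricted-mean life years reduce to the right closed forms", {
  # no censoring: arithmetic mean of min(death age, horizon)
  rec <- data.frame(entry = 40,
                    observed_age = c(55, 62, 71, 80, 90),
                    event = 1L)
  g <- rep("a", 5)
  ly <- km_life_years(rec, g, horizon = 85)
  expect_equal(ly$life_years, mean(pmin(rec$observed_age, 85)) - 40)
  # all censored: curve stays at 1 up to the horizon
  recc <- rec; recc$event <- 0L
  lyc <- km_life_years(recc, g, horizon = 85)
  expect_equal(lyc$life_years, 85 - 40)
  expect_error(km_life_years(rec, rep("a", 4)), "length")
})

test_that("life years decrease under an added positive hazard shift", {
  set.seed(64)
  n <- 4000
  mk <- function(eta) {
    death <- sample_gompertz_lifespan(0.002, 0.095, eta, runif(n))
    cens <- 40 + runif(n, 25, 60)
    data.frame(entry = 40, observed_age = pmin(death, cens),
               event = as.integer(death <= cens))
  }
  r0 <- mk(0); r1 <- mk(0.5)
  rec <- rbind(r0, r1)
  g <- rep(c("base", "shifted"), each = n)
  ly <- km_life_years(rec, g, horizon = 90)
  expect_gt(ly$life_years[ly$group == "base"],
            ly$life_years[ly$group == "shifted"])
})

test_that("age-window transforms follow the truncation and left-entry rules", {
  rec <- data.frame(entry = 40,
                    observed_age = c(80, 60, 74.5, 75 + 1e-9, 90),
                    event = c(1L, 1L, 1L, 0L, 0L))
  young <- truncate_age_window(rec, "40-75")
  expect_equal(young$observed_age, c(75, 60, 74.5, 75, 75))
  expect_equal(young$event, c(0L, 1L, 1L, 0L, 0L))
  old <- truncate_age_window(rec, "75+")
  expect_equal(nrow(old), 3)            # deaths/censoring at <=75 dropped
  expect_true(all(old$entry == 75))
  expect_equal(old$observed_age, c(80, 75 + 1e-9, 90))
})
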