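# Shared fixtures, all built in code.

# 11-subject phenotype table with one violation of each subject-level rule
# plus one single-parent pre-40 death; hand-counted expectations live in
# test-phenoqc.R.
make_qc_fixture <- function() {
  n <- 11
  ph <- data.frame(subject_id = rep(1:n, 2),
                   parent = rep(c("father", "mother"), each = n),
                   entry = 40,
                   observed_age = c(rep(80, n), rep(85, n)),
                   event = c(rep(1L, n), rep(0L, n)),
                   adopted = FALSE,
                   covariate_1 = 0.5,
                   stringsAsFactors = FALSE)
  fa <- function(i) which(ph$subject_id == i & ph$parent == "father")
  ph$adopted[ph$subject_id == 2] <- TRUE
  ph$observed_age[fa(3)] <- 120            # implausible father age
  ph$covariate_1[ph$subject_id == 4] <- NA # missing covariate
  ph$observed_age[fa(5)] <- 38             # father dead at 38, mother valid
  ph$event[fa(5)] <- 1L
  ph
}

# 6 records, distinct times, one binary covariate; small enough for a
# brute-force partial-likelihood grid search.
make_six_records <- function() {
  data.frame(entry = 40,
             observed_age = c(50, 55, 60, 65, 70, 72),
             event = c(1L, 1L, 0L, 1L, 0L, 1L),
             x = c(1, 0, 1, 1, 0, 0))
}

# Breslow log partial likelihood for one binary covariate, vectorised over a
# beta grid: independent oracle for fit_cox.
grid_partial_likelihood <- function(records, beta_grid) {
  ev <- which(records$event == 1)
  sum_x_events <- sum(records$x[ev])
  logpl <- beta_grid * sum_x_events
  for (t in records$observed_age[ev]) {
    risk <- records$observed_age >= t & records$entry < t
    n1 <- sum(records$x[risk] == 1)
    n0 <- sum(risk) - n1
    logpl <- logpl - log(n0 + n1 * exp(beta_grid))
  }
  logpl
}

# records of a generated cohort restricted to one parent stratum
stratum_records <- function(cohort_clean, sex) {
  cohort_clean[cohort_clean$parent == sex, , drop = FALSE]
}

# absolute-tolerance comparison for printed-precision checks
expect_close <- function(actual, printed, tol) {
  testthat::expect_lt(abs(actual - printed), tol)
}
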