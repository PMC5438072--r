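# IVW meta-analysis, contrast tests, life-year arithmetic. The frozen
# expectations are the published combined values, re-derivable from the
# bundled per-stratum estimates.

pub <- kin_published_estimates()
strat <- function(v, pop, par, win = "40+")
  pub[pub$variant == v & pub$population == pop & pub$parent == par &
        pub$window == win, ]

test_that("IVW meta reproduces the published discovery combinations", {
  fa <- strat("rs10519203", "genetically_british", "father")
  mo <- strat("rs10519203", "genetically_british", "mother")
  m <- ivw_meta(c(fa$beta, mo$beta), c(fa$se, mo$se))
  expect_close(m$beta, 0.0552, 1e-4)
  expect_close(m$hr, 1.057, 5e-4)
  expect_close(m$se, 0.0076, 1e-4)

  fa <- strat("rs429358", "genetically_british", "father")
  mo <- strat("rs429358", "genetically_british", "mother")
  m <- ivw_meta(c(fa$beta, mo$beta), c(fa$se, mo$se))
  expect_close(m$beta, 0.1086, 1e-4)
  expect_close(m$hr, 1.115, 5e-4)
  expect_close(m$se, 0.0122, 1e-4)
})

test_that("IVW meta reproduces the published replication and overall rows", {
  for (v in c("rs429358", "rs10519203")) {
    reps <- pub[pub$variant == v & pub$table == 1 & !pub$combined &
                  pub$population %in% c("declared_british", "other_origins",
                                        "estonian"), ]
    mrep <- ivw_meta(reps$beta, reps$se)
    printed_rep <- strat(v, "replication", "both")
    expect_close(mrep$beta, printed_rep$beta, 1e-4)
    expect_close(mrep$se, printed_rep$se, 1e-4)

    disc <- strat(v, "discovery", "both")
    mall <- ivw_meta(c(disc$beta, printed_rep$beta), c(disc$se, printed_rep$se))
    printed_all <- strat(v, "overall", "both")
    expect_close(mall$beta, printed_all$beta, 1e-4)
    expect_close(mall$hr, printed_all$hr, 5e-4)
    expect_close(mall$se, printed_all$se, 1e-4)
  }
})

test_that("IVW algebra: identical studies shrink s.e. by sqrt(k)", {
  m2 <- ivw_meta(c(0.07, 0.07), c(0.02, 0.02))
  expect_equal(m2$beta, 0.07)
  expect_equal(m2$se, 0.02 / sqrt(2))
  m5 <- ivw_meta(rep(0.07, 5), rep(0.02, 5))
  expect_equal(m5$se, 0.02 / sqrt(5))
  expect_error(ivw_meta(numeric(0), numeric(0)), "at least one")
  expect_error(ivw_meta(0.1, 0), "se > 0")
})

test_that("combined estimate stays inside the inputs with no larger s.e.", {
  set.seed(81)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    b <- rnorm(k, 0.05, 0.05)
    s <- runif(k, 0.005, 0.08)
    m <- ivw_meta(b, s)
    expect_lte(m$se, min(s))
    expect_gte(m$beta, min(b)); expect_lte(m$beta, max(b))
    expect_equal(sum(m$weights), 1)
  }
})

test_that("IVW matches metafor's fixed-effect model", {
  library(metafor)
  set.seed(82)
  b <- rnorm(4, 0.08, 0.03)
  s <- runif(4, 0.01, 0.05)
  m <- ivw_meta(b, s)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("sex contrast reproduces the published p-values", {
  fa <- strat("rs429358", "genetically_british", "father")
  mo <- strat("rs429358", "genetically_british", "mother")
  ct <- contrast_test(fa$beta, fa$se, mo$beta, mo$se)
  expect_equal(signif(ct$p, 2), 0.011)

  fa <- strat("rs10519203", "genetically_british", "father")
  mo <- strat("rs10519203", "genetically_british", "mother")
  ct <- contrast_test(fa$beta, fa$se, mo$beta, mo$se)
  expect_equal(signif(ct$p, 2), 0.075)

  eq <- contrast_test(0.1, 0.02, 0.1, 0.03)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(contrast_test(0.1, 0, 0.2, 0.01), "> 0")
})

test_that("age-window contrasts reproduce the frailty/longevity pattern", {
  fy <- strat("rs10519203", "genetically_british", "father", "40-75")
  fo <- strat("rs10519203", "genetically_british", "father", "75+")
  ct <- age_window_contrast(fy$beta, fy$se, fo$beta, fo$se)
  expect_close(ct$p, 0.003, 1e-3)
  expect_lt(ct$p, 0.006)
  expect_lt(ct$diff, 0)  # CHRNA3/5: effect wanes with age (frailty)

  my <- strat("rs429358", "genetically_british", "mother", "40-75")
  mo <- strat("rs429358", "genetically_british", "mother", "75+")
  ct <- age_window_contrast(my$beta, my$se, mo$beta, mo$se)
  expect_close(ct$p, 0.006, 1e-3)
  expect_gt(ct$diff, 0)  # APOE: effect grows with age (longevity)

  same <- age_window_contrast(0.05, 0.01, 0.05, 0.01)
  expect_equal(same$p, 1)
})

test_that("contrast test holds its type-I error on null stratum pairs", {
  set.seed(83)
  rej <- replicate(2000, {
    s1 <- runif(1, 0.01, 0.05); s2 <- runif(1, 0.01, 0.05)
    ct <- contrast_test(rnorm(1, 0.1, s1), s1, rnorm(1, 0.1, s2), s2)
    ct$p < 0.05
  })
  expect_gt(mean(rej), 0.032)
  expect_lt(mean(rej), 0.068)
})

test_that("double-homozygote life-year arithmetic matches the published 3.3-3.7", {
  t1 <- pub[pub$table == 1 & !pub$combined &
              pub$population == "genetically_british", ]
  fathers <- -t1$years[t1$parent == "father"]
  mothers <- -t1$years[t1$parent == "mother"]
  expect_equal(round(combined_homozygote_years(fathers), 1), 3.3)
  expect_equal(round(combined_homozygote_years(mothers), 1), 3.7)
  expect_equal(combined_homozygote_years(c(0, 0)), 0)
})
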