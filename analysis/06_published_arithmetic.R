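#!/usr/bin/env Rscript
# Reproduce the published combined rows for the two sentinel lifespan loci
# from the bundled per-stratum estimates: discovery, replication and overall
# IVW metas, sex contrasts, age-window contrasts, and the double-homozygote
# life-year prediction.

source("analysis/00_settings.R")

pub <- kin_published_estimates()
strat <- function(v, pop, par, win = "40+")
  pub[pub$variant == v & pub$population == pop & pub$parent == par &
        pub$window == win & !is.na(pub$beta), ]

for (v in c("rs429358", "rs10519203")) {
  cat(sprintf("\n== %s (%s) ==\n", v, pub$locus[pub$variant == v][1]))
  fa <- strat(v, "genetically_british", "father")
  mo <- strat(v, "genetically_british", "mother")
  disc <- ivw_meta(c(fa$beta, mo$beta), c(fa$se, mo$se))
  printed <- strat(v, "discovery", "both")
  cat(sprintf("discovery meta:   beta %.4f (printed %.4f), HR %.3f (%.3f), se %.4f (%.4f)\n",
              disc$beta, printed$beta, disc$hr, printed$hr, disc$se, printed$se))
  reps <- pub[pub$variant == v & pub$table == 1 & !pub$combined &
                pub$population %in% c("declared_british", "other_origins",
                                      "estonian"), ]
  mrep <- ivw_meta(reps$beta, reps$se)
  prep <- strat(v, "replication", "both")
  cat(sprintf("replication meta: beta %.4f (printed %.4f), se %.4f (%.4f)\n",
              mrep$beta, prep$beta, mrep$se, prep$se))
  mall <- ivw_meta(c(disc$beta, mrep$beta), c(disc$se, mrep$se))
  pall <- strat(v, "overall", "both")
  cat(sprintf("overall meta:     beta %.4f (printed %.4f), HR %.3f (%.3f)\n",
              mall$beta, pall$beta, mall$hr, pall$hr))
  ct <- contrast_test(fa$beta, fa$se, mo$beta, mo$se)
  cat(sprintf("sex contrast:     p = %.4f (printed %.3f)\n", ct$p,
              pub$p[pub$variant == v & pub$parent == "sex_difference"]))
  for (sex in c("father", "mother")) {
    y <- strat(v, "genetically_british", sex, "40-75")
    o <- strat(v, "genetically_british", sex, "75+")
    ct <- age_window_contrast(y$beta, y$se, o$beta, o$se)
    cat(sprintf("age-window contrast, %ss: diff %+.4f, p = %.4f\n",
                sex, ct$diff, ct$p))
  }
}

t1 <- pub[pub$table == 1 & !pub$combined &
            pub$population == "genetically_british", ]
cat(sprintf("\ndouble-homozygote prediction: fathers %.2f y, mothers %.2f y (printed 3.3-3.7)\n",
            combined_homozygote_years(-t1$years[t1$parent == "father"]),
            combined_homozygote_years(-t1$years[t1$parent == "mother"])))
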