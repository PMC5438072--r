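---
title: "Kin-cohort survival analysis of parental lifespan: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-cohort survival analysis of parental lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the design

Lifespan is hard to study by direct genotyping: by the time subjects die,
their DNA is rarely in a research cohort. The kin-cohort design sidesteps
this. Middle-aged participants of a population cohort report, by
questionnaire, whether each parent is alive and the parent's current age or
age at death. Participants are genotyped; their parents are not. Parental
survival is then regressed on *offspring* genotype, which acts as a
probabilistic proxy for the parental genotype.

The key piece of arithmetic is the dosage expectation. For a counted allele
A1 with population frequency $p$, under random mating:

* an offspring homozygous for the other allele implies an expected parental
  dosage of $p$ (the chance that the non-transmitted parental allele is A1);
* an A1 homozygote implies $2 - q = 1 + p$;
* a heterozygote implies the average of the two, $1/2 + p$.

The expected parental dosage is therefore $p + x/2$ for offspring dosage
$x$: exactly linear, with slope $1/2$ regardless of $p$. Effects estimated
per offspring allele are consequently *half* the per-parental-allele
effects, and `rescale_to_parent_scale()` doubles point estimate and
standard error at reporting time (z statistics and p-values are invariant).
`attenuation_slope()` verifies the $1/2$ analytically and the test-suite
verifies it empirically on simulated trios. Doubling the log hazard ratio
is itself a first-order convention — under Cox nonlinearity
$E[e^{\beta X_{par}} | X_{off}]$ is not exactly
$e^{\beta E[X_{par}|X_{off}]}$ — but at the per-allele effect sizes relevant
here (|log HR| ≤ 0.25) the discrepancy is far below sampling error, and the
package keeps the convention.

## Survival model

Each parent record is analysed on the **age** time scale with entry at 40
years: the phenotype is survival from age 40, with earlier parental deaths
excluded to limit the influence of accidents and war. The hazard model is

$$h_i(x) = h_0(x)\, \exp\!\big(\beta X_i + \gamma_1 Z_{i1} + \dots +
\gamma_k Z_{ik}\big),$$

where $x$ is age, $X_i$ the offspring's counted-allele dosage and
$Z_{i1..k}$ covariates (in real data: offspring sex, assessment centre,
genotyping batch, deprivation index, principal components; in the
generator: standard-normal stand-ins). Fathers and mothers are always
fitted as separate strata and combined afterwards by meta-analysis, since
effects are strongly sex-dependent. Living parents are right-censored at
their age when the offspring was interviewed. Partial-likelihood
maximisation is delegated to `survival::coxph()` (Efron tie correction by
default; ties are measure-zero in the generator's continuous ages but the
Breslow option is kept because the residual identity below is exact under
it).

### Martingale residuals as a survival score

Fitting a full Cox model per variant across hundreds of thousands of
markers is wasteful; the two-stage route fits the covariate-only model
once and scans its Martingale residuals,

$$\hat M_i = \delta_i - \hat H_0(\tau_i)\, e^{\hat\gamma' Z_i},$$

with $\delta_i$ the event indicator (1 died, 0 censored) and $\tau_i$ the
exit age. `breslow_cumhaz()` implements the Breslow step estimator
$\,d\hat H_0(t) = d_t / \sum_{j \in R(t)} e^{\hat\gamma' Z_j}$ over risk
sets $R(t) = \{j: \text{entry}_j < t \le \tau_j\}$ (delayed entry
supported, for the 75+ window). Under this baseline
$\sum_i \hat M_i = 0$ exactly, for any coefficient vector — the package
tests this identity to $10^{-8}$ and cross-checks the residuals against
`survival`'s own at $10^{-8}$. For a genotype omitted from the model with
small effect $\beta$, $E[\hat M_i]$ is linear in $X_i$, so a per-variant
linear regression of residuals on dosage is a valid score test.

Residuals are rank-normalised before scanning
(`rank_normal()`: $\Phi^{-1}((r - c)/(n - 2c + 1))$, Blom offset
$c = 3/8$, average ranks for ties). The offset is configurable; the Blom
convention was chosen as the common default in GWAS practice, and defines
the score scale exactly since the residual distribution is skewed.

### Calibration of the scan estimate

The slope of the *score* on dosage is not a log hazard ratio: the raw
residual slope is attenuated by roughly the event fraction, and the rank
transform rescales it again. The scan therefore reports two estimates per
variant:

* `beta_score` — the slope of the rank-normal score on dosage, whose t
  statistic supplies the scan p-value (column `P`);
* `beta_off` — a one-step hazard-scale estimate: the slope $b_M$ of the
  **raw** residuals on dosage times $n/d$ ($d$ = number of deaths). This is
  the Cox one-step approximation $\hat\beta \approx U/I$ with score
  $U = \sum_i (X_i - \bar X)\hat M_i = n\,\widehat{\mathrm{Var}}(X)\, b_M$
  and null information $I \approx d\,\widehat{\mathrm{Var}}(X)$ (genotype
  independent of risk-set composition at small $\beta$).

In simulation the one-step estimate agrees with the full-Cox verification
coefficient to about 1% at the effect sizes of interest (the acceptance
suite bounds the relative difference at 15%), and its standard error
$\,n/d$ times the OLS standard error reproduces the Cox standard error
$1/\sqrt{d\,\mathrm{Var}(X)}$. `beta_parent = 2 * beta_off` is the
parental-scale estimate. Fractions of residual variance explained (`r2`)
are *not* doubled: they live on the offspring/score scale by construction.

### Conditional scan, verification, windows

`conditional_scan()` residualises scores and dosages on sentinel variants
(equivalent to including them as covariates; Frisch–Waugh), with degrees of
freedom adjusted and variants collinear with a sentinel returned as NA
rows. `verify_full_cox()` refits sentinels inside the Cox model — singly,
or jointly for the multi-variant (LD-separation) fit. `km_life_years()`
converts genotype classes to restricted-mean life years (area under the
Kaplan–Meier curve from entry to a horizon); the per-allele difference of
adjacent classes, doubled, is the parental-scale life-year effect. The
restriction horizon defaults to the maximum observed age because the
source analyses do not state theirs; life-year values therefore depend
mildly on this choice and the analysis drivers state the horizon they use
(105 years).

Age-window analyses split at 75 years, approximately the mean age at
death. For 40–75, exits are capped at 75 and later deaths recoded as
survivors; for 75+, only records with follow-up beyond 75 enter, with
entry reset to 75 (left truncation). A *frailty* locus shows its effect
mainly below 75, a *longevity* locus mainly above; the contrast of window
log hazard ratios (normal approximation) tests the difference.

### Meta-analysis and contrasts

`ivw_meta()` is fixed-effect inverse-variance weighting on log hazard
ratios (weights $1/\mathrm{se}^2$); Cochran's Q is reported for
information only, as no heterogeneity model is specified by the design.
Sex and age-window contrasts use
$z = (\beta_2 - \beta_1)/\sqrt{se_1^2 + se_2^2}$ with two-sided normal
p-values — with tens of thousands of deaths per stratum the t/normal
distinction is immaterial. Two-sided tests are the default everywhere; a
one-sided option exists on `ivw_meta()` because published replication
p-values for this design are sometimes one-sided readings of the IVW z
(the bundled published replication values are consistent with that
convention). Life-year effects are treated as additive across alleles and
loci, so the double-homozygote prediction is twice the summed per-allele
effects.

## The synthetic cohort generator

Real kin-cohort data of this kind are access-controlled, so the package
generates trio-structured cohorts with the statistical structure the
analysis assumes:

* **Genotypes.** Parental genotypes i.i.d. Binomial(2, p) (HWE), fathers
  independent of mothers; offspring receive one uniformly chosen allele
  from each parent (`transmit_offspring_dosage()`), so Mendelian
  consistency holds by construction and the parental-on-offspring dosage
  slope is 1/2. Variants are independent; `draw_ld_pair()` provides a
  haplotype-level correlated pair (allelic correlation $\rho$, preserved
  through transmission) solely for conditional-scan testing. No
  relatedness between subjects, no assortative mating.
* **Lifespans.** Gompertz hazard from age 40,
  $h(t) = a\,e^{b (t - 40)} e^{\eta}$, sampled by exact inverse CDF;
  defaults $a = 0.002$/yr, $b = 0.095$/yr for both sexes give mean ages at
  death in the mid 70s, matching the design's use of 75 as the approximate
  mean. The paper-style analyses specify no lifespan law; Gompertz is the
  standard adult-mortality choice. Genotype effects enter $\eta$ as
  log-HRs per *parental* allele, piecewise-constant in age with a switch
  at 75, so frailty- and longevity-type architectures are both
  expressible; the piecewise sampler inverts the piecewise cumulative
  hazard exactly.
* **Ages.** Offspring interview ages uniform on 40–69 (the recruitment
  window); parents are their offspring's age plus an independent uniform
  20–35 year offset. No parental-age model is published; these ranges
  yield censoring fractions (roughly a third of parents alive) of the
  order seen in the real tables, and are configurable.
* **Contamination.** Adopted flags (default rate 1.5%), subjects with no
  parental data (2%), implausible parent ages > 115 (rare), missing
  covariates (0.12%), and pre-40 parental deaths (1%) are injected and
  indexed in the truth record; the first three rates loosely mirror the
  published exclusion counts relative to cohort size, the last two are
  round choices of the same order.
* **Determinism.** One global seed; sub-streams (genotypes, covariates,
  ages, lifespans, contamination) are derived by `stream_seed()` so each
  stage is independently reproducible, and identical configs give
  bit-identical cohorts.

What the generator does *not* emulate: linkage disequilibrium structure
beyond the test-only pair, population stratification, batch effects,
reporting error in questionnaire ages (heaping, recall bias), shared
environment between parents, or competing risks. Passing tests therefore
demonstrate the statistical machinery under the model's own assumptions,
not robustness to those real-data pathologies.

## Phenotype QC

`apply_exclusions()` applies the questionnaire exclusion rules with a fixed
precedence (adopted → no usable parental data → invalid parent age > 115 →
missing covariate), each subject counted once under the first rule it
triggers; the published counts do not fix a precedence, so one is chosen
and documented to make tallies deterministic. A subject with *both*
parents dead before 40 (or no parental ages at all) is excluded outright;
a single pre-40 parental death removes only that parent record. The tally
reconciles exactly — subjects in = subjects out + subject-level
exclusions — and the operation is idempotent. The published
"non-useful ethnicity" rule has no algorithmic definition and is treated
as an upstream labelling concern (sub-cohort labels for
discovery/replication splits), not a QC rule.

## Numerical choices

* Cox convergence: `coxph.control(eps = 1e-9, iter.max = 50)`; singular
  fits and non-convergence are errors, constant covariates are dropped to
  coefficient 0 rather than failing the fit.
* Scan hygiene: variants with > 5% missing dosages are dropped to NA rows;
  sporadic missingness below that is mean-imputed and counted;
  monomorphic and MAF < 0.1% variants become NA rows, preserving row
  count. Collinearity with a sentinel is detected by a $10^{-10}$
  relative-variance threshold after projection.
* Rank-normal ties take average ranks; an all-constant residual vector is
  a degenerate-input error.
* p-values: two-sided throughout; scan p from the t distribution with
  $n - 2$ (unconditional) or $n - 2 - s$ (conditional on $s$ sentinels)
  degrees of freedom.

## Problem sizes used in the checks

The bundled analyses and acceptance checks run at sizes chosen to make
Monte-Carlo error small relative to the assertions: 100,000 subjects for
end-to-end recovery of sex-specific parental log-HRs (the real discovery
cohort's order of magnitude), 50,000 for the empirical attenuation slope,
40,000 for the age-window recovery, 20,000 subjects × 500 null variants
for calibration of the genomic-inflation factor and type-I error. The
median-based $\lambda_{GC}$ over 500 variants has a sampling s.d. of about
0.10 under the null, which is worth remembering when reading any single
$\lambda$ from a panel of that size.

## Known limitations

The two-stage estimate is a one-step approximation, accurate only for
small effects (relative error grows with $|\beta|$); the full-Cox
verification path exists precisely to finalise effect sizes. The doubling
convention is first-order in the same sense. Standard errors in the scan
ignore the estimation error of the stage-1 covariate coefficients
(legitimate under genotype–covariate independence, as in the design).
Restricted-mean life-year effects depend on the chosen horizon. And the
generator's idealised structure means real-data issues — LD, stratification,
misreported ages — must be handled upstream, as they are in the published
analyses this package's workflow mirrors.
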