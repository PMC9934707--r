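---
title: "Separating childhood and adulthood BMI effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating childhood and adulthood BMI effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecourseMR)
```

## The scientific problem

Observationally, heavy children tend to become heavy adults, and heavy
adults develop type 2 diabetes (T2D) more often. Whether *childhood*
adiposity itself harms later glycaemic health — or whether its apparent
effect is entirely mediated by adulthood adiposity — cannot be settled
observationally, because lifelong confounders act on both. Mendelian
randomisation (MR) sidesteps part of that confounding by using genetic
variants, fixed at conception, as instruments for the exposures.

This package implements the full analytical machinery for a lifecourse MR
study of childhood vs adulthood BMI against diabetes-related outcomes:

1. a **continuous reconstruction of childhood BMI** from a three-level
   body-size recall question, anchored to an external reference
   distribution;
2. **instrument discovery**: rank-inverse-normalised, covariate-adjusted
   GWAS, quality-control filtering and greedy LD clumping;
3. **instrument validation**: genetic risk scores, variance explained,
   extreme-value prediction and F-statistics;
4. a **two-sample MR engine**: allele harmonisation, proxy lookup,
   inverse-variance-weighted (IVW), MR-Egger and multivariable (MVMR)
   estimators, Steiger directionality filtering and fixed-effect
   meta-analysis;
5. a **cohort simulator** that generates two-sample studies under the
   assumed causal diagram, so that every stage is testable end to end
   without any external data.

## The generative model

The simulator encodes the causal diagram in three structural equations
(all traits constructed with exact unit population variance, so
coefficients are SD-per-SD):

$$C = G b_C + c\,U + \varepsilon_C$$
$$A = \gamma C + G b_A + c\,U + \varepsilon_A$$
$$Y = \delta_C C + \delta_A A + G b_P + c\,U + \varepsilon_Y$$

where $C$, $A$ are childhood and adulthood BMI, $Y$ the outcome, $G$ the
centred dosage matrix, $U$ a hidden standard-normal confounder with
strength $c$, $\gamma$ the child-to-adult tracking path, $\delta_C$ and
$\delta_A$ the *direct* effects of each exposure, and $b_P$ optional
direct variant-to-outcome (pleiotropic) effects. The residual variances
are solved analytically from the configured coefficients, which keeps
every path coefficient an exact structural quantity; a configuration whose
genetic-plus-path variance exceeds 1 is rejected rather than renormalised.
Binary outcomes replace the last equation by a logistic model on the same
linear predictor, with the intercept solved numerically for a target
prevalence. The total causal effect of childhood BMI is then
$\delta_C + \gamma\,\delta_A$ (path rule), which is what a *univariable*
childhood MR estimates when its instruments act on $Y$ only through $C$.

Key default choices (all exposed in `sim_config()`):

* **Variant panel** — 50 child-specific, 50 adult-specific and 50 shared
  variants, allele frequencies uniform on (0.05, 0.5), placed 1 Mb apart
  (the simulator produces no LD; correlated reference panels for clumping
  and proxy search come from `simulate_ld_panel()`).
* **Per-allele effects** — drawn Normal(0, `effect_sd`) with
  `effect_sd = 0.1`, then rescaled so each exposure's realised genetic
  variance equals its expectation (≈ 0.37). The rescaling gives every
  seed the configured heritability instead of a chi-squared draw around
  it; without it, high-heritability configurations intermittently violate
  the unit-variance budget of the adulthood trait
  ($\gamma^2$ + genetic + confounder > 1) on unlucky seeds.
* **Shared effects** — correlated between the two exposures
  (default correlation 0.5), so variants with larger adulthood than
  childhood effects, and vice versa, arise naturally.
* **Paths** — $\gamma = 0.5$, $\delta_C = 0$, $\delta_A = 0.6$: the
  lifecourse hypothesis the MVMR machinery is designed to disentangle
  (childhood BMI acting on the outcome only through adulthood BMI).
* **Recall proportions** — thinner/same/plumper at (0.32, 0.51, 0.17), a
  plausible split for a "body size at age 10" question; this is a chosen
  parameter, not a reproduction of any cohort's observed proportions.
* **Nuisance covariates** — sex and age receive small fixed effects
  (0.1 per sex unit, 0.005 per year), independent of genotype, so
  covariate residualisation is exercised without confounding genetics.

What the simulator deliberately does *not* emulate: linkage
disequilibrium between causal variants, population structure,
relatedness, assortative mating, and recall-error mechanisms beyond
coarse categorisation. Tests passing on these cohorts therefore
demonstrate the correctness of the estimators and plumbing, not
robustness to those real-data complications.

## Childhood BMI reconstruction

Many adult biobank cohorts carry only a categorical recall of childhood
body size. The reconstruction treats an external reference distribution
(e.g. measured age-11 BMI in a birth cohort; default Normal with mean
17.8 kg/m², SD 2.6 kg/m² — plausible values, configurable, not a claimed
reproduction of any specific cohort) as the anchor: category proportions
are interpreted as quantiles splitting the reference into three strata,
and each individual receives an independent inverse-CDF draw from their
stratum. A lognormal family (moment-matched on the natural scale) is
offered because childhood BMI is right-skewed. The reconstructed values
are then rank-inverse-normalised (Blom scores, offset 3/8, average ranks
for ties) before association testing.

Two properties deserve emphasis:

* Because the within-stratum draws are independent of everything else,
  the reconstruction carries exactly the category information — no more.
  Its rank correlation with the true childhood BMI is therefore slightly
  *below* that of the raw category codes (the draws scramble
  within-category ranks), and a GWAS on the reconstruction cannot recover
  true effects better than a GWAS on the codes at equal n. The value of
  the reconstruction is the continuous SD scale — effect sizes
  directly comparable with adulthood BMI — not extra statistical
  information.
* Using a reconstructed (error-prone) exposure in MR inflates per-SD
  causal estimates by roughly 1/cor(reconstruction, truth): classical
  measurement error shrinks the variant-exposure effects while leaving
  variant-outcome effects untouched. Parameter-recovery analyses in this
  package therefore instrument the true continuous childhood phenotype;
  the pipeline's recall-based estimates are interpreted per SD of the
  *reconstructed* measure.

## Association scan and clumping

The GWAS stage residualises the phenotype on covariates by least squares,
optionally rank-inverse-normalises it, and fits each variant by simple
regression (vectorised closed form; two-sided t tests). This is a
deliberate substitution of covariate-adjusted least squares for a linear
mixed model: the simulated cohorts contain no relatedness, which is the
only thing the mixed model would add. Binary traits use per-variant
logistic regression with Wald tests. Monomorphic variants are emitted
with `SE = Inf` and flagged, and QC filtering (keep
0.01 < EAF < 0.99 and INFO > 0.8 where INFO is present) removes them
downstream.

Clumping is greedy: the smallest-p variant passing $p \le 5\times10^{-8}$
becomes an index and absorbs every unassigned variant within 250 kb *or*
correlated at $r^2 > 0.001$ in the reference panel. Removing on either
criterion makes the retained index set satisfy both jointly — a stricter
rule than distance-window-only clumping, chosen because both thresholds
are stated as joint independence criteria for instrument selection.
Numerical conventions: positions are 1-based; "within the window" is a
strict `<` comparison; $r^2$ is evaluated only within 1 Mb of the index
(beyond that it is treated as 0, a tractability cut-off that also defines
the scope of the pairwise-independence invariant); ties in p are broken
by (chromosome, position, id) so results are reproducible.

## The MR engine

`mr_fit()` is the package's central fitting function; `mr_ivw()`,
`mr_egger()` and `mr_mvmr()` are thin wrappers.

* **IVW** regresses variant-outcome on variant-exposure effects through
  the origin with weights $1/\mathrm{se}_Y^2$. Three standard-error models
  are offered (`se_method`): the fixed-effect form
  $\sqrt{1/\sum w\,\beta_X^2}$ (default; exact when exposure effects are
  noiseless and weights correct), the multiplicative random-effects form
  (fixed-effect SE inflated by $\sqrt{\max(1, Q/(k-p))}$; the default of
  the field's standard tooling), and a delete-one-variant jackknife,
  which is consistent when the exposure effects themselves carry
  estimation noise — including correlated noise across exposures — and is
  the recommended choice for finite-sample simulation studies. With
  estimated exposure effects the fixed-effect form demonstrably
  undercovers. A single instrument degenerates to the Wald ratio,
  labelled as such.
* **MR-Egger** adds a free intercept after orienting all exposure
  effects non-negative; the intercept estimates average directional
  pleiotropy. Inference is t-based with $k-2$ degrees of freedom and an
  estimated residual scale — the choice that makes the intercept test
  exactly calibrated under the no-pleiotropy null. A p < 0.01 flag on
  the intercept marks analyses with pleiotropy evidence.
* **MVMR** regresses outcome effects jointly on both exposures' effects
  without intercept, giving each exposure's direct effect conditional on
  the other. The instrument set is the union of both exposures' clumped
  instruments, re-clumped jointly on the smaller p so the union is itself
  independent. Collinear exposure-effect columns (condition number >
  1e10) are refused as weak conditional instruments; an exposure whose
  effects are all exactly zero is unidentified and reported `NA` (the
  other coefficient then equals univariable IVW).
* **Steiger filtering** removes variants explaining more variance in the
  outcome than the exposure, comparing
  $2\beta^2\,\mathrm{MAF}(1-\mathrm{MAF})$ on both sides. For binary
  outcomes this compares a log-OR against an SD effect — an
  approximation, flagged as such.
* **Harmonisation** orients all tables to the exposure's effect allele:
  direct matches kept, swapped pairs flipped, palindromic (A/T, C/G)
  variants oriented by allele frequency when both frequencies are clearly
  away from 0.5 (|EAF − 0.5| > 0.08, a documented choice) and dropped as
  ambiguous otherwise. Instruments missing from an outcome table may be
  replaced by the best proxy within 250 kb at $r^2 > 0.8$, sign-oriented
  through the panel dosage correlation.
* **Meta-analysis** across outcome studies is fixed-effect inverse
  variance (delegated to `metafor::rma.uni(method = "FE")`), always on
  the log-OR scale for binary outcomes; `to_odds_ratio()` exponentiates
  point estimates and confidence bounds for reporting.

No multiple-testing correction is applied anywhere: raw p-values are
reported, with the Egger p < 0.01 flag exposed as a configurable
threshold. Egger sensitivity analyses accompany MVMR models as
*univariable* Egger fits per exposure-outcome pair (an interpretation
choice; a multivariable Egger is not implemented).

### What parameter recovery can and cannot achieve

Under the default diagram ($\delta_C = 0$, $\gamma = 0.5$,
$\delta_A = 0.6$) with two cohorts of 20,000 and 150 strong instruments
(per-exposure genetic variance ≈ 0.54 in the validation scenario,
per-variant F in the hundreds — compensating at desk scale for the
biobank-scale instrument strength the method is normally run with),
univariable childhood MR centres on the path product 0.30 and MVMR
separates the direct effects. Two finite-sample phenomena remain and are
visible in the calibration results:

* *Regression dilution*: estimated exposure effects carry sampling noise,
  attenuating IVW/MVMR slopes by a factor of roughly
  $\sum\beta_X^2 / (\sum\beta_X^2 + \sum \mathrm{se}_X^2)$ — well under
  1% here, but never exactly zero, and amplified in MVMR by the
  correlation between the two exposures' estimated effects (both come
  from the same cohort).
* *Coverage*: with jackknife (or multiplicative) SEs the MVMR childhood
  CI covers its true value (0) close to the nominal 95%; the adulthood CI
  sits near 92–93% in expectation — and realises ~90% in the shipped
  200-replicate check — because the residual dilution bias is roughly
  0.45 of its (small) standard error. This is a property of the
  estimator at this equal-cohort scale, not an implementation artefact
  (fixed-effect SEs would sit far lower, ~83%); in the asymmetric regime
  the method is normally applied in, with the exposure GWAS an order of
  magnitude larger than the outcome GWAS, the dilution is negligible.

The univariable path-product recovery holds when instruments affect the
outcome only through the child→adult chain — i.e. child-specific
variants. Shared variants with correlated adulthood effects are genetic
confounding for the univariable analysis (they are precisely why MVMR is
needed), so the validation scenario uses disjoint child-/adult-specific
panels, while the package default keeps 50 shared variants to exercise
the realistic, contaminated setting.

## Validation metrics

Genetic risk scores are effect-allele-oriented weighted dosage sums
(missing variants are an error by default, skippable by flag). Reported
metrics: squared Pearson correlation against the phenotype; the
closed-form variance explained $\sum 2\beta^2\mathrm{MAF}(1-\mathrm{MAF})$;
extreme-value prediction of the phenotype exceeding +1 SD via the
Mann-Whitney AUC and a logistic odds ratio per score SD with Wald CI
(per-SD is a labelling choice; perfect separation is reported
non-converged); and the implied instrument F-statistic
$(r^2/(1-r^2))\cdot((n-k-1)/k)$, with mean per-variant $(\beta/\mathrm{se})^2$
available as an alternative strength summary through the summary
statistics themselves.

## Pipeline and reproducibility

`run_pipeline()` sequences simulate → reconstruct → gwas → clump → grs →
mr → report behind a YAML configuration with strict key validation.
Every stage reads its inputs from, and writes its outputs to, the run
directory (genotypes as VCF with DS dosages, tables as TSV), so any stage
re-runs in isolation bit-for-bit. All randomness flows from the single
config seed through fixed named substreams; a JSON manifest records the
resolved configuration, per-stage seeds, thresholds, variant counts
through every filter, output checksums and timings (the manifest itself
contains timings and is the one non-reproducible output). The
command-line entry point (`inst/cli/lifecourseMR.R`) exposes the stages
as verbs.

Problem sizes used by the shipped checks — chosen as the package's own
validation design — are: 200 replicates of 20,000-individual cohort
pairs for parameter recovery; 1,000 summary-level replicates for Egger
calibration; 50 panels of 50 variants for clumping fidelity; cohorts of
500–8,000 for the pipeline smoke and determinism runs.

## Known limitations

* The estimators assume independent instruments; correlated-instrument
  (LD-aware) MR, weighted-median/mode estimators and conditional
  F-statistics for MVMR are out of scope.
* Steiger filtering on binary outcomes uses the quantitative
  variance-explained formula on the log-OR scale — an approximation.
* The recall reconstruction assumes the reference distribution and
  category proportions are correctly specified; recall misclassification
  is not modelled.
* The GWAS stage is plain least squares / logistic regression and is not
  suitable for related or structured samples.
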