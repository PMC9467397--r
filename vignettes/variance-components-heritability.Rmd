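---
title: "Pedigree variance-components models for regional brain iron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree variance-components models for regional brain iron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

ironherit estimates how much of the variation in quantitative MRI
phenotypes — here, regional R2* relaxation rates, a proxy for tissue iron in
gray matter — is attributable to additive genetic effects, using family
structure alone (no genotypes). The engine is the classical polygenic
variance-components model. For a trait vector $y$ over $n$ phenotyped
relatives:

$$ y \sim N\!\left(X\beta,\; 2\Phi\,V_g + I\,V_e\right), $$

where $\Phi$ is the kinship matrix ($\phi_{ij}$ = probability that one
allele drawn from each of $i$ and $j$ is identical by descent, so $2\Phi$ is
the expected proportion of shared genes: 0.5 for full siblings and
parent–child pairs, 0.25 for half-siblings and avuncular pairs), $V_g$ the
additive polygenic variance and $V_e$ the residual environmental variance.
Covariates enter as fixed effects $X\beta$; $V_p = V_g + V_e$ is the
residual phenotypic variance after covariates, and the heritability is
$h^2 = V_g / V_p$. Significance of $h^2$ comes from a likelihood-ratio test
of $V_g = 0$ against $V_g > 0$; because the null pins a nonnegative variance
at its boundary, the statistic is referred to the 50:50 mixture
$\tfrac12\chi^2_0 : \tfrac12\chi^2_1$ (a pure $\chi^2_1$ reference is
available by flag).

For two traits the model extends to the stacked $2n$-vector with covariance
$2\Phi \otimes G + I \otimes E$, where $G$ and $E$ are the 2×2 genetic and
environmental covariance blocks with correlations $r_g$ and $r_e$. The
phenotypic correlation decomposes as

$$ r_p = r_g\sqrt{h^2_1 h^2_2} + r_e\sqrt{(1-h^2_1)(1-h^2_2)}, $$

so a high $r_g$ between two regions means the same genes drive both, while
$r_g \approx 0$ between region blocks indicates distinct gene sets. $r_g$
and $r_e$ are interior parameters under their nulls, so their
likelihood-ratio tests use $\chi^2_1$.

## Kinship and pair classification

`compute_kinship()` implements the recursive tabular method: processing
individuals parents-first, $\phi_{ij} = \tfrac12(\phi_{fj} + \phi_{mj})$ for
a non-founder $i$ with parents $f, m$, and
$\phi_{ii} = \tfrac12(1 + \phi_{fm})$, which carries inbreeding through the
diagonal. Founders are assumed unrelated and non-inbred. Kinship is always
computed over the *full* pedigree — including unphenotyped placeholder
founders that connect e.g. a sibling pair — and the phenotyped sub-matrix is
extracted for fitting, so indirect relationships are exact.
`classify_relative_pairs()` labels pairs structurally (shared listed
parents, parent-of relations), never from the kinship value, since
parent–child and full-sibling pairs are not distinguishable by $\phi$ alone.
The test suite validates the recursion against a gene-dropping Monte-Carlo
oracle (100,000 allele drops, agreement within 3 standard errors).

## The synthetic cohort

The original cohort is not publicly deposited, so the package carries a
deterministic generator that reproduces its published composition: 130
phenotyped members in 59 families (47 of two members, 12 of three), with a
within-family pair census of 55 full-sibling, 19 parent–child, 8 avuncular
and 1 half-sibling pair. The published counts do not identify the individual
family templates, so `cohort_config()` uses one consistent reconstruction —
two-member families: 39 sibling pairs, 7 parent–child pairs, 1 half-sib
pair; three-member families: 2 three-sibling sets, 2 parent-with-two-
children, 8 sibling-pairs-where-one-sibling-has-a-child — chosen because it
reproduces the census exactly under the published family sizes; the template
mix is a config field users can alter.

`simulate_covariates()` draws covariates at the published prevalences
(54.6% female, 16.9% APOE ε4 carriers, BMI 25.6 ± 3.9, 80.8% hypertension,
10% diabetes, 84.6% hypercholesterolemia, 45.4% ever-smokers) with ages in
38–85, median near 72, and parent–child gaps of at least 18 years. For each
binary vascular risk factor it also emits the raw measurements behind the
status (blood pressures, fasting glucose, lipids, history/medication flags),
constructed to be consistent with the encoding rules, so the encoders are
testable against ground truth. `simulate_traits()` is the generative mirror
of the bivariate model at 9 traits: cross-individual, cross-trait covariance
$2\Phi \otimes G + I \otimes E$, with a block genetic-correlation default
(0.85 within the four basal-ganglia measures, 0.80 within the five cortical
measures, 0 between blocks — the distinct-gene-sets regime) and identity
environmental correlation. Covariate effects are injected as mean shifts
whose variance share is configured per covariate; total variance is held at
$V_p$ by shrinking $V_g$ and $V_e$ proportionally, which makes the
"proportion of variance due to covariates" a recoverable quantity.

What the generator does *not* emulate: ascertainment (families were
recruited through an existing study), missing data, measurement artifacts of
R2* mapping, non-normal trait distributions, household/shared-environment
variance, dominance, and age-by-gene interactions. Passing recovery tests on
this cohort therefore demonstrate correctness of the estimators under the
model's own assumptions, not robustness to real-data violations of them.

## Preprocessing

Variance-components likelihoods assume normal traits, so each trait is
rank-based inverse-normal transformed before fitting:
$z_i = \Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with Blom offset
$c = 3/8$ (configurable; $c = 1/2$ gives van der Waerden-type scores — which
offset the original analysis software used is not documented, so the choice
is exposed). Ties receive average ranks. The vascular risk factors are
encoded from raw measurements with *strict* thresholds — systolic over
140 mmHg, diastolic over 90 mmHg, fasting glucose above 126 mg/dl, total
cholesterol higher than 200 mg/dl, LDL higher than 130 mg/dl — reading
"over/above/higher than" literally, so boundary values are negative;
history or current treatment always dominates.

## Fitting: numerical choices

**Univariate.** After a one-time eigendecomposition $2\Phi = U D U'$, the
rotated model has diagonal covariance $V_p\,(h^2 (d_k - 1) + 1)$, so each
likelihood evaluation is $O(n)$. $\beta$ is profiled by generalized least
squares and $V_p$ analytically, leaving a one-dimensional bounded search
over $h^2 \in [0, 1]$ (Brent's method plus explicit endpoint checks). This
was chosen over optimizing a transformed two-parameter surface because the
profile is exact, the boundary is handled without penalties or restarts, and
it makes the boundary flag ($\hat V_g = 0$) unambiguous. The default is ML
rather than REML (matching the convention of the pedigree-analysis software
this mirrors, and required for likelihood-ratio tests between models with
different fixed effects); REML is available via `options$reml`. The standard
error of $h^2$ is the delta-method value from the curvature of the profile
log-likelihood, reported missing at a boundary.

**Bivariate.** The same eigendecomposition turns the joint likelihood into
$n$ independent 2×2 blocks $d_k G + E$. Six parameters
$(h^2_1, h^2_2, \log V_{p1}, \log V_{p2}, r_g, r_e)$ are optimized with
box constraints (L-BFGS-B from several starts seeded by the univariate fits
and the residual correlation, polished by Nelder–Mead); within the box the
2×2 blocks are always positive definite, so no penalty terms are needed.
Estimates pinned at $|r| = 1$ are flagged as boundary solutions and reported
without a standard error, mirroring how such fits are footnoted in published
tables. Degenerate inputs (identical traits, constant traits, pedigrees with
no related pairs) error with explicit messages rather than returning
meaningless estimates.

**Screening and attribution.** Covariate screening is single-pass
drop-one-from-full: every candidate is tested by a 1-df LRT of the full
candidate model against the model without it, retained at $p < 0.1$ (the
deliberately liberal published threshold), and the final model is refit on
the retained set. Whether the original analysis screened stepwise is not
documented; single-pass is deterministic and order-independent, which we
prioritized. The "proportion of variance due to final covariates" is
$\mathrm{Var}(X\hat\beta)/\mathrm{Var}(y)$ — one reasonable reading of the
software's output, stated here explicitly. A risk factor's share is the
extended-model proportion minus the basic-model proportion, floored at zero
(published tables contain 0.00 entries), with the sign of its coefficient
reported alongside.

**FDR.** q-values are Benjamini–Hochberg, computed separately within each of
five result families: univariate heritability, Spearman correlation,
phenotypic correlation, genetic correlation, environmental correlation. The
phenotypic-correlation p-value is the joint LRT of $r_g = r_e = 0$
($\chi^2_2$), a choice made here because the derived $r_p$ has no
single-parameter null; the original report does not document its test.

## Problem sizes and what the tests show

The validation suite runs at sizes chosen to separate estimator properties
from sampling noise. Oracle-equivalence checks (grid search over $(h^2,
V_p)$ and $(r_g, r_e)$, dense multivariate-normal likelihoods, gene
dropping) run on pedigrees of 3–8 members where exhaustive computation is
exact. Parameter recovery uses the cohort replicated tenfold (1,300
phenotyped members): the mean $\hat h^2$ over 50 replicates is within
±0.05 of each truth in {0.25, 0.5, 0.75}, and the mean $\hat r_g$ within
±0.1 of 0.8. The boundary-mixture LRT is calibrated on the single cohort
(n = 130) over 1,000 null simulations, with empirical size in [0.03, 0.07]
at nominal 0.05.

At the single-cohort size the ML estimator shows the expected small-sample
behavior: with SE ≈ 0.2 and $\hat h^2$ truncated to $[0, 1]$, the mean
estimate sits a few hundredths below a truth of 0.74 and individual draws
scatter widely — the same order of uncertainty as the published standard
errors. Single-cohort results should therefore be read with their standard
errors, not as point recoveries; the recovery guarantees above are
statements about the estimator at 10× scale.

## Known limitations

- Additive genetics only: no household, dominance or gene–environment
  interaction components; shared-environment variance would inflate $h^2$.
- Founders are assumed unrelated and non-inbred; the recursion supports
  inbred descendants but the shipped cohort is non-inbred.
- X-linked kinship, marker-based identity-by-descent and genotype data are
  out of scope.
- The bivariate fit maximizes a 6-parameter likelihood numerically; with
  n = 130 and weak signal the $r_g$ surface is flat and estimates frequently
  hit $\pm 1$, which the code flags rather than hides.
- Missing covariates are not imputed; rows with missing traits must be
  handled by the caller.
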