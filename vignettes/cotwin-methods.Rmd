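---
title: "Co-twin control analysis of education and dementia: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-twin control analysis of education and dementia: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotwin)
```

## The scientific question

Lower educational attainment is a widely cited modifiable risk factor for
dementia, but the association could instead reflect familial confounding:
genes and rearing environments that push both education and dementia risk.
The co-twin control design separates these explanations. Twins from the
same family share their rearing environment; monozygotic (MZ) twins
additionally share all their segregating genes, dizygotic (DZ) twins on
average half. If education causally protects against dementia, the
better-educated twin of a pair should have lower dementia risk *within* MZ
pairs. If the within-pair effect vanishes in MZ pairs but survives in DZ
pairs, additive-genetic confounding is implicated; if it vanishes in both
while the between-family effect remains, shared environment is.

This package implements that full analysis chain as tested code: a twin
cohort simulator with known ground truth, variable harmonization, the
education-discrepant matched-pair comparison, the between-within
generalized linear mixed model, and the classification and sensitivity
rules.

## The between-within model

For dementia status $Dx_{ij}$ of twin $i$ in pair $j$, the full model on
the logit scale is

$$\mathrm{logit}\,P(Dx_{ij}=1) = \pi_{0j} + \pi_1 \overline{Educ}_j +
\pi_2 (Educ_{ij} - \overline{Educ}_j) + \pi_3 Zyg_j +
\pi_4 (Educ_{ij} - \overline{Educ}_j) Zyg_j + \pi_5 Female_{ij} + \cdots +
\pi_9' \mathbf{c}_{ij},$$

with $\pi_{0j} = \gamma_{00} + u_{0j}$, $u_{0j} \sim N(0,
\sigma^2_{zyg(j)})$ a pair-level random intercept whose variance differs
between MZ and DZ pairs, $\overline{Educ}_j$ the pair mean of the
3-category education score (the between-family exposure) and the deviation
from it the within-family exposure, and $Zyg_j$ coded DZ = 1, MZ = 0.
Covariates (age centered at 60 years, study indicators, and study-by-female
indicators when several studies are present) enter every model. Five models
form a ladder: (1) raw education only — the phenotypic effect,
conceptually $\pi_1 + \pi_2$; (2) the between/within split; (3) zygosity
and its interaction with the within deviation; (4) the female main effect;
(5) all female interactions.

Under DZ = 1 coding, $\pi_2$ is the within-pair effect in MZ twins once
the interaction is in the model, and $\pi_2 + \pi_4$ the within effect in
DZ twins. A significant protective $\pi_2$ is the quasi-causal signature;
a null $\pi_2$ with significant $\pi_1$ and $\pi_4$ is the
additive-genetic confounding signature; a null interaction points to
shared environment. `classify_confounding()` encodes exactly these rules,
with a `familial_unspecified` verdict when no Model 3 is available (for
example in small subgroups where only the first models can be fit).

### Estimation

The model is a logistic random-intercept model with heterogeneous
(zygosity-specific) intercept variances. `fit_bw_glmm()` maximizes the
exact marginal likelihood: each pair's likelihood contribution integrates
the Bernoulli kernel over its random intercept by adaptive Gauss–Hermite
quadrature (AGHQ), with the nodes recentered at the pair's conditional
mode and rescaled by the local curvature. The default 15 nodes give
single-pair likelihoods accurate to about $10^{-9}$ against brute-force
integration, and fitted coefficients stable to $<10^{-4}$ between 15 and
25 nodes. Optimization is quasi-Newton (BFGS) on the fixed effects and
log-variances, started from an ordinary logistic regression with variances
at 0.5, with the analytic score obtained from Fisher's identity (the
posterior expectation of the complete-data score over the same nodes).
Convergence is declared when each gradient component, scaled by the
corresponding parameter's standard error, is below $5 \times 10^{-3}$ —
i.e. the optimum is located to within a few thousandths of a standard
error, orders of magnitude below inferential relevance.
Standard errors come from the inverted observed information; variance-
component standard errors are delta-method transforms from the log scale.

Two deliberate departures from the original computing environment are
documented rather than imitated. First, the reference analyses were run in
a pseudo-likelihood framework that also estimates zygosity-specific
residual scale factors on the working response; a true maximum-likelihood
binomial fit has no such free residual scale, so this package estimates
zygosity-specific random-intercept variances only, and no pseudo-likelihood
mode is provided — an approximate second estimator would add an untested
surface without changing any scientific conclusion the package supports.
Second, the model display can be read with a log link; because the
reported effects are changes in log-odds and the outcome is binary, the
logit link is the default, with `link = "log"` available.

Education enters as a numeric 1–3 score (one coefficient per term),
matching the single-row presentation of the reference tables; dummy coding
is available via `educ_coding = "dummy"`. The between-pair mean is not
centered by default (`center_between` exists because centering changes
only the intercept, and leaving it raw keeps the intercept interpretable
at education = 0). Singletons are retained with within-deviation 0 and
their own random intercept. A Gaussian-identity family is provided for
continuous outcomes and for the degenerate check that with zero variance
the fit reproduces ordinary least squares exactly.

## The simulator and what it emulates

`simulate_cohort()` draws per-pair liabilities for education and dementia
from a bivariate ACE model: each liability is $aA + cC + eE$ with
$a^2+c^2+e^2=1$; A correlates 1 within MZ and 0.5 within DZ pairs, C is
pair-shared, E individual; the two traits' components correlate
$r_A, r_C, r_E$; and an optional causal path adds $\beta_{causal} L_{edu}$
to the dementia liability. The causal path is *not* restandardized — doing
so would entangle $\beta_{causal}$ with the variance components — so the
dementia-liability variance exceeds 1 by $\beta^2 + 2\beta\,\mathrm{cov}$
when the path is active; the documented closed forms account for this.

Observed phenotypes: ISCED 0–8 education from eight thresholds on the
education liability; a continuous latent-dementia-index (LDI) score as an
affine transform of the negated dementia liability plus Gaussian noise
(lower LDI = greater dementia likelihood); and a dementia indicator that
is a Bernoulli draw on a logistic risk model (clinical/registry strata) or
a deterministic LDI-cutoff call (LDI strata), mirroring the mixed
ascertainment of multi-study consortia. Registry-ascertained cases carry a
recorded age inflated by the known reporting delay (5 years for patient,
outpatient and drug registers; 7 for cause-of-death), which
`harmonize_cohort()` removes — so the simulator and harmonizer are
round-trip consistent. Onset ages for cases are uniform between 65 (or the
assessment age if lower) and the assessment age; this is a configurable
placeholder, not an epidemiological claim.

Default parameters were fixed once from the twin literature and the
descriptive shape of large aging-twin consortia: education
$a^2=0.40, c^2=0.25, e^2=0.35$; dementia $a^2=0.60, c^2=0.05, e^2=0.35$
(late-life dementia heritability near 0.6 with little shared environment);
log-odds slope $\lambda = 1.5$ per liability SD with baseline prevalence
near 11%; ISCED thresholds giving a 9-category mean near 2.9; LDI centered
at 6.5 with SD near 1.3. Sex enters the risk model only (no
sex-limitation ACE structure), since the reference analyses found no
interactions with sex. Opposite-sex pairs use the same liability
machinery and are DZ by construction.

What the simulator does *not* emulate: country-specific education systems
behind the ISCED coding, time-varying dementia incidence, survival/
mortality selection, diagnostic misclassification beyond the LDI noise
term, and assortative mating or dominance variance. Passing tests
therefore demonstrate that the estimator and decision rules recover the
truth of this generative family, not that any real cohort satisfies its
assumptions.

### Scenarios and calibration

`scenario_config()` bundles the study designs used by the checks:

* **null** — all cross-trait correlations and paths zero; used to verify
  the within-pair Wald test holds its 5% size (500 replicates of 1,000
  pairs in the shipped checks).
* **recovery** — a known direct log-odds effect of the 3-category score
  ($-0.5$) with the dementia liability fully pair-shared ($c^2=1$), so the
  generative model *is* a logistic random-intercept model and the
  between/within coefficients have an exact known truth. In this scenario
  the recorded age is the assessment age for everyone: recording onset age
  for cases (as real ascertainment does) makes the age covariate
  outcome-dependent, and no fixed coefficient truth would exist.
* **quasi_causal** — a protective liability-scale path
  ($\beta_{causal}=-0.6$), no confounding.
* **genetic_confounding** — a protective additive-genetic correlation
  ($|r_A| = 0.8$), no causal path. The correlation is negative (higher
  education liability, lower dementia liability) so that the confounded
  association is protective, matching the sign structure of the reference
  results.

Replicate sizes for the verdict-rate checks were chosen by simulated Wald
power: at 20,000 pairs the zygosity-interaction noncentrality is about 5,
putting interaction power near 0.999, so the end-to-end verdict is
`genetic_confounding` in ≈97% of replicates (the ceiling is set by the
2.5% chance of a spuriously protective-significant MZ within effect, which
the rules classify as quasi-causal). The shipped checks run 40 replicates
at that size; the quasi-causal analogue runs at 8,000 pairs where the MZ
within-effect power is also near 1.

## Matched-pair and sensitivity analyses

`find_discrepant_pairs()` keeps twin pairs whose members differ in ISCED
category and reports the LDI of the higher-educated member minus that of
the lower-educated member; `match_unrelated()` builds the non-twin
comparison by pairing individuals matched exactly on sex and birth year,
shuffled with a seeded RNG and drawn without replacement (same-family
pairings are reshuffled, up to 100 attempts per stratum, then reported as
unmatched). Opposite-sex DZ pairs form their own stratum with no unrelated
analogue. `diff_by_group()` summarizes each pair type with the matched
t-test $t = \bar d/(s_d/\sqrt n)$; zero-variance difference vectors are
flagged degenerate rather than producing infinities. Under genetic
confounding the mean difference attenuates from unrelated to DZ to MZ
pairs, with the MZ difference indistinguishable from zero. Note that even
under a purely causal liability path the *per-discrepant-pair* difference
is not equal across pair types: conditioning on ISCED discrepancy selects
larger underlying liability gaps in unrelated pairs than in MZ pairs, so
some attenuation in this display is expected under causality too — the
model-based within-pair coefficients, not this display, carry the causal
test.

`find_discordant_pairs()` implements the survival-aware sensitivity
analysis: dementia-discordant pairs where the unaffected co-twin was last
seen after the affected twin's onset. The education comparison is
tabulated by study and zygosity and tested with an exact binomial sign
test against 0.5; the two-sided p doubles the smaller tail (including the
observed point) and is capped at 1 — a mid-p variant is deliberately not
used, keeping the test conservative. Equal-education pairs are tabulated
but excluded from the test denominator. `delayed_onset_variant()` adds
both-affected pairs whose onsets differ by at least 5 years (configurable),
treating the later twin as the control, to probe onset delay rather than
prevention.

## Numerical and degenerate-input policy

* Variances are optimized on the log scale and never go negative; fits at
  the zero-variance boundary are available through `fix_sigma2`.
* With both variances zero the AGHQ integral collapses analytically to
  the fixed-effects Bernoulli likelihood (tested to $10^{-6}$ against a
  reference logistic regression).
* Coefficients beyond 15 in absolute value on the link scale raise a
  separation flag; non-convergence returns the fit with
  `converged = FALSE`, and `classify_confounding()` refuses unconverged
  input rather than classifying noise.
* ISCED values outside 0–8, non-increasing thresholds, non-positive ages
  and unknown ascertainment labels are validation errors; missing values
  propagate and are flagged with reason codes rather than dropped, so
  record counts are conserved through harmonization and the accounting
  identities ($N = 2 \times$ pairs $+$ singletons, percentage =
  $100 \times$ numerator/denominator) hold exactly.
* All randomness flows from explicit seeds: a cohort is byte-identical
  when re-simulated with the same config, and the matching shuffle is
  reproducible given its seed.

## Problem sizes in the shipped checks

The test suite exercises the estimator at the sizes the scientific claims
need: 100,000 pairs for simulator calibration (Monte-Carlo standard errors
near 0.002), 20,000 pairs for parameter recovery and the confounding
signature, 40 verdict replicates of 20,000 pairs, and 500 null replicates
of 1,000 pairs for test size. The analysis scripts under `analysis/` use
5,000-pair cohorts, where every qualitative conclusion is already stable.

## Known limitations

* The estimator supports one random intercept per pair; no crossed or
  nested random effects beyond the pair, and no survival modelling of
  onset — onset enters only through the discordant-pair sensitivity rules.
* Wald inference is first-order; for very sparse subgroups (few pairs per
  zygosity) profile-likelihood intervals would be preferable and are not
  implemented.
* The log-link binomial option clamps fitted probabilities below 1 and can
  be fragile far from the null; it exists for comparability, not as the
  recommended analysis.
* The unrelated-pair matching is exact on birth year with no caliper; in
  small strata this reports unmatched individuals rather than loosening
  the match.
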