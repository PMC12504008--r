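# cotwin

Co-twin control analysis of educational attainment and dementia risk.

Lower education is a headline modifiable risk factor for dementia, but the
association could instead be familial: genes and shared rearing
environments that influence both how far people go in school and their
late-life dementia risk. Twin pairs let the two explanations be separated.
Monozygotic (MZ) co-twins share all their segregating genes and their
rearing environment; dizygotic (DZ) co-twins share half their genes on
average and their rearing environment. A causal effect of education must
survive *within* MZ pairs; genetic confounding shows up as a within-pair
effect that is present in DZ but absent in MZ pairs.

`cotwin` is an analysis workflow built on a tested package. It provides:

* **a twin-cohort simulator** with known ground truth under a bivariate
  ACE liability model (additive genetic, shared and nonshared environment
  for both traits, cross-trait component correlations `rA`, `rC`, `rE`,
  and an optional causal liability path), producing ISCED-coded education,
  a continuous latent dementia index (LDI, lower = more impaired), and
  clinical / registry / LDI-cutoff dementia ascertainment across study
  strata;
* **harmonization** rules: ISCED 0–8 collapsed to a 3-category score
  (0–2 / 3–5 / 6–8), registry onset-age delay removal (−5 years for
  patient/outpatient/drug registers, −7 for cause-of-death), age capped at
  90 and centered at 60, LDI-cutoff dementia calls, and exclusion flags
  that conserve record counts;
* **education-discrepant matched pairs**: within-pair LDI differences for
  twin pairs differing in ISCED category, and for unrelated pairs matched
  on sex and birth year, summarized by matched t-tests per pair type;
* **the between-within mixed model**: for twin $i$ in pair $j$,

  $$\mathrm{logit}\,P(Dx_{ij}=1) = \gamma_{00} + u_{0j} +
  \pi_1 \overline{Educ}_j + \pi_2 (Educ_{ij}-\overline{Educ}_j) +
  \pi_3 Zyg_j + \pi_4 (Educ_{ij}-\overline{Educ}_j)Zyg_j + \cdots$$

  with $u_{0j} \sim N(0, \sigma^2_{zyg(j)})$ — zygosity-specific
  random-intercept variances — fit by exact maximum likelihood with
  adaptive Gauss–Hermite quadrature, implemented in this package
  (C++ core, analytic score via Fisher's identity);
* **decision rules and sensitivity analyses**: classification of the fit
  pattern into quasi-causal / genetic confounding / shared-environmental
  confounding / no association, dementia-discordant pairs whose co-twin
  control outlived the onset, exact sign tests, and a delayed-onset
  variant.

## Worked example

```r
library(cotwin)

# a cohort with pure additive-genetic confounding and no causal effect
sc  <- scenario_config("genetic_confounding", n_pairs = 5000, seed = 1)
coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                        ldi_cutoff = sc$cfg$ldi_cutoff)

fits <- fit_bw_models(coh, models = 2:3)
print(classify_confounding(fits$model2, fits$model3))
```

```
Confounding classification: genetic_confounding 
  pi1        estimate  -0.8117   p 1.715e-27
  pi2_model2 estimate  -0.2985   p 0.001874
  pi2        estimate   0.0656   p 0.6926
  pi4        estimate  -0.5449   p 0.007473
  alpha = 0.05 
```

Read: the between-family education effect (`pi1`) is strongly protective,
the naive within-family effect (`pi2_model2`) looks protective too — but
once the zygosity interaction is added, the within effect in MZ twins
(`pi2`) is null while DZ pairs carry a significant extra within effect
(`pi4`): the association is genetically confounded, which is exactly how
this cohort was generated.

The matched-pair view of the same cohort shows the attenuation pattern —
mean within-pair LDI difference (higher-educated minus lower-educated
member) of about 0.65 in unrelated pairs, 0.43 in DZ pairs, and ~0 in MZ
pairs:

```r
twin <- find_discrepant_pairs(coh)
un   <- match_unrelated(coh, seed = 2)
diff_by_group(rbind(twin, un))
```

The numbered scripts under `analysis/` run the full chain on all
scenarios (`01_simulate_cohorts.R` … `05_sensitivity_classification.R`),
writing tables under `results/`.

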