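test_that("closed-form twin correlations follow the ACE sharing rules", {
  a <- ace_params(a2_edu = 1, c2_edu = 0, e2_edu = 0,
                  a2_dem = 0, c2_dem = 0, e2_dem = 1)
  expect_equal(expected_twin_correlation(a, "edu", "MZ"), 1.0)
  expect_equal(expected_twin_correlation(a, "dem", "DZ"), 0.0)
  b <- ace_params(a2_edu = 0.5, c2_edu = 0.2, e2_edu = 0.3)
  expect_equal(expected_twin_correlation(b, "edu", "DZ"), 0.45)
  expect_equal(expected_twin_correlation(b, "edu", "MZ"), 0.7)
})

test_that("invalid ACE parameter sets are rejected", {
  expect_error(ace_params(a2_edu = 0.5, c2_edu = 0.2, e2_edu = 0.2),
               "sum to 1")
  expect_error(ace_params(a2_edu = -0.1, c2_edu = 0.6, e2_edu = 0.5),
               "non-negative")
  expect_error(ace_params(rA = 1.2), "\\[-1, 1\\]")
  # per-pair covariance carries unit diagonal and the cross-twin block
  S <- pair_covariance(ace_params(rA = -0.8), "DZ")
  expect_equal(diag(S), setNames(rep(1, 4), colnames(S)))
  expect_equal(S["edu_1", "edu_2"], 0.5 * 0.40 + 0.25)
})

test_that("empirical within-pair correlations match closed forms", {
  set.seed(101)
  grid <- list(
    ace_params(a2_edu = 0.5, c2_edu = 0.2, e2_edu = 0.3,
               a2_dem = 0.5, c2_dem = 0.2, e2_dem = 0.3),
    ace_params(a2_edu = 0.8, c2_edu = 0.0, e2_edu = 0.2,
               a2_dem = 0.3, c2_dem = 0.4, e2_dem = 0.3))
  n <- 1e5
  for (ace in grid) for (zyg in c("MZ", "DZ")) {
    d <- draw_pair_components(ace, zyg, n)
    for (trait in c("edu", "dem")) {
      r_hat <- if (trait == "edu") cor(d$edu_liab_1, d$edu_liab_2)
               else cor(d$dem_liab_1, d$dem_liab_2)
      r_exp <- expected_twin_correlation(ace, trait, zyg)
      mc_se <- (1 - r_exp^2) / sqrt(n)
      expect_lt(abs(r_hat - r_exp), 3 * mc_se)
    }
  }
  # MZ similarity exceeds DZ whenever additive-genetic variance is present
  for (ace in grid) {
    mz <- draw_pair_components(ace, "MZ", n)
    dz <- draw_pair_components(ace, "DZ", n)
    expect_gt(cor(mz$edu_liab_1, mz$edu_liab_2),
              cor(dz$edu_liab_1, dz$edu_liab_2))
  }
})

test_that("cross-trait liability correlation matches the component formula", {
  # within-person cov = aE aD rA + cE cD rC + eE eD rE
  set.seed(7)
  ace <- ace_params(a2_edu = 0.6, c2_edu = 0.2, e2_edu = 0.2,
                    a2_dem = 0.4, c2_dem = 0.2, e2_dem = 0.4, rA = 0.8)
  d <- draw_pair_components(ace, "MZ", 1e5)
  expect_lt(abs(cor(d$edu_liab_1, d$dem_liab_1) -
                  0.8 * sqrt(0.6 * 0.4)), 0.01)
  # and the causal path shifts the dementia liability by beta * edu
  ace2 <- ace_params(beta_causal = -0.6)
  d2 <- draw_pair_components(ace2, "DZ", 1e5)
  expect_lt(abs(cov(d2$edu_liab_1, d2$dem_liab_1) - (-0.6)), 0.02)
})

test_that("liability-to-phenotype mapping respects thresholds and cutoffs", {
  cfg <- cohort_config(seed = 1)
  ph_lo <- liabilities_to_phenotypes(-10, 0, cfg, 70, 0, "clinical")
  ph_hi <- liabilities_to_phenotypes(10, 0, cfg, 70, 0, "clinical")
  expect_equal(ph_lo$isced9, 0L)
  expect_equal(ph_hi$isced9, 8L)
  # noiseless LDI stratum: dementia call is exactly the cutoff indicator
  cfg0 <- cohort_config(ldi_noise_sd = 0, seed = 1)
  liab <- seq(-3, 3, length.out = 201)
  ph <- liabilities_to_phenotypes(liab, liab, cfg0, 70, 0,
                                  rep("ldi", 201))
  expect_equal(ph$dementia, as.integer(ph$ldi <= cfg0$ldi_cutoff))
  bad <- cfg
  bad$isced_thresholds <- rev(bad$isced_thresholds)
  expect_error(liabilities_to_phenotypes(0, 0, bad, 70, 0, "clinical"),
               "strictly increasing")
})

test_that("ISCED marginal matches normal-CDF increments of the thresholds", {
  cfg <- cohort_config(seed = 2)
  set.seed(2)
  liab <- rnorm(1e5)
  ph <- liabilities_to_phenotypes(liab, rnorm(1e5), cfg, 70, 0,
                                  rep("clinical", 1e5))
  probs <- diff(c(0, pnorm(cfg$isced_thresholds), 1))
  obs <- tabulate(ph$isced9 + 1L, nbins = 9)
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulated cohorts have the promised structure", {
  ace <- ace_params()
  cfg <- cohort_config(n_pairs_by_type = c(MZF = 1, MZM = 1, DZF = 1,
                                           DZM = 1, DZOS = 1), seed = 3)
  coh <- simulate_cohort(cfg, ace)
  expect_equal(nrow(coh), 10L)
  expect_equal(length(unique(coh$pair_id)), 5L)
  # same seed reproduces byte-identically; different seed does not
  cfg2 <- cohort_config(n_pairs_by_type = c(MZF = 40, MZM = 0, DZF = 40,
                                            DZM = 0, DZOS = 20),
                        n_singletons = 5, seed = 9)
  expect_identical(simulate_cohort(cfg2, ace), simulate_cohort(cfg2, ace))
  cfg3 <- cohort_config(n_pairs_by_type = c(MZF = 40, MZM = 0, DZF = 40,
                                            DZM = 0, DZOS = 20),
                        n_singletons = 5, seed = 10)
  expect_false(identical(simulate_cohort(cfg2, ace),
                         simulate_cohort(cfg3, ace)))
  coh2 <- simulate_cohort(cfg2, ace)
  # pairs share id, study and (same-sex types) sex; DZOS pairs are DZ
  m1 <- coh2[coh2$member == 1L, ]
  m2 <- coh2[coh2$member == 2L, ]
  shared <- intersect(m1$pair_id, m2$pair_id)
  i1 <- m1[match(shared, m1$pair_id), ]
  i2 <- m2[match(shared, m2$pair_id), ]
  expect_true(all(i1$study == i2$study))
  expect_true(all(i1$female[i1$same_sex == 1L] ==
                    i2$female[i2$same_sex == 1L]))
  expect_true(all(i1$zygosity[i1$same_sex == 0L] == "DZ"))
  expect_equal(nrow(coh2), 2 * 100 + 5)
  expect_error(simulate_cohort(
    cohort_config(n_pairs_by_type = c(MZF = 0, MZM = 0, DZF = 0, DZM = 0,
                                      DZOS = 0), seed = 1), ace),
    "empty cohort")
})

test_that("a consortium-shaped config at 1% scale yields 601 records", {
  cfg <- config_consortium(scale = 0.01, seed = 4)
  coh <- simulate_cohort(cfg, ace_params())
  expect_equal(nrow(coh), 601L)   # 2 x 299 pairs + 3 singletons
})

test_that("uncorrelated traits produce no education-dementia association", {
  sc <- scenario_config("null", n_pairs = 50000, seed = 12)
  coh <- simulate_cohort(sc$cfg, sc$ace)
  h <- harmonize_cohort(coh, ldi_cutoff = sc$cfg$ldi_cutoff)
  g <- glm(dementia ~ educ3 + age_centered + female, binomial(), data = h)
  z <- coef(summary(g))["educ3", "z value"]
  expect_lt(abs(z), 3)
})
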