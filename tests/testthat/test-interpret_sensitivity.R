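test_that("classification reproduces the canonical decision patterns", {
  m2 <- make_fit_stub(c("intercept", "educ_between", "educ_within"),
                      c(-0.81, -0.98, -0.07), c(0.05, 0.03, 0.04))
  # between strong, MZ within null, zygosity interaction present:
  # additive-genetic confounding
  m3 <- make_fit_stub(c("intercept", "educ_between", "educ_within",
                        "zyg", "educ_within:zyg"),
                      c(-0.80, -0.98, 0.13, -0.02, -0.26),
                      c(0.06, 0.03, 0.09, 0.03, 0.10))
  v <- classify_confounding(m2, m3)
  expect_equal(v$verdict, "genetic_confounding")
  expect_equal(unname(v$evidence$pi4["estimate"]), -0.26)
  # protective significant MZ within effect: quasi-causal
  m3q <- make_fit_stub(c("educ_between", "educ_within", "educ_within:zyg"),
                       c(-0.5, -0.4, 0.05), c(0.05, 0.08, 0.10))
  expect_equal(classify_confounding(m2, m3q)$verdict, "quasi_causal")
  # null interaction with familial between effect: shared environment
  m3s <- make_fit_stub(c("educ_between", "educ_within", "educ_within:zyg"),
                       c(-0.5, 0.02, -0.03), c(0.05, 0.08, 0.10))
  expect_equal(classify_confounding(m2, m3s)$verdict,
               "shared_env_confounding")
  # nothing significant anywhere: no association
  m2n <- make_fit_stub(c("educ_between", "educ_within"),
                       c(-0.02, 0.01), c(0.05, 0.05))
  expect_equal(classify_confounding(m2n, m3s)$verdict, "no_association")
  # familial effect without a testable zygosity interaction
  expect_equal(classify_confounding(m2, NULL)$verdict,
               "familial_unspecified")
  # refusal on unconverged input
  bad <- make_fit_stub("educ_between", -1, 0.1, converged = FALSE)
  expect_error(classify_confounding(bad, NULL), "refused")
})

test_that("classification is insensitive to coefficient-table row order", {
  m2 <- make_fit_stub(c("educ_within", "educ_between"),
                      c(-0.07, -0.98), c(0.04, 0.03))
  m3 <- make_fit_stub(c("educ_within:zyg", "zyg", "educ_within",
                        "educ_between"),
                      c(-0.26, -0.02, 0.13, -0.98),
                      c(0.10, 0.03, 0.09, 0.03))
  expect_equal(classify_confounding(m2, m3)$verdict, "genetic_confounding")
})

test_that("exact sign test matches binomial enumeration", {
  expect_equal(sign_test(7, 3)$p_two_sided, 0.34375)
  expect_equal(sign_test(5, 5)$p_two_sided, 1.0)
  expect_equal(sign_test(0, 8)$p_two_sided, 2 / 256)
  expect_error(sign_test(0, 0), "insufficient")
  # enumeration oracle: double the smaller exact tail, capped at 1
  for (n in c(1, 2, 5, 10, 17, 20)) for (k in 0:n) {
    probs <- dbinom(0:n, n, 0.5)
    p_enum <- min(1, 2 * min(sum(probs[seq_len(k + 1)]),
                             sum(probs[seq(k + 1, n + 1)])))
    expect_equal(sign_test(k, n - k)$p_two_sided, p_enum,
                 info = sprintf("n=%d k=%d", n, k))
  }
})

test_that("discordant pairs require the control to outlive the onset", {
  coh <- toy_cohort(isced9_1 = c(6L, 6L, 3L), isced9_2 = c(2L, 2L, 3L),
                    dementia1 = 1L, dementia2 = 0L,
                    onset1 = 75, age = 80)
  # control last seen at 80 > onset 75: all three pairs qualify
  d <- find_discordant_pairs(coh)
  expect_equal(nrow(d), 3L)
  expect_equal(d$educ_comparison, c("affected_higher", "affected_higher",
                                    "equal"))
  # control died before onset: excluded
  coh2 <- coh
  coh2$age[coh2$member == 2L] <- 72
  expect_equal(nrow(find_discordant_pairs(coh2)), 0L)
  # concordant-unaffected pairs never appear
  coh3 <- toy_cohort(5L, 2L, dementia1 = 0L, dementia2 = 0L)
  expect_equal(nrow(find_discordant_pairs(coh3)), 0L)
})

test_that("delayed-onset variant augments with late-onset co-twins only", {
  both <- toy_cohort(isced9_1 = c(6L, 6L), isced9_2 = c(2L, 2L),
                     dementia1 = 1L, dementia2 = 1L,
                     onset1 = 70, onset2 = 76, age = 80)
  both$onset_age[both$pair_id == "T002" & both$member == 2L] <- 73
  v <- delayed_onset_variant(both, min_gap = 5)
  expect_equal(nrow(v$pairs), 1L)            # gap 6 in, gap 3 out
  expect_true(all(v$pairs$delayed_onset))
  expect_equal(v$pairs$educ_comparison, "affected_higher")
  # with no both-affected pairs the variant equals the base analysis
  disc <- toy_cohort(c(6L, 4L), c(2L, 5L), dementia1 = 1L, dementia2 = 0L,
                     onset1 = 75, age = 80)
  v2 <- delayed_onset_variant(disc, min_gap = 5)
  base <- find_discordant_pairs(disc)
  expect_equal(v2$pairs[names(base)], base)
})

test_that("frequency table stratifies by study and zygosity with exact p", {
  coh <- rbind(toy_cohort(rep(6L, 4), rep(2L, 4), zygosity = "MZ",
                          dementia1 = 1L, dementia2 = 0L, onset1 = 70,
                          age = 80, study = "A"),
               within(toy_cohort(rep(2L, 3), rep(7L, 3), zygosity = "DZ",
                                 dementia1 = 1L, dementia2 = 0L,
                                 onset1 = 72, age = 80, study = "B"),
                      pair_id <- paste0(pair_id, "x")))
  tab <- discordant_frequency_table(coh)
  expect_equal(nrow(tab), 2L)
  a <- tab[tab$study == "A", ]
  expect_equal(a$affected_higher, 4L)
  expect_equal(a$p_sign_test, sign_test(4, 0)$p_two_sided)
  b <- tab[tab$study == "B", ]
  expect_equal(b$control_higher, 3L)
})

test_that("end-to-end verdicts recover the quasi-causal generative truth", {
  # protective liability-scale causal path, no confounding; replicate size
  # chosen for near-unit Wald power on the MZ within effect
  hits <- 0L
  for (r in 1:8) {
    sc <- scenario_config("quasi_causal", n_pairs = 8000, seed = 500 + r)
    coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                            sc$cfg$ldi_cutoff)
    fits <- fit_bw_models(coh, models = 2:3)
    v <- tryCatch(classify_confounding(fits$model2, fits$model3),
                  error = function(e) list(verdict = "refused"))
    if (v$verdict == "quasi_causal") hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})
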