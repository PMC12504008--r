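test_that("between/within decomposition reconstructs the exposure", {
  coh <- toy_cohort(isced9_1 = c(0L, 4L, 8L), isced9_2 = c(8L, 4L, 5L))
  d <- decompose_exposure(coh)
  p1 <- d[d$pair_id == "T001", ]
  expect_equal(p1$educ_between, c(2, 2))     # educ3 (1, 3) -> mean 2
  expect_equal(p1$educ_within, c(-1, 1))
  p2 <- d[d$pair_id == "T002", ]
  expect_equal(p2$educ_within, c(0, 0))
  # reconstruction and exact zero-sum inside complete pairs
  expect_equal(d$educ_between + d$educ_within, as.numeric(d$educ3))
  sums <- tapply(d$educ_within, d$pair_id, sum)
  expect_equal(as.numeric(sums), rep(0, 3))
  # singleton: between = own value, within = 0
  single <- toy_cohort(6L, 6L)[1, ]
  ds <- decompose_exposure(single)
  expect_equal(ds$educ_between, 3)
  expect_equal(ds$educ_within, 0)
})

test_that("design matrices follow the model ladder", {
  sc <- scenario_config("null", n_pairs = 50, seed = 31)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  cols <- function(m) colnames(build_design(coh, m)$X)
  expect_setequal(cols(1), c("intercept", "educ", "age_c"))
  expect_setequal(cols(2), c("intercept", "educ_between", "educ_within",
                             "age_c"))
  expect_setequal(cols(3), c("intercept", "educ_between", "educ_within",
                             "zyg", "educ_within:zyg", "age_c"))
  expect_setequal(cols(4), c(cols(3), "female"))
  expect_setequal(cols(5), c(cols(4), "female:educ_within", "female:zyg",
                             "female:zyg:educ_within"))
  expect_error(build_design(coh, 6), "unknown model_id")
  # multi-study cohorts gain study and study-by-female indicator columns
  cfg2 <- config_consortium(scale = 0.003, seed = 31)
  coh2 <- harmonize_cohort(simulate_cohort(cfg2, sc$ace),
                           cfg2$ldi_cutoff)
  expect_true(any(grepl("^study:", cols_multi <- colnames(
    build_design(coh2, 2)$X))))
  expect_true(any(grepl(":female$", cols_multi)))
})

test_that("AGHQ marginal likelihood matches brute-force integration", {
  cases <- list(list(eta = c(0, 0), y = c(1, 0), s2 = 1),
                list(eta = c(0.5, -0.3), y = c(1, 1), s2 = 0.4),
                list(eta = c(-1, 2), y = c(0, 0), s2 = 2.5),
                list(eta = 0.7, y = 1, s2 = 1.2))   # singleton
  for (cs in cases) {
    des <- one_pair_design(cs$eta, cs$y)
    ll <- marginal_loglik(list(beta = 1, s2_mz = cs$s2, s2_dz = 99),
                          des, n_quad = 20)
    oracle <- brute_force_pair_loglik(cs$eta, cs$y, cs$s2)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("zero-variance limit equals the plain Bernoulli GLM likelihood", {
  sc <- scenario_config("null", n_pairs = 400, seed = 41)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  d <- build_design(coh, 2)
  g <- glm.fit(d$X, d$y, family = binomial())
  ll <- marginal_loglik(list(beta = g$coefficients, s2_mz = 0, s2_dz = 0), d)
  expect_equal(ll, sum(dbinom(d$y, 1, g$fitted.values, log = TRUE)),
               tolerance = 1e-6)
})

test_that("log-likelihood is additive over pairs", {
  des1 <- one_pair_design(c(0.3, -0.8), c(1, 0))
  params <- list(beta = 1, s2_mz = 0.9, s2_dz = 0.9)
  ll1 <- marginal_loglik(params, des1)
  des2 <- structure(list(X = rbind(des1$X, des1$X), y = c(des1$y, des1$y),
                         pair_start = c(0L, 2L), pair_len = c(2L, 2L),
                         pair_dz = c(0L, 0L), n_obs = 4L, n_pairs = 2L,
                         model_id = 2), class = "bw_design")
  expect_equal(marginal_loglik(params, des2), 2 * ll1, tolerance = 1e-12)
})

test_that("variance-free fits reproduce reference GLM and OLS solutions", {
  sc <- scenario_config("null", n_pairs = 300, seed = 51)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  coh <- coh[coh$member == 1L, ]    # single-member "pairs"
  d <- build_design(coh, 1)   # within column would be aliased at 0
  f <- fit_bw_glmm(d, fix_sigma2 = c(0, 0))
  ref <- glm.fit(d$X, d$y, family = binomial())
  expect_equal(unname(f$coefficients$estimate),
               unname(ref$coefficients), tolerance = 1e-6)
  # Gaussian-identity kernel with zero variance = closed-form OLS
  fg <- fit_bw_glmm(d, family = "gaussian", fix_sigma2 = c(0, 0))
  ols <- lm.fit(d$X, d$y)
  expect_equal(unname(fg$coefficients$estimate),
               unname(ols$coefficients), tolerance = 1e-8)
})

test_that("estimates are stable in the number of quadrature nodes", {
  sc <- scenario_config("genetic_confounding", n_pairs = 2000, seed = 61)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  d <- build_design(coh, 2)
  f15 <- fit_bw_glmm(d, n_quad = 15)
  f25 <- fit_bw_glmm(d, n_quad = 25,
                     start = list(beta = f15$coefficients$estimate,
                                  s2_mz = f15$var_pair_mz,
                                  s2_dz = f15$var_pair_dz))
  expect_lt(max(abs(f15$coefficients$estimate - f25$coefficients$estimate)),
            1e-4)
})

test_that("the equal-variance fit agrees with an independent GLMM routine", {
  skip_if_not_installed("lme4")
  sc <- scenario_config("recovery", n_pairs = 1500, seed = 71)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  d <- build_design(coh, 2)
  f <- fit_bw_glmm(d, het_variance = FALSE)
  dat <- data.frame(y = d$y, d$X[, -1],
                    pair = rep(seq_along(d$pair_len), d$pair_len))
  gm <- lme4::glmer(y ~ educ_between + educ_within + age_c + (1 | pair),
                    data = dat, family = binomial, nAGQ = 15)
  expect_equal(unname(f$coefficients$estimate),
               unname(lme4::fixef(gm)), tolerance = 1e-3)
  expect_equal(f$var_pair_mz,
               unname(unlist(lme4::VarCorr(gm))), tolerance = 1e-2)
  expect_equal(-f$minus2LL / 2, as.numeric(stats::logLik(gm)),
               tolerance = 1e-4)
})

test_that("Wald summary flags significance at the requested level", {
  stub <- make_fit_stub(c("educ_between", "educ_within"),
                        c(-0.26, 0.13), c(0.10, 0.09))
  tab <- wald_summary(stub, alpha = 0.05)
  expect_equal(tab$z, c(-2.6, 13 / 9), tolerance = 1e-12)
  expect_equal(tab$p[1], 0.0093, tolerance = 1e-2)
  expect_true(tab$sig[1])
  expect_equal(tab$p[2], 0.149, tolerance = 1e-2)
  expect_false(tab$sig[2])
  zero <- make_fit_stub("educ_within", 0, 1)
  expect_equal(wald_summary(zero)$p, 1)
  expect_false(wald_summary(zero)$sig)
})

test_that("Wald and likelihood-ratio inference agree for large samples", {
  sc <- scenario_config("recovery", n_pairs = 6000, seed = 81)
  coh <- harmonize_cohort(simulate_cohort(sc$cfg, sc$ace),
                          sc$cfg$ldi_cutoff)
  d2 <- build_design(coh, 2)
  full <- fit_bw_glmm(d2)
  # drop educ_within for the reduced model
  d0 <- d2
  d0$X <- d2$X[, colnames(d2$X) != "educ_within"]
  red <- fit_bw_glmm(d0)
  lr <- red$minus2LL - full$minus2LL
  p_lr <- pchisq(lr, df = 1, lower.tail = FALSE)
  p_wald <- full$coefficients$p[full$coefficients$term == "educ_within"]
  expect_equal(signif(p_lr, 1), signif(p_wald, 1))
})
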