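# Independent oracles and small fixture builders used across the suite.

# Brute-force marginal log-likelihood for a single pair: trapezoid rule
# over u in [-10, 10]. Deliberately naive and independent of the AGHQ path.
brute_force_pair_loglik <- function(eta, y, s2, n_nodes = 1e5) {
  u <- seq(-10, 10, length.out = n_nodes + 1)
  logf <- sapply(u, function(uu) {
    p <- stats::plogis(eta + uu)
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      stats::dnorm(uu, 0, sqrt(s2), log = TRUE)
  })
  f <- exp(logf)
  log(sum((f[-1] + f[-length(f)]) / 2) * (u[2] - u[1]))
}

# Single-pair design wrapper for marginal_loglik
one_pair_design <- function(eta, y, dz = 0L) {
  structure(list(X = matrix(eta, ncol = 1, dimnames = list(NULL, "off")),
                 y = y, pair_start = 0L, pair_len = length(y),
                 pair_dz = as.integer(dz), n_obs = length(y),
                 n_pairs = 1L, model_id = 2),
            class = "bw_design")
}

# Minimal harmonized cohort from per-pair member vectors
toy_cohort <- function(isced9_1, isced9_2, zygosity = "MZ",
                       female1 = 0L, female2 = NULL, ldi1 = NULL,
                       ldi2 = NULL, dementia1 = 0L, dementia2 = 0L,
                       age = 75, birth_year = 1940, study = "S",
                       onset1 = NA, onset2 = NA) {
  n <- length(isced9_1)
  rec <- function(member, isced, fem, ldi, dem, onset) {
    data.frame(pair_id = sprintf("T%03d", seq_len(n)), member = member,
               zygosity = rep_len(zygosity, n), same_sex = 1L,
               female = rep_len(fem, n), black = 0L,
               study = rep_len(study, n), age = rep_len(age, n),
               birth_year = rep_len(birth_year, n),
               isced9 = isced, ldi = rep_len(ldi, n),
               dementia = rep_len(dem, n),
               onset_age = rep_len(onset, n),
               ascertainment = "clinical", stringsAsFactors = FALSE)
  }
  if (is.null(female2)) female2 <- female1
  if (is.null(ldi1)) ldi1 <- 6.5
  if (is.null(ldi2)) ldi2 <- 6.0
  coh <- rbind(rec(1L, isced9_1, female1, ldi1, dementia1, onset1),
               rec(2L, isced9_2, female2, ldi2, dementia2, onset2))
  harmonize_cohort(coh, ldi_cutoff = 4.9)
}

# Fit stub with a given coefficient table, for classification-rule tests
make_fit_stub <- function(terms, estimates, ses, converged = TRUE) {
  z <- estimates / ses
  structure(list(coefficients = data.frame(
    term = terms, estimate = estimates, se = ses, z = z,
    p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE),
    converged = converged), class = "bw_glmm_fit")
}
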