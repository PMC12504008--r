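#' Configuration of a simulated twin cohort
#'
#' Describes the structure of a synthetic cohort: pair counts by zygosity and
#' sex, singletons, study strata with their age distributions and dementia
#' ascertainment modes, the ISCED discretization of the education liability,
#' the LDI measurement model, and the dementia risk model.
#'
#' The dementia risk model for clinical/registry strata is
#' \deqn{\mathrm{logit}\,P(Dx=1) = \alpha + \lambda L_D +
#'   \beta_{educ} \cdot educ3 + \beta_{age}(age-60) + \beta_{fem} \cdot female}
#' where \eqn{L_D} is the (possibly causally shifted) dementia liability.
#' \code{beta_educ3} adds a direct log-odds effect of the observed
#' three-category education score, which gives scenarios with a known
#' coefficient-scale truth for parameter-recovery checks. In LDI strata the
#' dementia call is deterministic: impaired iff the noisy LDI score falls at
#' or below \code{ldi_cutoff} (lower LDI = greater dementia likelihood).
#'
#' @param n_pairs_by_type Named counts for the five pair types
#'   \code{c(MZF=, MZM=, DZF=, DZM=, DZOS=)}.
#' @param n_singletons Number of singleton records (one member of a pair).
#' @param studies Data frame of study strata with columns \code{study},
#'   \code{prop} (sampling weight), \code{age_mean}, \code{age_sd},
#'   \code{age_min}, \code{age_max} (years), \code{ascertainment}
#'   (\code{"clinical"}, \code{"registry"} or \code{"ldi"}) and
#'   \code{assess_year} (calendar year used to derive birth year).
#' @param isced_thresholds Eight strictly increasing cutpoints on the
#'   standard-normal education liability mapping to ISCED categories 0-8.
#' @param ldi_center,ldi_scale Affine transform of the (negated) dementia
#'   liability onto the LDI scale.
#' @param ldi_noise_sd Measurement noise SD of the LDI score.
#' @param ldi_cutoff Dementia threshold on the LDI scale (at or below =
#'   impaired).
#' @param alpha_dem Baseline log-odds of dementia at age 60, male, liability 0.
#' @param lambda Log-odds slope per SD of dementia liability.
#' @param beta_age Log-odds effect per year of age (centered at 60).
#' @param beta_female Log-odds effect of female sex.
#' @param beta_educ3 Direct log-odds effect of the 3-category education score.
#' @param p_black Probability a pair is coded Black (pair-level).
#' @param missing_rates Named per-field missingness probabilities for
#'   \code{zygosity}, \code{isced9}, \code{ldi}, \code{dementia}, \code{age}.
#' @param onset_min_age Floor (years) for the uniform onset-age draw of cases.
#' @param age_is_onset_for_cases Record onset age (rather than assessment
#'   age) as the age of cases, as clinical/registry ascertainment does
#'   (default TRUE). Set FALSE for estimator checks that need the model
#'   covariate to be outcome-independent.
#' @param seed Integer seed; all cohort randomness flows from it.
#' @return An object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_pairs_by_type = c(MZF = 250, MZM = 250,
                                              DZF = 250, DZM = 250, DZOS = 250),
                          n_singletons = 0,
                          studies = default_studies(),
                          isced_thresholds = default_isced_thresholds(),
                          ldi_center = 6.5, ldi_scale = 1.2,
                          ldi_noise_sd = 0.4, ldi_cutoff = 4.9,
                          alpha_dem = -3.5, lambda = 1.5,
                          beta_age = 0.05, beta_female = 0.25,
                          beta_educ3 = 0,
                          p_black = 0,
                          missing_rates = c(zygosity = 0, isced9 = 0,
                                            ldi = 0, dementia = 0, age = 0),
                          onset_min_age = 65,
                          age_is_onset_for_cases = TRUE,
                          seed = 1L) {
  need <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  if (!all(need %in% names(n_pairs_by_type)))
    stop("n_pairs_by_type must be named with ", paste(need, collapse = ", "))
  n_pairs_by_type <- n_pairs_by_type[need]
  if (any(n_pairs_by_type < 0) || n_singletons < 0)
    stop("pair and singleton counts must be non-negative")
  if (length(isced_thresholds) != 8L ||
      any(diff(isced_thresholds) <= 0))
    stop("isced_thresholds must be 8 strictly increasing cutpoints")
  mr <- c(zygosity = 0, isced9 = 0, ldi = 0, dementia = 0, age = 0)
  mr[names(missing_rates)] <- missing_rates
  if (any(mr < 0 | mr > 1) || p_black < 0 || p_black > 1)
    stop("probabilities must lie in [0, 1]")
  stopifnot(is.data.frame(studies),
            all(c("study", "prop", "age_mean", "age_sd", "age_min",
                  "age_max", "ascertainment", "assess_year") %in%
                  names(studies)),
            all(studies$ascertainment %in% c("clinical", "registry", "ldi")))
  structure(list(n_pairs_by_type = n_pairs_by_type,
                 n_singletons = n_singletons, studies = studies,
                 isced_thresholds = isced_thresholds,
                 ldi_center = ldi_center, ldi_scale = ldi_scale,
                 ldi_noise_sd = ldi_noise_sd, ldi_cutoff = ldi_cutoff,
                 alpha_dem = alpha_dem, lambda = lambda,
                 beta_age = beta_age, beta_female = beta_female,
                 beta_educ3 = beta_educ3, p_black = p_black,
                 missing_rates = mr, onset_min_age = onset_min_age,
                 age_is_onset_for_cases = age_is_onset_for_cases,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_studies <- function() {
  data.frame(study = "SIM1", prop = 1,
             age_mean = 72, age_sd = 9, age_min = 50, age_max = 105,
             ascertainment = "clinical", assess_year = 2005,
             stringsAsFactors = FALSE)
}

# Cutpoints chosen once so the ISCED 0-8 marginal has mean ~2.9 (an
# older-cohort educational distribution, heavier at the low end).
#' @rdname cohort_config
#' @export
default_isced_thresholds <- function() {
  probs <- c(0.10, 0.20, 0.22, 0.18, 0.10, 0.07, 0.06, 0.04, 0.03)
  stats::qnorm(cumsum(probs)[1:8])
}

#' Multi-study pair counts shaped like a large twin consortium
#'
#' Returns a config whose pair-type counts and study mix mirror the relative
#' structure of a multi-national twin consortium (five pair types across
#' several strata, a small number of singletons, mixed clinical / registry /
#' LDI ascertainment), scaled by \code{scale}.
#'
#' @param scale Fraction of the full-consortium counts (default 0.01).
#' @param seed Integer seed.
#' @param ... Passed on to [cohort_config()].
#' @return A \code{"cohort_config"}.
#' @export
config_consortium <- function(scale = 0.01, seed = 1L, ...) {
  counts <- round(c(MZF = 4123, MZM = 5317, DZF = 5973,
                    DZM = 6503, DZOS = 7953) * scale)
  studies <- data.frame(
    study = c("REGISTRY_A", "CLINIC_B", "LDI_C"),
    prop = c(0.72, 0.10, 0.18),
    age_mean = c(73.6, 74.7, 66), age_sd = c(9.8, 5.7, 10),
    age_min = c(50, 60, 45), age_max = c(105, 100, 95),
    ascertainment = c("registry", "clinical", "ldi"),
    assess_year = c(2000, 2006, 2000), stringsAsFactors = FALSE)
  cohort_config(n_pairs_by_type = counts,
                n_singletons = round(289 * scale),
                studies = studies, seed = seed, ...)
}

#' Draw per-pair bivariate ACE liability components
#'
#' Simulates education and dementia liabilities for \code{n} twin pairs under
#' the sharing rules: the A component correlates 1 within MZ and 0.5 within
#' DZ pairs, C is identical within a pair, E is independent across twins, and
#' the A/C/E components of the two traits correlate \code{rA}/\code{rC}/
#' \code{rE}. When \code{beta_causal} is nonzero the dementia liability gains
#' \code{beta_causal} times the education liability (not restandardized).
#'
#' Uses R's global RNG stream; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param ace An [ace_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param n Number of pairs.
#' @return Data frame with columns \code{edu_liab_1}, \code{edu_liab_2},
#'   \code{dem_liab_1}, \code{dem_liab_2}.
#' @export
draw_pair_components <- function(ace, zygosity = c("MZ", "DZ"), n = 1L) {
  zygosity <- match.arg(zygosity)
  validate_ace_params(ace)
  rbar <- if (zygosity == "MZ") 1 else 0.5
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")

  # bivariate standard-normal draws with cross-trait correlation r
  rbiv <- function(n, r) {
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    cbind(z1, z2)
  }
  A_sh <- rbiv(n, ace$rA); A_u1 <- rbiv(n, ace$rA); A_u2 <- rbiv(n, ace$rA)
  A1 <- sqrt(rbar) * A_sh + sqrt(1 - rbar) * A_u1
  A2 <- sqrt(rbar) * A_sh + sqrt(1 - rbar) * A_u2
  C  <- rbiv(n, ace$rC)
  E1 <- rbiv(n, ace$rE); E2 <- rbiv(n, ace$rE)

  aE <- sqrt(ace$a2_edu); cE <- sqrt(ace$c2_edu); eE <- sqrt(ace$e2_edu)
  aD <- sqrt(ace$a2_dem); cD <- sqrt(ace$c2_dem); eD <- sqrt(ace$e2_dem)

  edu1 <- aE * A1[, 1] + cE * C[, 1] + eE * E1[, 1]
  edu2 <- aE * A2[, 1] + cE * C[, 1] + eE * E2[, 1]
  dem1 <- aD * A1[, 2] + cD * C[, 2] + eD * E1[, 2] + ace$beta_causal * edu1
  dem2 <- aD * A2[, 2] + cD * C[, 2] + eD * E2[, 2] + ace$beta_causal * edu2

  data.frame(edu_liab_1 = edu1, edu_liab_2 = edu2,
             dem_liab_1 = dem1, dem_liab_2 = dem2)
}

#' Map liabilities to observed phenotypes
#'
#' Discretizes the education liability into ISCED 0-8 by counting thresholds
#' below it, produces the noisy LDI score as an affine transform of the
#' negated dementia liability (lower LDI = greater dementia likelihood), and
#' generates the dementia indicator: a Bernoulli draw on the logistic risk
#' model for clinical/registry ascertainment, or a deterministic LDI-cutoff
#' call for LDI ascertainment.
#'
#' Uses R's global RNG stream.
#'
#' @param edu_liab,dem_liab Numeric liability vectors (one entry per person).
#' @param cfg A [cohort_config()].
#' @param age Assessment age in years.
#' @param female 0/1 indicator.
#' @param ascertainment Character vector per person: \code{"clinical"},
#'   \code{"registry"} or \code{"ldi"}.
#' @return Data frame with columns \code{isced9}, \code{ldi}, \code{dementia}.
#' @export
liabilities_to_phenotypes <- function(edu_liab, dem_liab, cfg, age, female,
                                      ascertainment) {
  if (any(diff(cfg$isced_thresholds) <= 0))
    stop("isced_thresholds must be strictly increasing")
  n <- length(edu_liab)
  isced9 <- findInterval(edu_liab, cfg$isced_thresholds)
  ldi <- cfg$ldi_center + cfg$ldi_scale * (-dem_liab) +
    stats::rnorm(n, 0, cfg$ldi_noise_sd)
  educ3 <- collapse_isced(isced9)
  eta <- cfg$alpha_dem + cfg$lambda * dem_liab +
    cfg$beta_educ3 * educ3 +
    cfg$beta_age * (age - 60) + cfg$beta_female * female
  dementia <- stats::rbinom(n, 1L, stats::plogis(eta))
  is_ldi <- ascertainment == "ldi"
  dementia[is_ldi] <- as.integer(ldi[is_ldi] <= cfg$ldi_cutoff)
  data.frame(isced9 = isced9, ldi = ldi, dementia = dementia)
}

#' Simulate a twin cohort with known ground truth
#'
#' Generates a per-individual cohort table under a bivariate ACE liability
#' model: pairs of the five zygosity-by-sex types plus singletons, assigned
#' to study strata, with ISCED education, LDI scores, dementia status, onset
#' ages and optional missingness. Registry-stratum cases carry a
#' registry-recorded age inflated by the known reporting delay, which the
#' harmonization step removes.
#'
#' @param cfg A [cohort_config()].
#' @param ace An [ace_params()] object.
#' @param keep_truth Keep the latent liability columns \code{true_edu_liab},
#'   \code{true_dem_liab}.
#' @return A data frame (the cohort table) with one row per individual:
#'   \code{pair_id}, \code{member}, \code{zygosity}, \code{same_sex},
#'   \code{female}, \code{black}, \code{study}, \code{age},
#'   \code{birth_year}, \code{isced9}, \code{ldi}, \code{dementia},
#'   \code{onset_age}, \code{ascertainment}, and the truth columns.
#' @export
simulate_cohort <- function(cfg, ace, keep_truth = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(ace, "ace_params"))
  n_total_pairs <- sum(cfg$n_pairs_by_type) + cfg$n_singletons
  if (n_total_pairs == 0L) stop("empty cohort: zero pairs requested")
  set.seed(cfg$seed)

  types <- c("MZF", "MZM", "DZF", "DZM", "DZOS")
  # singletons are generated as pairs of a sampled type; member 2 dropped
  w <- cfg$n_pairs_by_type
  if (all(w == 0)) w <- rep(1, 5)
  singleton_types <- if (cfg$n_singletons > 0)
    sample(types, cfg$n_singletons, replace = TRUE, prob = w) else character()
  type_of_pair <- c(rep(types, times = cfg$n_pairs_by_type), singleton_types)
  n_pairs <- length(type_of_pair)
  is_singleton <- seq_len(n_pairs) > sum(cfg$n_pairs_by_type)
  zyg <- ifelse(substr(type_of_pair, 1, 2) == "MZ", "MZ", "DZ")

  liab <- data.frame(edu_liab_1 = numeric(n_pairs),
                     edu_liab_2 = numeric(n_pairs),
                     dem_liab_1 = numeric(n_pairs),
                     dem_liab_2 = numeric(n_pairs))
  for (z in c("MZ", "DZ")) {
    idx <- which(zyg == z)
    if (length(idx)) liab[idx, ] <- draw_pair_components(ace, z, length(idx))
  }

  # pair-level assignments
  st <- cfg$studies
  study_idx <- sample.int(nrow(st), n_pairs, replace = TRUE, prob = st$prop)
  # truncated-normal ages via inverse-CDF so twins share one age
  plo <- stats::pnorm(st$age_min[study_idx], st$age_mean[study_idx],
                      st$age_sd[study_idx])
  phi <- stats::pnorm(st$age_max[study_idx], st$age_mean[study_idx],
                      st$age_sd[study_idx])
  age_pair <- stats::qnorm(stats::runif(n_pairs, plo, phi),
                           st$age_mean[study_idx], st$age_sd[study_idx])
  birth_year <- st$assess_year[study_idx] - round(age_pair)
  black <- stats::rbinom(n_pairs, 1L, cfg$p_black)
  # DZOS: randomize which member is female
  os_first_female <- stats::rbinom(n_pairs, 1L, 0.5)
  fem1 <- ifelse(type_of_pair %in% c("MZF", "DZF"), 1L,
          ifelse(type_of_pair == "DZOS", os_first_female, 0L))
  fem2 <- ifelse(type_of_pair %in% c("MZF", "DZF"), 1L,
          ifelse(type_of_pair == "DZOS", 1L - os_first_female, 0L))

  long <- data.frame(
    pair_id = rep(sprintf("P%06d", seq_len(n_pairs)), each = 2L),
    member = rep(1:2, n_pairs),
    zygosity = rep(zyg, each = 2L),
    same_sex = rep(as.integer(type_of_pair != "DZOS"), each = 2L),
    female = as.integer(rbind(fem1, fem2)),
    black = rep(black, each = 2L),
    study = rep(st$study[study_idx], each = 2L),
    age = rep(age_pair, each = 2L),
    birth_year = rep(birth_year, each = 2L),
    ascertainment = rep(st$ascertainment[study_idx], each = 2L),
    true_edu_liab = as.numeric(rbind(liab$edu_liab_1, liab$edu_liab_2)),
    true_dem_liab = as.numeric(rbind(liab$dem_liab_1, liab$dem_liab_2)),
    stringsAsFactors = FALSE)

  ph <- liabilities_to_phenotypes(long$true_edu_liab, long$true_dem_liab,
                                  cfg, long$age, long$female,
                                  long$ascertainment)
  long <- cbind(long, ph)

  # onset age for cases: uniform between floor and assessment age
  long$onset_age <- NA_real_
  case <- long$dementia == 1L
  lo <- pmin(cfg$onset_min_age, long$age[case])
  long$onset_age[case] <- stats::runif(sum(case), lo, long$age[case])

  # registry strata: cases get a registry source and a recorded age inflated
  # by the known reporting delay (harmonization subtracts it back out)
  reg_case <- case & long$ascertainment == "registry" &
    cfg$age_is_onset_for_cases
  if (any(reg_case)) {
    src <- sample(c("registry_NPR", "registry_OPR", "registry_PDR",
                    "registry_CDR"), sum(reg_case), replace = TRUE,
                  prob = c(0.6, 0.2, 0.1, 0.1))
    long$ascertainment[reg_case] <- src
    delay <- ifelse(src == "registry_CDR", 7, 5)
    long$onset_age[reg_case] <- long$onset_age[reg_case] + delay
    long$age[reg_case] <- long$onset_age[reg_case]
  }
  long$ascertainment[long$ascertainment == "registry"] <- "registry_NPR"
  # non-registry cases: recorded age is the onset age
  if (cfg$age_is_onset_for_cases) {
    plain_case <- case & !reg_case
    long$age[plain_case] <- long$onset_age[plain_case]
  }

  # drop member 2 of singleton "pairs"
  keep <- !(rep(is_singleton, each = 2L) & long$member == 2L)
  long <- long[keep, , drop = FALSE]

  # per-field missingness
  mr <- cfg$missing_rates
  blank <- function(x, rate) {
    if (rate > 0) x[stats::runif(length(x)) < rate] <- NA
    x
  }
  long$zygosity <- blank(long$zygosity, mr[["zygosity"]])
  long$isced9 <- blank(long$isced9, mr[["isced9"]])
  long$ldi <- blank(long$ldi, mr[["ldi"]])
  long$dementia <- blank(long$dementia, mr[["dementia"]])
  long$age <- blank(long$age, mr[["age"]])

  if (!keep_truth)
    long <- long[, setdiff(names(long), c("true_edu_liab", "true_dem_liab"))]
  rownames(long) <- NULL
  long
}

#' Named simulation scenarios with known truth
#'
#' Bundles an [ace_params()] and a [cohort_config()] for the study designs
#' the package's checks rely on:
#' \describe{
#'   \item{null}{No education-dementia link at all: all cross-trait
#'     correlations and causal paths zero. Used for type-I-error
#'     calibration.}
#'   \item{recovery}{A known direct log-odds effect of education
#'     (\code{beta_educ3 = -0.5}) with the dementia liability fully
#'     pair-shared (\eqn{c^2 = 1}), so the generative model is exactly a
#'     logistic random-intercept model and the between/within coefficients
#'     have a known truth of -0.5.}
#'   \item{quasi_causal}{A protective causal path on the liability scale
#'     (\code{beta_causal = -0.6}) with no confounding: within-pair effects
#'     present in MZ and DZ alike.}
#'   \item{genetic_confounding}{A strong protective additive-genetic
#'     correlation (\code{rA = -0.8}) and no causal path: the within-MZ
#'     effect is null while the within-DZ effect is not.}
#'   \item{shared_env_confounding}{A protective shared-environmental
#'     correlation (\code{rC = -0.8}) and no causal path: within effects
#'     null in both zygosity groups, between effect present.}
#' }
#'
#' @param name Scenario name.
#' @param n_pairs Total pairs, split equally across the five pair types.
#' @param seed Integer seed.
#' @param ... Additional overrides passed to [cohort_config()].
#' @return List with elements \code{ace} and \code{cfg}.
#' @export
scenario_config <- function(name = c("null", "recovery", "quasi_causal",
                                     "genetic_confounding",
                                     "shared_env_confounding"),
                            n_pairs = 5000, seed = 1L, ...) {
  name <- match.arg(name)
  per <- floor(n_pairs / 5)
  counts <- c(MZF = per, MZM = per, DZF = per, DZM = per,
              DZOS = n_pairs - 4 * per)
  ace <- switch(name,
    null = ace_params(),
    recovery = ace_params(a2_dem = 0, c2_dem = 1, e2_dem = 0),
    quasi_causal = ace_params(beta_causal = -0.6),
    genetic_confounding = ace_params(rA = -0.8),
    shared_env_confounding = ace_params(a2_edu = 0.30, c2_edu = 0.35,
                                        e2_edu = 0.35, a2_dem = 0.30,
                                        c2_dem = 0.35, e2_dem = 0.35,
                                        rC = -0.8))
  extra <- switch(name,
    recovery = list(beta_educ3 = -0.5, lambda = 1.2, alpha_dem = -2.6,
                    beta_female = 0, age_is_onset_for_cases = FALSE),
    list())
  args <- c(list(n_pairs_by_type = counts, seed = seed), extra, list(...))
  # later overrides win
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  cfg <- do.call(cohort_config, args)
  list(ace = ace, cfg = cfg)
}

#' Write / read the cohort CSV dialect
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}
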