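#' Classify the familial-confounding pattern of the education effect
#'
#' Encodes the inferential decision rules of the co-twin control design.
#' Writing \eqn{\pi_1} for the between-pair education effect, \eqn{\pi_2}
#' for the within-pair education effect (the MZ within effect once the
#' zygosity interaction is in the model), and \eqn{\pi_4} for the
#' within-education-by-zygosity interaction:
#' \itemize{
#'   \item neither \eqn{\pi_1} nor \eqn{\pi_2} significant:
#'     \code{no_association};
#'   \item \eqn{\pi_2} significant with a protective (negative) sign:
#'     \code{quasi_causal} -- the within-family effect survives control for
#'     everything twins share;
#'   \item \eqn{\pi_2} null, \eqn{\pi_1} significant and \eqn{\pi_4}
#'     significant: \code{genetic_confounding} -- the within-family effect
#'     is larger in DZ than in MZ twins, the signature of additive-genetic
#'     confounds;
#'   \item \eqn{\pi_2} null, \eqn{\pi_1} significant, \eqn{\pi_4} null:
#'     \code{shared_env_confounding};
#'   \item \eqn{\pi_1} significant but the zygosity interaction untestable
#'     (no Model 3 supplied): \code{familial_unspecified}.
#' }
#'
#' @param model2_fit [fit_bw_glmm()] result for Model 2 (between/within).
#' @param model3_fit Optional Model 3 result (zygosity interaction); when
#'   NULL the genetic vs shared-environment distinction is not attempted.
#' @param alpha Significance level (default 0.05).
#' @param protective_sign Sign of a protective education effect (default
#'   -1: higher education lowers dementia log-odds).
#' @return Object of class \code{"confounding_verdict"}: \code{verdict},
#'   \code{evidence} (the estimates and p-values used), \code{alpha}.
#' @export
classify_confounding <- function(model2_fit, model3_fit = NULL,
                                 alpha = 0.05, protective_sign = -1) {
  if (!model2_fit$converged)
    stop("classification refused: Model 2 fit did not converge")
  if (!is.null(model3_fit) && !model3_fit$converged)
    stop("classification refused: Model 3 fit did not converge")
  coef_row <- function(fit, term) {
    tab <- fit$coefficients
    row <- tab[tab$term == term, , drop = FALSE]
    if (nrow(row) != 1L) stop("term not found in fit: ", term)
    row
  }
  p1 <- coef_row(model2_fit, "educ_between")
  p2_m2 <- coef_row(model2_fit, "educ_within")
  ev <- list(pi1 = c(estimate = p1$estimate, p = p1$p),
             pi2_model2 = c(estimate = p2_m2$estimate, p = p2_m2$p))
  have3 <- !is.null(model3_fit)
  if (have3) {
    p2 <- coef_row(model3_fit, "educ_within")
    p4 <- coef_row(model3_fit, "educ_within:zyg")
    ev$pi2 <- c(estimate = p2$estimate, p = p2$p)
    ev$pi4 <- c(estimate = p4$estimate, p = p4$p)
  } else {
    p2 <- p2_m2
  }
  sig <- function(row) !is.na(row$p) && row$p < alpha
  protective <- function(row) sign(row$estimate) == protective_sign

  verdict <-
    if (!sig(p1) && !sig(p2_m2)) "no_association"
    else if (sig(p2) && protective(p2)) "quasi_causal"
    else if (sig(p1) && have3 && sig(p4)) "genetic_confounding"
    else if (sig(p1) && have3 && !sig(p4)) "shared_env_confounding"
    else "familial_unspecified"

  structure(list(verdict = verdict, evidence = ev, alpha = alpha),
            class = "confounding_verdict")
}

#' @export
print.confounding_verdict <- function(x, ...) {
  cat("Confounding classification:", x$verdict, "\n")
  for (nm in names(x$evidence))
    cat(sprintf("  %-10s estimate %8.4f   p %.4g\n", nm,
                x$evidence[[nm]]["estimate"], x$evidence[[nm]]["p"]))
  cat("  alpha =", x$alpha, "\n")
  invisible(x)
}

#' Identify dementia-discordant pairs with a surviving co-twin control
#'
#' Returns all twin pairs where exactly one member developed dementia and
#' the unaffected co-twin was last seen (or died) after the affected twin's
#' onset age and never developed dementia. For each pair the education
#' comparison on the 9-category ISCED scale is recorded
#' (\code{affected_higher} / \code{control_higher} / \code{equal}).
#'
#' @param cohort A harmonized cohort data frame (needs \code{dementia},
#'   \code{onset_age}, \code{age}, \code{isced9}, \code{zygosity}).
#' @return Data frame with one row per qualifying pair: \code{pair_id},
#'   \code{zygosity}, \code{study}, \code{onset_affected},
#'   \code{control_last_seen}, \code{educ_comparison}.
#' @export
find_discordant_pairs <- function(cohort) {
  ok <- !is.na(cohort$dementia) & !is.na(cohort$isced9) &
    !is.na(cohort$zygosity) & !is.na(cohort$age)
  x <- cohort[ok, , drop = FALSE]
  counts <- table(x$pair_id)
  x <- x[x$pair_id %in% names(counts)[counts == 2L], , drop = FALSE]
  x <- x[order(x$pair_id, x$member), , drop = FALSE]
  m1 <- x[x$member == 1L, ]
  m2 <- x[x$member == 2L, ]
  disc <- m1$dementia + m2$dementia == 1L
  m1 <- m1[disc, ]; m2 <- m2[disc, ]
  aff_is_1 <- m1$dementia == 1L
  pick <- function(a, b, take_a) ifelse(take_a, a, b)
  onset <- pick(m1$onset_age, m2$onset_age, aff_is_1)
  ctrl_seen <- pick(m2$age, m1$age, aff_is_1)
  isced_aff <- pick(m1$isced9, m2$isced9, aff_is_1)
  isced_ctl <- pick(m2$isced9, m1$isced9, aff_is_1)
  survived <- !is.na(onset) & ctrl_seen > onset
  out <- data.frame(
    pair_id = m1$pair_id, zygosity = m1$zygosity, study = m1$study,
    onset_affected = onset, control_last_seen = ctrl_seen,
    educ_comparison = ifelse(isced_aff > isced_ctl, "affected_higher",
                      ifelse(isced_aff < isced_ctl, "control_higher",
                             "equal")),
    stringsAsFactors = FALSE)[survived, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact two-sided sign test on discordant-pair education frequencies
#'
#' Compares the number of dementia-discordant pairs where the affected twin
#' had the higher education against the number where the control did, by an
#' exact binomial test of p = 0.5. The two-sided p-value doubles the
#' smaller tail (including the observed count) and is capped at 1.
#' Equal-education pairs are excluded by the caller.
#'
#' @param n_affected_higher,n_control_higher Non-negative counts.
#' @return List: \code{n}, \code{n_affected_higher},
#'   \code{n_control_higher}, \code{p_two_sided}.
#' @export
sign_test <- function(n_affected_higher, n_control_higher) {
  stopifnot(n_affected_higher >= 0, n_control_higher >= 0)
  n <- n_affected_higher + n_control_higher
  if (n == 0) stop("insufficient data: no unequal-education discordant pairs")
  k <- n_affected_higher
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(n = n, n_affected_higher = n_affected_higher,
       n_control_higher = n_control_higher,
       p_two_sided = min(1, 2 * min(lower, upper)))
}

#' Discordant-pair analysis with delayed-onset augmentation
#'
#' Repeats the discordant-pair identification after adding pairs where both
#' twins developed dementia but the second onset came at least
#' \code{min_gap} years after the first; the later-onset twin is treated as
#' the control. This probes whether education delays onset rather than
#' preventing dementia.
#'
#' @param cohort A harmonized cohort data frame.
#' @param min_gap Minimum onset gap in years (default 5).
#' @return List: \code{pairs} (the augmented discordant-pair table, with a
#'   \code{delayed_onset} flag) and \code{test} (the [sign_test()] on
#'   unequal-education pairs).
#' @export
delayed_onset_variant <- function(cohort, min_gap = 5) {
  stopifnot(min_gap > 0)
  base <- find_discordant_pairs(cohort)
  if (nrow(base)) base$delayed_onset <- FALSE

  ok <- !is.na(cohort$dementia) & !is.na(cohort$isced9) &
    !is.na(cohort$zygosity) & !is.na(cohort$onset_age)
  x <- cohort[ok & cohort$dementia == 1L, , drop = FALSE]
  counts <- table(x$pair_id)
  x <- x[x$pair_id %in% names(counts)[counts == 2L], , drop = FALSE]
  x <- x[order(x$pair_id, x$member), , drop = FALSE]
  if (nrow(x)) {
    m1 <- x[x$member == 1L, ]
    m2 <- x[x$member == 2L, ]
    gap_ok <- abs(m1$onset_age - m2$onset_age) >= min_gap
    m1 <- m1[gap_ok, ]; m2 <- m2[gap_ok, ]
    aff_is_1 <- m1$onset_age < m2$onset_age  # earlier onset = affected
    pick <- function(a, b, take_a) ifelse(take_a, a, b)
    if (nrow(m1)) {
      isced_aff <- pick(m1$isced9, m2$isced9, aff_is_1)
      isced_ctl <- pick(m2$isced9, m1$isced9, aff_is_1)
      extra <- data.frame(
        pair_id = m1$pair_id, zygosity = m1$zygosity, study = m1$study,
        onset_affected = pick(m1$onset_age, m2$onset_age, aff_is_1),
        control_last_seen = pick(m2$onset_age, m1$onset_age, aff_is_1),
        educ_comparison = ifelse(isced_aff > isced_ctl, "affected_higher",
                          ifelse(isced_aff < isced_ctl, "control_higher",
                                 "equal")),
        delayed_onset = TRUE, stringsAsFactors = FALSE)
      base <- rbind(base, extra)
    }
  }
  tab <- table(factor(base$educ_comparison,
                      levels = c("affected_higher", "control_higher",
                                 "equal")))
  test <- if (sum(tab[1:2]) > 0)
    sign_test(tab[["affected_higher"]], tab[["control_higher"]])
  else NULL
  list(pairs = base, test = test)
}

#' Discordant-pair frequency table by study and zygosity
#'
#' Tabulates dementia-discordant pairs (control surviving past onset) by
#' study and zygosity with the education comparison counts and the exact
#' sign-test p-value where both unequal-education counts exist.
#'
#' @param cohort A harmonized cohort data frame.
#' @return Data frame with columns \code{study}, \code{zygosity},
#'   \code{n_pairs}, \code{affected_higher}, \code{control_higher},
#'   \code{equal}, \code{p_sign_test}.
#' @export
discordant_frequency_table <- function(cohort) {
  d <- find_discordant_pairs(cohort)
  if (!nrow(d))
    return(data.frame(study = character(), zygosity = character(),
                      n_pairs = integer(), affected_higher = integer(),
                      control_higher = integer(), equal = integer(),
                      p_sign_test = numeric(), stringsAsFactors = FALSE))
  grp <- split(d, list(d$study, d$zygosity), drop = TRUE)
  rows <- lapply(grp, function(g) {
    tab <- table(factor(g$educ_comparison,
                        levels = c("affected_higher", "control_higher",
                                   "equal")))
    p <- if (sum(tab[1:2]) > 0)
      sign_test(tab[["affected_higher"]], tab[["control_higher"]])$p_two_sided
    else NA_real_
    data.frame(study = g$study[1], zygosity = g$zygosity[1],
               n_pairs = nrow(g),
               affected_higher = as.integer(tab[["affected_higher"]]),
               control_higher = as.integer(tab[["control_higher"]]),
               equal = as.integer(tab[["equal"]]),
               p_sign_test = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
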