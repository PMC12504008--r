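#' Collapse ISCED 0-8 into the three-category education score
#'
#' Categories 0-2 (lower secondary or less) map to 1, categories 3-5 (upper
#' secondary through short-cycle tertiary) to 2, and categories 6-8
#' (bachelor's degree or higher) to 3. The collapse avoids overfitting the
#' genetically informative models with a 9-level ordinal exposure.
#'
#' @param isced9 Integer vector of ISCED codes in 0..8 (NA allowed).
#' @return Integer vector in 1..3 (NA preserved).
#' @export
collapse_isced <- function(isced9) {
  ok <- is.na(isced9) | (isced9 %in% 0:8)
  if (!all(ok))
    stop("isced9 values outside 0..8: ",
         paste(unique(isced9[!ok]), collapse = ", "))
  as.integer(isced9 %/% 3L + 1L)
}

registry_sources <- c(registry_NPR = 5, registry_OPR = 5,
                      registry_PDR = 5, registry_CDR = 7)

#' Adjust registry-recorded onset ages for reporting delay
#'
#' Dementia onset ages taken from national registries lag true onset;
#' recorded ages are adjusted by subtracting 5 years for the National
#' Patient, Outpatient and Prescribed Drug Registers and 7 years for the
#' Cause of Death Register. Non-registry sources are returned unchanged.
#'
#' @param age Recorded age in years.
#' @param source Ascertainment label per record: one of
#'   \code{"clinical"}, \code{"ldi"}, \code{"registry_NPR"},
#'   \code{"registry_OPR"}, \code{"registry_PDR"}, \code{"registry_CDR"}.
#' @return Adjusted age vector.
#' @export
adjust_registry_onset_age <- function(age, source) {
  known <- c("clinical", "ldi", names(registry_sources))
  bad <- !is.na(source) & !(source %in% known)
  if (any(bad))
    stop("unknown ascertainment source: ",
         paste(unique(source[bad]), collapse = ", "))
  offset <- ifelse(source %in% names(registry_sources),
                   registry_sources[match(source, names(registry_sources))],
                   0)
  offset[is.na(source)] <- 0
  age - offset
}

#' Cap age at 90 and center at 60
#'
#' Participants above 90 are recoded to 90 (few individuals remain that
#' old); the model covariate is age minus 60.
#'
#' @param age Age in years (> 0).
#' @return List with \code{age_capped} and \code{age_centered}.
#' @export
cap_and_center_age <- function(age) {
  if (any(!is.na(age) & age <= 0)) stop("age must be positive")
  age_capped <- pmin(age, 90)
  list(age_capped = age_capped, age_centered = age_capped - 60)
}

#' Operationalize dementia from clinical diagnosis or LDI cutoff
#'
#' A clinical (or registry) diagnosis, when present, is used as-is.
#' Otherwise the latent dementia index decides: scores at or below the
#' cutoff are impaired (lower LDI indicates greater dementia likelihood).
#' Records missing both sources stay missing.
#'
#' @param clinical_dx 0/1/NA clinical or registry diagnosis.
#' @param ldi LDI score or NA.
#' @param cutoff Dementia threshold on the LDI scale.
#' @return Integer 0/1/NA vector.
#' @export
operationalize_dementia <- function(clinical_dx, ldi, cutoff) {
  use_ldi <- is.na(clinical_dx) & !is.na(ldi)
  if (any(use_ldi) && (length(cutoff) != 1L || !is.finite(cutoff)))
    stop("a finite LDI cutoff is required when LDI scores are used")
  out <- as.integer(clinical_dx)
  out[use_ldi] <- as.integer(ldi[use_ldi] <= cutoff)
  out
}

#' Harmonize a raw cohort table
#'
#' Applies the variable-construction rules to a cohort table: collapses
#' ISCED into the 3-category education score, removes the registry
#' reporting delay from registry-ascertained cases' ages, caps age at 90
#' and centers it at 60, codes zygosity DZ = 1 / MZ = 0, fills dementia
#' status from the LDI cutoff where no diagnosis exists, and flags records
#' unusable for model fitting (missing zygosity, ISCED, dementia status or
#' age) with a reason code. No rows are created or dropped; the flags feed
#' the exclusion accounting.
#'
#' Harmonization is idempotent: the registry age adjustment is recorded in
#' an \code{age_adj_applied} column and never applied twice.
#'
#' @param cohort A cohort data frame (the [simulate_cohort()] dialect).
#' @param ldi_cutoff LDI dementia threshold; required only if some records
#'   lack a dementia status but have LDI scores.
#' @return The cohort with added columns \code{educ3}, \code{zyg_dz},
#'   \code{age_capped}, \code{age_centered}, \code{valid},
#'   \code{exclusion_reason}, \code{age_adj_applied}.
#' @export
harmonize_cohort <- function(cohort, ldi_cutoff = NULL) {
  h <- cohort
  h$educ3 <- collapse_isced(h$isced9)
  h$zyg_dz <- ifelse(is.na(h$zygosity), NA_integer_,
                     as.integer(h$zygosity == "DZ"))

  if (is.null(h$age_adj_applied)) h$age_adj_applied <- 0L
  if (!is.null(h$ascertainment)) {
    adj <- which(h$age_adj_applied == 0L & !is.na(h$dementia) &
                   h$dementia == 1L)
    if (length(adj)) {
      h$age[adj] <- adjust_registry_onset_age(h$age[adj],
                                              h$ascertainment[adj])
      if (!is.null(h$onset_age))
        h$onset_age[adj] <- adjust_registry_onset_age(h$onset_age[adj],
                                                      h$ascertainment[adj])
    }
    h$age_adj_applied <- 1L
  }

  cc <- cap_and_center_age(h$age)
  h$age_capped <- cc$age_capped
  h$age_centered <- cc$age_centered

  if (!is.null(h$ldi) && any(is.na(h$dementia) & !is.na(h$ldi))) {
    if (is.null(ldi_cutoff))
      stop("ldi_cutoff required: some records have LDI but no diagnosis")
    h$dementia <- operationalize_dementia(h$dementia, h$ldi, ldi_cutoff)
  }

  miss <- cbind(zygosity = is.na(h$zyg_dz), ISCED = is.na(h$educ3),
                `dementia status` = is.na(h$dementia), age = is.na(h$age))
  h$valid <- as.integer(rowSums(miss) == 0L)
  reason <- do.call(paste, c(lapply(colnames(miss), function(cn)
    ifelse(miss[, cn], cn, "")), list(sep = "|")))
  reason <- gsub("\\|+", " and ", gsub("^\\|+|\\|+$", "", reason))
  h$exclusion_reason <- ifelse(h$valid == 1L, "", paste("without", reason))
  h
}
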