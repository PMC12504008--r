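#' Bivariate ACE liability parameters
#'
#' Standardized variance components for the education and dementia
#' liabilities, the cross-trait correlations of the A, C and E components,
#' and an optional direct (causal) path from the education liability to the
#' dementia liability.
#'
#' Each trait's liability is decomposed as
#' \eqn{L = a\,A + c\,C + e\,E} with \eqn{a^2 + c^2 + e^2 = 1}, where A is
#' shared completely within monozygotic (MZ) pairs and half-shared (r = 0.5)
#' within dizygotic (DZ) pairs, C is identical within every pair, and E is
#' individual-specific. The A components of the two traits correlate
#' \code{rA} within a person (and \code{rA} times the sharing coefficient
#' across co-twins), and likewise for \code{rC} and \code{rE}. When
#' \code{beta_causal} is nonzero the generated dementia liability is
#' \eqn{L_D + \beta\,L_E}; the result is deliberately not restandardized,
#' so that \code{beta_causal} stays interpretable on the original liability
#' scale (the variance inflation \eqn{\beta^2 + 2\beta\,\mathrm{cov}} is a
#' documented property of the generator, not an error).
#'
#' @param a2_edu,c2_edu,e2_edu Standardized A/C/E variance components of the
#'   education liability; must be non-negative and sum to 1.
#' @param a2_dem,c2_dem,e2_dem Same for the dementia liability.
#' @param rA,rC,rE Cross-trait correlations of the A, C and E components,
#'   each in \[-1, 1\].
#' @param beta_causal Direct effect of the education liability on the
#'   dementia liability (0 = pure confounding).
#' @return An object of class \code{"ace_params"}.
#' @examples
#' ace <- ace_params(a2_edu = 0.5, c2_edu = 0.2, e2_edu = 0.3,
#'                   a2_dem = 0.5, c2_dem = 0.2, e2_dem = 0.3)
#' expected_twin_correlation(ace, "edu", "MZ")  # 0.7
#' @export
ace_params <- function(a2_edu = 0.40, c2_edu = 0.25, e2_edu = 0.35,
                       a2_dem = 0.60, c2_dem = 0.05, e2_dem = 0.35,
                       rA = 0, rC = 0, rE = 0, beta_causal = 0) {
  p <- structure(
    list(a2_edu = a2_edu, c2_edu = c2_edu, e2_edu = e2_edu,
         a2_dem = a2_dem, c2_dem = c2_dem, e2_dem = e2_dem,
         rA = rA, rC = rC, rE = rE, beta_causal = beta_causal),
    class = "ace_params")
  validate_ace_params(p)
  p
}

#' @export
print.ace_params <- function(x, ...) {
  cat("Bivariate ACE liability parameters\n")
  cat(sprintf("  education: a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2_edu, x$c2_edu, x$e2_edu))
  cat(sprintf("  dementia:  a2 = %.3f, c2 = %.3f, e2 = %.3f\n",
              x$a2_dem, x$c2_dem, x$e2_dem))
  cat(sprintf("  cross-trait: rA = %.2f, rC = %.2f, rE = %.2f\n",
              x$rA, x$rC, x$rE))
  cat(sprintf("  causal path (edu liability -> dem liability): %.2f\n",
              x$beta_causal))
  invisible(x)
}

validate_ace_params <- function(p, tol = 1e-12) {
  comps <- unlist(p[c("a2_edu", "c2_edu", "e2_edu",
                      "a2_dem", "c2_dem", "e2_dem")])
  if (any(!is.finite(comps)) || any(comps < 0))
    stop("ACE variance components must be finite and non-negative")
  if (abs(p$a2_edu + p$c2_edu + p$e2_edu - 1) > tol)
    stop("education variance components must sum to 1")
  if (abs(p$a2_dem + p$c2_dem + p$e2_dem - 1) > tol)
    stop("dementia variance components must sum to 1")
  rs <- unlist(p[c("rA", "rC", "rE")])
  if (any(!is.finite(rs)) || any(abs(rs) > 1))
    stop("cross-trait correlations must lie in [-1, 1]")
  if (!is.finite(p$beta_causal))
    stop("beta_causal must be finite")
  for (zyg in c("MZ", "DZ")) {
    S <- pair_covariance(p, zyg)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("rejected configuration: implied per-pair covariance for ", zyg,
           " pairs is not positive semi-definite")
  }
  invisible(TRUE)
}

#' Implied per-pair cross-trait covariance matrix
#'
#' The 4x4 covariance of \code{(edu_1, dem_1, edu_2, dem_2)} liabilities
#' (before the causal path is added) implied by a parameter set, for a given
#' zygosity. Used for validation and as a closed-form oracle for the
#' simulator.
#'
#' @param ace An [ace_params()] object (validated by the caller).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A 4x4 symmetric matrix with unit diagonal.
#' @export
pair_covariance <- function(ace, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  rbar <- if (zygosity == "MZ") 1 else 0.5
  aE <- sqrt(ace$a2_edu); cE <- sqrt(ace$c2_edu); eE <- sqrt(ace$e2_edu)
  aD <- sqrt(ace$a2_dem); cD <- sqrt(ace$c2_dem); eD <- sqrt(ace$e2_dem)
  # within-person cross-trait covariance and across-twin blocks
  cov_within  <- aE * aD * ace$rA + cE * cD * ace$rC + eE * eD * ace$rE
  cov_cross   <- rbar * aE * aD * ace$rA + cE * cD * ace$rC
  r_edu <- rbar * ace$a2_edu + ace$c2_edu
  r_dem <- rbar * ace$a2_dem + ace$c2_dem
  S <- matrix(c(
    1,          cov_within, r_edu,      cov_cross,
    cov_within, 1,          cov_cross,  r_dem,
    r_edu,      cov_cross,  1,          cov_within,
    cov_cross,  r_dem,      cov_within, 1), 4, 4, byrow = TRUE)
  dimnames(S) <- rep(list(c("edu_1", "dem_1", "edu_2", "dem_2")), 2)
  S
}

#' Closed-form within-pair twin correlation
#'
#' The expected within-pair correlation of a trait's liability under the
#' ACE sharing rules: \eqn{a^2 + c^2} for MZ pairs and
#' \eqn{0.5\,a^2 + c^2} for DZ pairs. Serves as the analytic oracle the
#' simulator is tested against.
#'
#' @param ace An [ace_params()] object.
#' @param trait `"edu"` or `"dem"`.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return The expected correlation (scalar).
#' @export
expected_twin_correlation <- function(ace, trait = c("edu", "dem"),
                                      zygosity = c("MZ", "DZ")) {
  trait <- match.arg(trait)
  zygosity <- match.arg(zygosity)
  a2 <- if (trait == "edu") ace$a2_edu else ace$a2_dem
  c2 <- if (trait == "edu") ace$c2_edu else ace$c2_dem
  rbar <- if (zygosity == "MZ") 1 else 0.5
  rbar * a2 + c2
}
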