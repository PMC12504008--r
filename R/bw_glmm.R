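#' Between/within decomposition of the education exposure
#'
#' Splits each individual's 3-category education score into the pair mean
#' (the between-family exposure) and the deviation from the pair mean (the
#' within-family exposure). For singletons, and for members whose co-twin's
#' education is unknown, the pair mean is the individual's own value and the
#' within deviation is 0. Within deviations sum to exactly zero inside every
#' complete pair.
#'
#' @param cohort A harmonized cohort data frame (needs \code{pair_id},
#'   \code{educ3}).
#' @return The cohort with columns \code{educ_between}, \code{educ_within}.
#' @export
decompose_exposure <- function(cohort) {
  if (is.null(cohort$educ3)) stop("cohort must be harmonized first (educ3)")
  pm <- tapply(cohort$educ3, cohort$pair_id, mean, na.rm = TRUE)
  pm[!is.finite(pm)] <- NA
  cohort$educ_between <- as.numeric(pm[match(cohort$pair_id, names(pm))])
  cohort$educ_within <- cohort$educ3 - cohort$educ_between
  cohort
}

model_flags <- function(model_id) {
  if (!model_id %in% 1:5) stop("unknown model_id: ", model_id)
  list(between_within = model_id >= 2,
       zyg_interaction = model_id >= 3,
       female_main = model_id >= 4,
       female_interactions = model_id >= 5)
}

#' Build the between-within model design
#'
#' Assembles the outcome, fixed-effect design matrix and pair/cluster
#' structure for one of the five models of the fitting ladder:
#' \describe{
#'   \item{Model 1}{raw 3-category education only (the total phenotypic
#'     effect, conceptually the sum of the between and within parameters).}
#'   \item{Model 2}{the between-pair mean and within-pair deviation of
#'     education.}
#'   \item{Model 3}{adds the zygosity main effect (DZ = 1) and the
#'     within-education-by-zygosity interaction.}
#'   \item{Model 4}{adds the female main effect.}
#'   \item{Model 5}{adds all female interactions (female x within-education,
#'     female x zygosity, female x zygosity x within-education).}
#' }
#' Age (centered at 60), study indicators and study-by-female indicators
#' (when more than one study is present) are included in every model.
#' Education enters as a numeric 1-3 score by default; \code{educ_coding =
#' "dummy"} expands it to indicator columns before decomposition.
#'
#' Records flagged invalid by harmonization, or missing the outcome or
#' exposure, are excluded from the design.
#'
#' @param cohort A harmonized cohort data frame.
#' @param model_id Integer 1-5.
#' @param educ_coding \code{"numeric"} (default) or \code{"dummy"}.
#' @param center_between Center the between-pair education at its grand
#'   mean (default FALSE; affects only the intercept).
#' @param extra_covariates Optional character vector of additional numeric
#'   columns to include as covariates.
#' @return Object of class \code{"bw_design"}: \code{y}, \code{X},
#'   \code{pair_start}, \code{pair_len}, \code{pair_dz} (one entry per
#'   pair), \code{model_id}, \code{n_obs}, \code{n_pairs}.
#' @export
build_design <- function(cohort, model_id = 2,
                         educ_coding = c("numeric", "dummy"),
                         center_between = FALSE,
                         extra_covariates = NULL) {
  educ_coding <- match.arg(educ_coding)
  flags <- model_flags(model_id)
  if (is.null(cohort$valid)) cohort$valid <- 1L
  keep <- cohort$valid == 1L & !is.na(cohort$dementia)
  if (!is.null(extra_covariates))
    for (cv in extra_covariates) keep <- keep & !is.na(cohort[[cv]])
  x <- cohort[keep, , drop = FALSE]
  x <- x[order(x$pair_id, x$member), , drop = FALSE]
  x <- decompose_exposure(x)

  educ_cols <- function(v, suffix = "") {
    if (educ_coding == "numeric") {
      m <- matrix(v, ncol = 1)
      colnames(m) <- paste0("educ", suffix)
    } else {
      m <- cbind(as.integer(v == 2), as.integer(v == 3))
      colnames(m) <- paste0("educ", c("2", "3"), suffix)
    }
    m
  }

  X <- matrix(1, nrow(x), 1, dimnames = list(NULL, "intercept"))
  if (!flags$between_within) {
    X <- cbind(X, educ_cols(x$educ3))
  } else {
    if (educ_coding == "numeric") {
      eb <- x$educ_between
      if (center_between) eb <- eb - mean(eb)
      B <- matrix(eb, ncol = 1, dimnames = list(NULL, "educ_between"))
      W <- matrix(x$educ_within, ncol = 1,
                  dimnames = list(NULL, "educ_within"))
    } else {
      d <- cbind(as.integer(x$educ3 == 2), as.integer(x$educ3 == 3))
      pb <- apply(d, 2, function(col)
        as.numeric(tapply(col, x$pair_id, mean)[
          match(x$pair_id, names(tapply(col, x$pair_id, mean)))]))
      B <- pb; colnames(B) <- c("educ2_between", "educ3_between")
      W <- d - pb; colnames(W) <- c("educ2_within", "educ3_within")
    }
    X <- cbind(X, B, W)
    if (flags$zyg_interaction) {
      Z <- matrix(x$zyg_dz, ncol = 1, dimnames = list(NULL, "zyg"))
      WZ <- W * x$zyg_dz
      colnames(WZ) <- paste0(colnames(W), ":zyg")
      X <- cbind(X, Z, WZ)
    }
    if (flags$female_main)
      X <- cbind(X, female = x$female)
    if (flags$female_interactions) {
      FW <- W * x$female
      colnames(FW) <- paste0("female:", colnames(W))
      FZ <- matrix(x$female * x$zyg_dz, ncol = 1,
                   dimnames = list(NULL, "female:zyg"))
      FWZ <- W * x$female * x$zyg_dz
      colnames(FWZ) <- paste0("female:zyg:", colnames(W))
      X <- cbind(X, FW, FZ, FWZ)
    }
  }
  # covariates present in all models
  X <- cbind(X, age_c = x$age_centered)
  studies <- sort(unique(x$study))
  if (length(studies) > 1) {
    for (s in studies[-1]) {
      ind <- as.integer(x$study == s)
      X <- cbind(X, ind)
      colnames(X)[ncol(X)] <- paste0("study:", s)
    }
    for (s in studies[-1]) {
      X <- cbind(X, as.integer(x$study == s) * x$female)
      colnames(X)[ncol(X)] <- paste0("study:", s, ":female")
    }
  }
  if (!is.null(extra_covariates))
    for (cv in extra_covariates) {
      X <- cbind(X, x[[cv]])
      colnames(X)[ncol(X)] <- cv
    }

  if (any(!is.finite(X)))
    stop("non-finite design entries at records: ",
         paste(utils::head(which(rowSums(!is.finite(X)) > 0)), collapse = ", "))

  runs <- rle(x$pair_id)
  pair_len <- runs$lengths
  pair_start <- cumsum(c(0L, pair_len[-length(pair_len)]))
  pair_dz <- x$zyg_dz[pair_start + 1L]
  structure(list(y = as.numeric(x$dementia), X = X,
                 pair_start = as.integer(pair_start),
                 pair_len = as.integer(pair_len),
                 pair_dz = as.integer(pair_dz),
                 model_id = model_id,
                 n_obs = nrow(X), n_pairs = length(pair_len)),
            class = "bw_design")
}

gh_rule <- function(n_quad) {
  if (n_quad < 1) stop("n_quad must be >= 1")
  pracma::gaussHermite(n_quad)
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Each pair contributes \deqn{\log \int \prod_i f(y_{ij} \mid
#' g^{-1}(\eta_{ij} + u))\, \phi(u; 0, \sigma^2_{zyg(j)})\, du} evaluated by
#' Gauss-Hermite quadrature after recentering and rescaling the nodes at the
#' pair's conditional mode (adaptive quadrature); the total is the sum over
#' pairs. The zygosity of the pair selects between the MZ and DZ
#' random-intercept variances. With both variances zero the integral
#' collapses and the result equals the ordinary fixed-effects Bernoulli (or
#' Gaussian) log-likelihood.
#'
#' @param params List with \code{beta} (fixed effects, in design-column
#'   order), \code{s2_mz}, \code{s2_dz} (variances, >= 0), and for the
#'   Gaussian family \code{scale} (residual SD).
#' @param design A [build_design()] object.
#' @param n_quad Number of quadrature nodes (default 15).
#' @param family \code{"binomial"} or \code{"gaussian"}.
#' @param link \code{"logit"} or \code{"log"} (binomial only).
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(params, design, n_quad = 15,
                            family = c("binomial", "gaussian"),
                            link = c("logit", "log")) {
  family <- match.arg(family); link <- match.arg(link)
  if (any(c(params$s2_mz, params$s2_dz) < 0))
    stop("variance parameters must be non-negative")
  gh <- gh_rule(n_quad)
  fam_code <- if (family == "gaussian") 2L else if (link == "log") 1L else 0L
  scale <- if (family == "gaussian") params$scale else 1
  cpp_aghq_loglik(as.numeric(params$beta), params$s2_mz, params$s2_dz,
                  design$X, design$y, design$pair_start, design$pair_len,
                  design$pair_dz, gh$x, gh$w, fam_code, scale)
}

#' Fit the between-within mixed model by maximum likelihood
#'
#' Maximizes the [marginal_loglik()] over the fixed effects and the
#' log-variances of the zygosity-specific random intercepts with a
#' quasi-Newton (BFGS) search started from an ordinary GLM fit (variances
#' started at 0.5). Standard errors come from the inverted observed
#' information at the optimum; Wald z and two-sided p-values are reported
#' per coefficient. The fit is deterministic given the data and options.
#'
#' @param design A [build_design()] object.
#' @param n_quad Quadrature nodes (default 15).
#' @param family,link As in [marginal_loglik()].
#' @param het_variance Estimate separate MZ and DZ variances (default TRUE;
#'   FALSE shares one variance across zygosity groups).
#' @param fix_sigma2 Optional numeric vector \code{c(mz, dz)} fixing the
#'   variances instead of estimating them.
#' @param start Optional list of starting values (\code{beta},
#'   \code{s2_mz}, \code{s2_dz}).
#' @param max_iter Maximum BFGS iterations.
#' @return Object of class \code{"bw_glmm_fit"} with elements
#'   \code{coefficients} (term, estimate, se, z, p), \code{var_pair_mz},
#'   \code{var_pair_dz} (with SEs), \code{minus2LL}, \code{n_obs},
#'   \code{n_pairs}, \code{n_quad}, \code{converged}, \code{separation},
#'   \code{model_id}, \code{vcov}, \code{grad_norm}.
#' @export
fit_bw_glmm <- function(design, n_quad = 15,
                        family = c("binomial", "gaussian"),
                        link = c("logit", "log"),
                        het_variance = TRUE, fix_sigma2 = NULL,
                        start = NULL, max_iter = 500) {
  family <- match.arg(family); link <- match.arg(link)
  X <- design$X; y <- design$y
  p <- ncol(X)
  gh <- gh_rule(n_quad)
  fam_code <- if (family == "gaussian") 2L else if (link == "log") 1L else 0L
  fixed_var <- !is.null(fix_sigma2)
  if (fixed_var) stopifnot(length(fix_sigma2) == 2, all(fix_sigma2 >= 0))
  est_scale <- family == "gaussian"

  if (!fixed_var && het_variance) {
    for (z in 0:1) if (sum(design$pair_dz == z) < 2)
      stop("need >= 2 pairs in each zygosity group for ",
           "zygosity-specific variances")
  }

  # parameter vector: beta, then log-variances (0, 1 or 2), then log-scale
  n_var <- if (fixed_var) 0L else if (het_variance) 2L else 1L
  unpack <- function(par) {
    beta <- par[seq_len(p)]
    if (fixed_var) {
      s2 <- fix_sigma2
    } else if (het_variance) {
      s2 <- exp(par[p + 1:2])
    } else {
      s2 <- rep(exp(par[p + 1]), 2)
    }
    scale <- if (est_scale) exp(par[p + n_var + 1L]) else 1
    list(beta = unname(beta), s2_mz = unname(s2[1]), s2_dz = unname(s2[2]),
         scale = scale)
  }
  nll <- function(par) {
    q <- unpack(par)
    -cpp_aghq_loglik(q$beta, q$s2_mz, q$s2_dz, X, y,
                     design$pair_start, design$pair_len, design$pair_dz,
                     gh$x, gh$w, fam_code, q$scale)
  }
  # analytic score (Fisher identity over the posterior node weights)
  ngr <- function(par) {
    q <- unpack(par)
    sc <- cpp_aghq_score(q$beta, q$s2_mz, q$s2_dz, X, y,
                         design$pair_start, design$pair_len, design$pair_dz,
                         gh$x, gh$w, fam_code, q$scale)
    g <- -sc$gbeta
    if (!fixed_var) {
      g <- if (het_variance) c(g, -sc$g_ls2_mz, -sc$g_ls2_dz)
           else c(g, -(sc$g_ls2_mz + sc$g_ls2_dz))
    }
    if (est_scale) g <- c(g, -sc$g_lscale)
    g
  }

  if (is.null(start)) {
    if (family == "binomial") {
      g0 <- stats::glm.fit(X, y, family = stats::binomial(link = link))
      beta0 <- g0$coefficients
    } else {
      beta0 <- stats::lm.fit(X, y)$coefficients
    }
    beta0[!is.finite(beta0)] <- 0
    par0 <- c(beta0,
              if (n_var > 0) rep(log(0.5), n_var),
              if (est_scale) log(max(stats::sd(y), 1e-3)))
  } else {
    par0 <- c(start$beta,
              if (n_var == 2) log(pmax(c(start$s2_mz, start$s2_dz), 1e-4))
              else if (n_var == 1) log(max(start$s2_mz, 1e-4)),
              if (est_scale) log(start$scale))
  }

  opt <- stats::optim(par0, nll, gr = ngr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  grad_norm <- max(abs(ngr(opt$par)))
  for (restart in 1:3) {     # polish: BFGS can quit on reltol early
    if (grad_norm <= 1e-4 * max(1, abs(opt$value))) break
    opt2 <- stats::optim(opt$par, nll, gr = ngr, method = "BFGS",
                         control = list(maxit = max_iter, reltol = 1e-12))
    if (opt2$value > opt$value) break
    opt <- opt2
    grad_norm <- max(abs(ngr(opt$par)))
  }
  par_hat <- opt$par

  H <- stats::optimHess(par_hat, nll, gr = ngr)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(par_hat),
                                                      length(par_hat)))
  q <- unpack(par_hat)
  se_beta <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  z <- q$beta / se_beta
  coefs <- data.frame(term = colnames(X), estimate = q$beta, se = se_beta,
                      z = z, p = 2 * stats::pnorm(-abs(z)),
                      row.names = NULL, stringsAsFactors = FALSE)

  var_se <- c(NA_real_, NA_real_)
  if (n_var == 2) {     # delta method from log scale
    var_se <- c(q$s2_mz, q$s2_dz) * sqrt(pmax(diag(vc)[p + 1:2], 0))
  } else if (n_var == 1) {
    var_se <- rep(exp(par_hat[p + 1]) * sqrt(max(diag(vc)[p + 1], 0)), 2)
  }

  # convergence in parameter-scaled units: gradient component times the
  # parameter's SE, i.e. how far (in SEs) the optimum could still move
  se_all <- sqrt(pmax(diag(vc), 0))
  grad_scaled <- max(abs(ngr(par_hat)) * se_all)
  converged <- opt$convergence == 0 && is.finite(grad_scaled) &&
    grad_scaled <= 5e-3 &&
    all(is.finite(se_beta)) && all(se_beta > 0)
  separation <- family == "binomial" && any(abs(q$beta) > 15)
  structure(list(coefficients = coefs,
                 var_pair_mz = q$s2_mz, var_pair_dz = q$s2_dz,
                 var_pair_se = var_se,
                 scale = q$scale,
                 minus2LL = 2 * opt$value,
                 n_obs = design$n_obs, n_pairs = design$n_pairs,
                 n_quad = n_quad, model_id = design$model_id,
                 family = family, link = link,
                 converged = converged, separation = separation,
                 grad_norm = grad_norm, grad_scaled = grad_scaled, vcov = vc,
                 optim_convergence = opt$convergence),
            class = "bw_glmm_fit")
}

#' @export
print.bw_glmm_fit <- function(x, ...) {
  cat(sprintf("Between-within mixed model (Model %s), %s-%s, AGHQ %d nodes\n",
              x$model_id, x$family, x$link, x$n_quad))
  cat(sprintf("  n = %d observations in %d pairs; -2logLik = %.1f%s\n",
              x$n_obs, x$n_pairs, x$minus2LL,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(wald_summary(x), row.names = FALSE)
  cat(sprintf("  Random intercept variance: MZ %.3f (se %.3f), DZ %.3f (se %.3f)\n",
              x$var_pair_mz, x$var_pair_se[1],
              x$var_pair_dz, x$var_pair_se[2]))
  invisible(x)
}

#' Wald coefficient table with significance flags
#'
#' @param fit A [fit_bw_glmm()] result.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The coefficient data frame with a logical \code{sig} column.
#' @export
wald_summary <- function(fit, alpha = 0.05) {
  tab <- fit$coefficients
  tab$sig <- !is.na(tab$p) & tab$p < alpha
  tab
}

#' Fit the ladder of between-within models
#'
#' Convenience wrapper fitting a sequence of the five models on one
#' harmonized cohort.
#'
#' @param cohort A harmonized cohort data frame.
#' @param models Integer vector of model ids (subset of 1:5).
#' @param ... Passed to [build_design()] and [fit_bw_glmm()]
#'   (design arguments: \code{educ_coding}, \code{center_between},
#'   \code{extra_covariates}).
#' @return Named list of \code{"bw_glmm_fit"} objects ("model1", ...).
#' @export
fit_bw_models <- function(cohort, models = 1:4, ...) {
  dots <- list(...)
  design_args <- dots[names(dots) %in%
    c("educ_coding", "center_between", "extra_covariates")]
  fit_args <- dots[!names(dots) %in% names(design_args)]
  fits <- lapply(models, function(m) {
    d <- do.call(build_design, c(list(cohort = cohort, model_id = m),
                                 design_args))
    do.call(fit_bw_glmm, c(list(design = d), fit_args))
  })
  names(fits) <- paste0("model", models)
  fits
}
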