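#' Identify education-discrepant twin pairs
#'
#' A pair is discrepant on educational attainment when its two members do
#' not share the same ISCED category on the nine-category scale. For each
#' discrepant pair the within-pair LDI difference is taken as LDI of the
#' higher-educated member minus LDI of the lower-educated member, so a
#' positive difference means the better-educated twin shows lower dementia
#' likelihood. Pairs are tagged by zygosity and sex (MZF, MZM, DZF, DZM,
#' DZOS). Only pairs where both members have known ISCED, LDI and zygosity
#' are eligible.
#'
#' @param cohort A harmonized cohort data frame.
#' @return Data frame of matched pairs: \code{pair_id}, \code{pair_type},
#'   \code{isced_hi}, \code{isced_lo}, \code{ldi_hi}, \code{ldi_lo},
#'   \code{ldi_diff}.
#' @export
find_discrepant_pairs <- function(cohort) {
  ok <- !is.na(cohort$isced9) & !is.na(cohort$ldi) & !is.na(cohort$zygosity)
  x <- cohort[ok, , drop = FALSE]
  counts <- table(x$pair_id)
  x <- x[x$pair_id %in% names(counts)[counts == 2L], , drop = FALSE]
  x <- x[order(x$pair_id, x$member), , drop = FALSE]
  m1 <- x[x$member == 1L, ]
  m2 <- x[x$member == 2L, ]
  stopifnot(all(m1$pair_id == m2$pair_id))
  disc <- m1$isced9 != m2$isced9
  m1 <- m1[disc, ]; m2 <- m2[disc, ]
  hi_is_1 <- m1$isced9 > m2$isced9
  pick <- function(a, b, take_a) ifelse(take_a, a, b)
  pair_type <- twin_pair_type(m1$zygosity, m1$female, m2$female)
  data.frame(
    pair_id = m1$pair_id,
    pair_type = pair_type,
    isced_hi = pick(m1$isced9, m2$isced9, hi_is_1),
    isced_lo = pick(m2$isced9, m1$isced9, hi_is_1),
    ldi_hi = pick(m1$ldi, m2$ldi, hi_is_1),
    ldi_lo = pick(m2$ldi, m1$ldi, hi_is_1),
    ldi_diff = pick(m1$ldi, m2$ldi, hi_is_1) -
               pick(m2$ldi, m1$ldi, hi_is_1),
    stringsAsFactors = FALSE)
}

twin_pair_type <- function(zygosity, female1, female2) {
  ifelse(female1 != female2, "DZOS",
  ifelse(zygosity == "MZ",
         ifelse(female1 == 1L, "MZF", "MZM"),
         ifelse(female1 == 1L, "DZF", "DZM")))
}

#' Construct unrelated matched pairs
#'
#' Randomly assigns each individual with an LDI score to an unrelated
#' individual matched on sex and year of birth, drawn without replacement:
#' within each (sex, birth-year) stratum, records are shuffled with the
#' seeded RNG and consecutive entries paired; a pairing that lands two
#' members of the same family together is redrawn (up to \code{max_tries}
#' shuffles of the stratum). Matched pairs that are not education-discrepant
#' and individuals with no available match are excluded from the returned
#' pairs but tallied in the attached report.
#'
#' @param cohort A harmonized cohort data frame.
#' @param seed Integer seed for the matching shuffle.
#' @param max_tries Maximum reshuffles per stratum before unmatchable
#'   same-family leftovers are reported.
#' @return Data frame of unrelated matched pairs in the
#'   [find_discrepant_pairs()] layout (pair types \code{UNF}/\code{UNM}),
#'   with attribute \code{"report"}: counts of matched, unmatched,
#'   not-discrepant and discrepant.
#' @export
match_unrelated <- function(cohort, seed = 1L, max_tries = 100L) {
  ok <- !is.na(cohort$isced9) & !is.na(cohort$ldi) &
    !is.na(cohort$female) & !is.na(cohort$birth_year)
  x <- cohort[ok, , drop = FALSE]
  set.seed(seed)
  strata <- split(seq_len(nrow(x)),
                  list(x$female, x$birth_year), drop = TRUE)
  a_idx <- integer(); b_idx <- integer(); n_unmatched <- 0L
  for (s in strata) {
    if (length(s) < 2L) { n_unmatched <- n_unmatched + length(s); next }
    fam <- x$pair_id[s]
    best <- NULL
    for (try in seq_len(max_tries)) {
      perm <- sample(s)
      npair <- length(perm) %/% 2L
      a <- perm[seq_len(npair) * 2L - 1L]
      b <- perm[seq_len(npair) * 2L]
      bad <- x$pair_id[a] == x$pair_id[b]
      if (is.null(best) || sum(bad) < sum(best$bad))
        best <- list(a = a, b = b, bad = bad)
      if (!any(bad)) break
    }
    keep <- !best$bad
    a_idx <- c(a_idx, best$a[keep]); b_idx <- c(b_idx, best$b[keep])
    n_unmatched <- n_unmatched + (length(s) - 2L * sum(keep))
  }
  m1 <- x[a_idx, , drop = FALSE]
  m2 <- x[b_idx, , drop = FALSE]
  disc <- m1$isced9 != m2$isced9
  report <- c(matched_pairs = length(a_idx),
              unmatched_individuals = n_unmatched,
              not_discrepant = sum(!disc),
              discrepant = sum(disc))
  m1 <- m1[disc, , drop = FALSE]; m2 <- m2[disc, , drop = FALSE]
  hi_is_1 <- m1$isced9 > m2$isced9
  pick <- function(a, b, take_a) ifelse(take_a, a, b)
  out <- data.frame(
    pair_id = paste(m1$pair_id, m2$pair_id, sep = "+"),
    pair_type = ifelse(m1$female == 1L, "UNF", "UNM"),
    isced_hi = pick(m1$isced9, m2$isced9, hi_is_1),
    isced_lo = pick(m2$isced9, m1$isced9, hi_is_1),
    ldi_hi = pick(m1$ldi, m2$ldi, hi_is_1),
    ldi_lo = pick(m2$ldi, m1$ldi, hi_is_1),
    ldi_diff = pick(m1$ldi, m2$ldi, hi_is_1) -
               pick(m2$ldi, m1$ldi, hi_is_1),
    stringsAsFactors = FALSE)
  attr(out, "report") <- report
  out
}

#' Matched (paired) t-test on within-pair differences
#'
#' \eqn{t = \bar d / (s_d/\sqrt n)} with a two-sided p-value from the
#' Student-t distribution on \eqn{n-1} degrees of freedom. Zero-variance
#' inputs are flagged degenerate rather than producing an infinite
#' statistic.
#'
#' @param diffs Numeric vector of within-pair differences (n >= 2, finite).
#' @return List of class \code{"paired_t"}: \code{n}, \code{mean_diff},
#'   \code{se}, \code{t_stat}, \code{df}, \code{p_two_sided},
#'   \code{degenerate}.
#' @export
paired_t_test <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L) stop("insufficient data: need at least 2 pairs")
  if (any(!is.finite(diffs))) stop("differences must be finite")
  n <- length(diffs)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  if (s == 0) {
    out <- list(n = n, mean_diff = m, se = 0, t_stat = NA_real_,
                df = n - 1L, p_two_sided = NA_real_, degenerate = TRUE)
  } else {
    se <- s / sqrt(n)
    t <- m / se
    out <- list(n = n, mean_diff = m, se = se, t_stat = t, df = n - 1L,
                p_two_sided = 2 * stats::pt(-abs(t), n - 1L),
                degenerate = FALSE)
  }
  structure(out, class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("matched t-test: n = %d, mean diff = %.4f (se %.4f)\n",
              x$n, x$mean_diff, x$se))
  if (x$degenerate) cat("  degenerate: zero variance in differences\n")
  else cat(sprintf("  t = %.4f, df = %d, p = %.4g\n",
                   x$t_stat, x$df, x$p_two_sided))
  invisible(x)
}

#' Within-pair LDI differences by pair type
#'
#' Runs the matched t-test within each pair type present (MZF, MZM, DZF,
#' DZM, DZOS, UNF, UNM), yielding the mean within-pair difference in
#' dementia likelihood with its standard error for education-discrepant
#' pairs, stratified by genetic relationship and sex.
#'
#' @param pairs Data frame of matched pairs ([find_discrepant_pairs()] /
#'   [match_unrelated()] layout, possibly rbind-ed).
#' @return Data frame with one row per pair type: \code{pair_type},
#'   \code{n}, \code{mean_diff}, \code{se}, \code{t_stat}, \code{df},
#'   \code{p_two_sided}, \code{degenerate}.
#' @export
diff_by_group <- function(pairs) {
  types <- c("UNM", "UNF", "DZOS", "DZM", "DZF", "MZM", "MZF")
  present <- types[types %in% pairs$pair_type]
  rows <- lapply(present, function(tp) {
    d <- pairs$ldi_diff[pairs$pair_type == tp]
    tt <- paired_t_test(d)
    data.frame(pair_type = tp, n = tt$n, mean_diff = tt$mean_diff,
               se = tt$se, t_stat = tt$t_stat, df = tt$df,
               p_two_sided = tt$p_two_sided, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
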