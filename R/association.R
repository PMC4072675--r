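# Per-SNP case-control association statistics: allelic and genotypic
# Pearson chi-square tests, Hardy-Weinberg goodness of fit, risk-oriented
# allelic odds ratios with Wald intervals, Bonferroni and max-T permutation
# adjustment, and the design power calculation.
#
# Degenerate tables (monomorphic SNPs, zero margins) return p = 1 with a
# `degenerate` flag instead of raising, so batch runs over many simulated
# panels never abort.

# Pearson chi-square on a contingency table, no continuity correction.
# Zero-margin rows/columns must be handled by the caller.
pearson_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Tabulate case/control allele counts at one SNP
#'
#' The minor allele is defined by the control cohort frequency; at an exact
#' 50/50 tie, `allele_b` is taken as minor. Samples with missing calls at
#' the SNP are excluded (per-SNP complete-case analysis).
#'
#' @param case `genotype_matrix` of case (germline) samples.
#' @param control `genotype_matrix` of control samples.
#' @param rsid marker to tabulate.
#' @return A list of class `allele_counts`: `case_minor`, `case_major`,
#'   `control_minor`, `control_major` (allele counts), `minor_allele` (its
#'   nucleotide symbol), `minor_is_b`, `maf_case`, `maf_control` and `rsid`.
#' @export
allele_counts <- function(case, control, rsid) {
  j <- match(rsid, case$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid)
  dc <- case$dosage[, j]
  d0 <- control$dosage[, j]
  b_case <- sum(dc, na.rm = TRUE)
  n_case <- 2L * sum(!is.na(dc))
  b_ctrl <- sum(d0, na.rm = TRUE)
  n_ctrl <- 2L * sum(!is.na(d0))
  fb_ctrl <- if (n_ctrl > 0) b_ctrl / n_ctrl else 0.5
  minor_is_b <- fb_ctrl <= 0.5
  res <- if (minor_is_b) {
    list(case_minor = b_case, case_major = n_case - b_case,
         control_minor = b_ctrl, control_major = n_ctrl - b_ctrl)
  } else {
    list(case_minor = n_case - b_case, case_major = b_case,
         control_minor = n_ctrl - b_ctrl, control_major = b_ctrl)
  }
  res$minor_is_b <- minor_is_b
  res$minor_allele <- if (minor_is_b) case$panel$allele_b[j] else
    case$panel$allele_a[j]
  res$maf_case <- if (n_case > 0)
    res$case_minor / n_case else NA_real_
  res$maf_control <- if (n_ctrl > 0)
    res$control_minor / n_ctrl else NA_real_
  res$rsid <- rsid
  class(res) <- "allele_counts"
  res
}

#' Allelic chi-square test on a 2x2 allele-count table
#'
#' One-degree-of-freedom Pearson chi-square comparing minor-allele
#' frequency between cases and controls, without continuity correction.
#'
#' @param counts an `allele_counts` object, or a list/vector with fields
#'   `case_minor`, `case_major`, `control_minor`, `control_major`.
#' @return List with `chi2`, `p` and `degenerate` (TRUE when a zero margin
#'   makes the test undefined, in which case chi2 = 0 and p = 1).
#' @export
allele_chi2_test <- function(counts) {
  tab <- matrix(c(counts$case_minor, counts$case_major,
                  counts$control_minor, counts$control_major),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("allele counts must be non-negative")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  }
  chi2 <- pearson_chi2(tab)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Tabulate genotype counts at one SNP
#'
#' @param mat `genotype_matrix`.
#' @param rsid marker.
#' @return Integer vector `c(n_aa, n_ab, n_bb)` over non-missing samples.
#' @export
genotype_counts <- function(mat, rsid) {
  j <- match(rsid, mat$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid)
  d <- mat$dosage[, j]
  c(n_aa = sum(d == 0L, na.rm = TRUE), n_ab = sum(d == 1L, na.rm = TRUE),
    n_bb = sum(d == 2L, na.rm = TRUE))
}

#' Genotypic chi-square test on a 2x3 genotype table
#'
#' Pearson chi-square comparing the genotype distribution between cases and
#' controls. Genotype classes absent from both cohorts are dropped with the
#' degrees of freedom reduced accordingly.
#'
#' @param case,control integer vectors `c(n_aa, n_ab, n_bb)`.
#' @return List with `chi2`, `df`, `p`, `degenerate`.
#' @export
genotype_chi2_test <- function(case, control) {
  tab <- rbind(case = as.numeric(case), control = as.numeric(control))
  if (any(tab < 0)) stop("genotype counts must be non-negative")
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
    return(list(chi2 = 0, df = 0L, p = 1, degenerate = TRUE))
  }
  chi2 <- pearson_chi2(tab)
  df <- ncol(tab) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Hardy-Weinberg equilibrium test
#'
#' Goodness-of-fit chi-square (1 df) of observed genotype counts against
#' the p^2, 2pq, q^2 expectation at the observed allele frequency, or an
#' exact test that enumerates heterozygote counts conditional on the minor
#' allele count.
#'
#' @param counts integer vector `c(n_aa, n_ab, n_bb)`.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return List with `p`, `chi2` (`NA` for the exact test) and `degenerate`
#'   (monomorphic input).
#' @export
hwe_test <- function(counts, method = c("chisq", "exact")) {
  method <- match.arg(method)
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be c(n_aa, n_ab, n_bb), all non-negative")
  }
  n <- sum(counts)
  if (n == 0) return(list(p = 1, chi2 = NA_real_, degenerate = TRUE))
  p_a <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p_a == 0 || p_a == 1) {
    return(list(p = 1, chi2 = 0, degenerate = TRUE))
  }
  if (method == "chisq") {
    expected <- n * c(p_a^2, 2 * p_a * (1 - p_a), (1 - p_a)^2)
    chi2 <- sum((counts - expected)^2 / expected)
    list(p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), chi2 = chi2,
         degenerate = FALSE)
  } else {
    list(p = hwe_exact_p(counts), chi2 = NA_real_, degenerate = FALSE)
  }
}

# Exact HWE p: sum of probabilities of heterozygote counts no more likely
# than the observed one, conditional on the rare-allele count.
hwe_exact_p <- function(counts) {
  n <- sum(counts)
  n_rare <- min(2 * counts[1] + counts[2], 2 * counts[3] + counts[2])
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- counts[2]
  min(1, sum(prob[prob <= prob[hets == obs] * (1 + 1e-9)]))
}

#' Allelic odds ratio with Wald 95% confidence interval
#'
#' OR = (case_minor * control_major) / (case_major * control_minor). When
#' any cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied before the Wald interval. With `orient_risk = TRUE` an OR below
#' 1 is reciprocated (interval reciprocated and reversed) so the reported
#' ratio refers to the case-enriched allele, matching the usual reporting
#' convention for replication tables.
#'
#' @param counts an `allele_counts` object (or compatible list).
#' @param orient_risk orient the OR to the case-enriched allele?
#' @param conf_level confidence level for the Wald interval.
#' @return List with `or_value`, `ci_low`, `ci_high`, `oriented` (TRUE when
#'   the reciprocal was reported), `reported_allele` (`"minor"` or
#'   `"major"`), and `undefined` (both cells of a diagonal zero).
#' @export
allelic_odds_ratio <- function(counts, orient_risk = TRUE,
                               conf_level = 0.95) {
  a <- counts$case_minor; b <- counts$case_major
  c0 <- counts$control_minor; d <- counts$control_major
  if ((a == 0 && d == 0) || (b == 0 && c0 == 0)) {
    return(list(or_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                oriented = FALSE, reported_allele = NA_character_,
                undefined = TRUE))
  }
  if (any(c(a, b, c0, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c0)
  se <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  oriented <- FALSE
  reported <- "minor"
  if (orient_risk && or < 1) {
    or <- 1 / or
    ci <- rev(1 / ci)
    oriented <- TRUE
    reported <- "major"
  }
  list(or_value = or, ci_low = ci[1], ci_high = ci[2], oriented = oriented,
       reported_allele = reported, undefined = FALSE)
}

#' Odds ratio from a pair of allele frequencies
#'
#' OR = odds(maf_case) / odds(maf_control); with `orient_risk = TRUE`
#' ratios below 1 are reciprocated so the reported value refers to the
#' case-enriched allele. This is how a published replication table's OR
#' column is reconstructed from its printed MAF columns.
#'
#' @param maf_case,maf_control allele frequencies in (0, 1).
#' @param orient_risk reciprocate ORs below 1?
#' @return The odds ratio (`NA` when either frequency is 0 or 1).
#' @export
or_from_maf <- function(maf_case, maf_control, orient_risk = TRUE) {
  if (any(maf_case <= 0 | maf_case >= 1 | maf_control <= 0 |
          maf_control >= 1)) {
    return(NA_real_)
  }
  or <- (maf_case / (1 - maf_case)) / (maf_control / (1 - maf_control))
  if (orient_risk) or <- ifelse(or < 1, 1 / or, or)
  or
}

#' Bonferroni adjustment at an explicit family size
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param m family size (defaults to the number of p-values; must be at
#'   least that).
#' @return `pmin(1, p_values * m)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("family size m smaller than number of tests")
  pmin(1, p_values * m)
}

# Vectorised 1-df allelic chi-square from minor(b)-allele counts and allele
# totals per group; zero margins give statistic 0.
chi2_from_allele_counts <- function(b1, n1, b2, n2) {
  a <- b1; b <- n1 - b1; c0 <- b2; d <- n2 - b2
  N <- n1 + n2
  col1 <- a + c0
  col2 <- b + d
  num <- (a * d - b * c0)^2 * N
  den <- n1 * n2 * col1 * col2
  out <- ifelse(den > 0, num / den, 0)
  out
}

#' Westfall-Young max-T permutation adjustment of allelic test p-values
#'
#' Permutes case/control labels, recomputes every per-SNP allelic
#' chi-square, and applies the step-down max-T construction: the adjusted
#' p-value of the i-th ordered statistic is the proportion of permutations
#' whose maximum statistic over the SNPs still in the step-down set reaches
#' the observed one, with monotonicity enforced down the ordering and the
#' add-one correction so no adjusted p is below 1/(n_perm + 1). Controls
#' the family-wise error rate while respecting the correlation structure
#' among markers, which plain Bonferroni ignores.
#'
#' @param case,control `genotype_matrix` cohorts over a shared panel.
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed; the permutation stream is reproducible.
#' @return Data frame with `rsid`, `chi2`, `p_raw` (asymptotic 1-df) and
#'   `p_perm` (max-T adjusted), in panel order.
#' @export
permutation_adjust <- function(case, control, n_perm = 1000, seed = NULL) {
  if (!identical(case$panel$rsid, control$panel$rsid)) {
    stop("case and control matrices must share the same panel")
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  n1 <- nrow(case$dosage); n2 <- nrow(control$dosage)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per cohort")
  D <- rbind(case$dosage, control$dosage)
  M <- !is.na(D)
  Dz <- D; Dz[!M] <- 0L
  storage.mode(Dz) <- "double"
  Mn <- M; storage.mode(Mn) <- "double"
  n <- n1 + n2
  tot_b <- colSums(Dz)
  tot_n <- 2 * colSums(Mn)

  obs_b1 <- colSums(Dz[seq_len(n1), , drop = FALSE])
  obs_n1 <- 2 * colSums(Mn[seq_len(n1), , drop = FALSE])
  obs <- chi2_from_allele_counts(obs_b1, obs_n1, tot_b - obs_b1,
                                 tot_n - obs_n1)

  P <- with_seed(seed, {
    out <- matrix(0, nrow = n, ncol = n_perm)
    for (bb in seq_len(n_perm)) out[sample.int(n, n1), bb] <- 1
    out
  })
  perm_b1 <- crossprod(P, Dz)            # n_perm x m case b-allele counts
  perm_n1 <- 2 * crossprod(P, Mn)
  perm_stat <- matrix(chi2_from_allele_counts(
    perm_b1, perm_n1,
    matrix(tot_b, n_perm, length(tot_b), byrow = TRUE) - perm_b1,
    matrix(tot_n, n_perm, length(tot_n), byrow = TRUE) - perm_n1),
    nrow = n_perm)

  m <- length(obs)
  ord <- order(obs, decreasing = TRUE)
  # successive maxima over the step-down sets, from the smallest statistic up
  succ_max <- perm_stat[, ord, drop = FALSE]
  for (i in seq(m - 1, 1)) {
    if (m > 1) succ_max[, i] <- pmax(succ_max[, i], succ_max[, i + 1])
  }
  p_adj_ord <- vapply(seq_len(m), function(i) {
    (1 + sum(succ_max[, i] >= obs[ord[i]] - 1e-12)) / (n_perm + 1)
  }, numeric(1))
  p_adj_ord <- cummax(p_adj_ord)
  p_perm <- numeric(m)
  p_perm[ord] <- p_adj_ord
  p_raw <- stats::pchisq(obs, df = 1, lower.tail = FALSE)
  # an adjusted p-value is never reported below its raw p-value
  p_perm <- pmax(p_perm, p_raw)
  data.frame(rsid = case$panel$rsid, chi2 = obs, p_raw = p_raw,
             p_perm = p_perm, stringsAsFactors = FALSE)
}

#' Power of the case-control allelic test
#'
#' Power to detect an allele-frequency difference `delta` between cases and
#' controls with a two-proportion test on 2n alleles per group, either by
#' the normal approximation or by simulating cohorts under Hardy-Weinberg
#' sampling and counting allelic chi-square rejections.
#'
#' @param n_case,n_control cohort sizes (individuals; each contributes two
#'   alleles).
#' @param maf_control control minor-allele frequency.
#' @param delta case-minus-control allele-frequency difference.
#' @param alpha two-sided type-I error level.
#' @param method `"analytic"` or `"simulation"`.
#' @param n_reps simulated cohorts for `method = "simulation"`.
#' @param seed integer seed for the simulation.
#' @return Estimated power in \[0, 1\]; equals `alpha` when `delta = 0`
#'   under the analytic method (test size, not power).
#' @export
power_allele_test <- function(n_case, n_control, maf_control, delta,
                              alpha = 0.05,
                              method = c("analytic", "simulation"),
                              n_reps = 2000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(maf_control > 0, maf_control + delta < 1, alpha > 0, alpha < 1)
  p1 <- maf_control + delta
  p2 <- maf_control
  n1 <- 2 * n_case
  n2 <- 2 * n_control
  if (method == "analytic") {
    if (delta == 0) return(alpha)
    z <- stats::qnorm(1 - alpha / 2)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    stats::pnorm((delta - z * se0) / se1) +
      stats::pnorm((-delta - z * se0) / se1)
  } else {
    with_seed(seed, {
      b1 <- stats::rbinom(n_reps, n1, p1)
      b2 <- stats::rbinom(n_reps, n2, p2)
      chi2 <- chi2_from_allele_counts(b1, n1, b2, n2)
      crit <- stats::qchisq(1 - alpha, df = 1)
      mean(chi2 > crit)
    })
  }
}

#' Full per-SNP association table for a case-control panel
#'
#' Runs, for every panel SNP: allele counting, the 1-df allelic chi-square,
#' the genotypic chi-square, the control-cohort Hardy-Weinberg test, the
#' risk-oriented allelic odds ratio with Wald 95% CI, and Bonferroni
#' (and optionally max-T permutation) adjustment of the allelic p-values.
#'
#' @param case,control `genotype_matrix` cohorts over a shared panel.
#' @param n_perm permutations for the max-T adjustment; 0 skips it.
#' @param seed seed for the permutation stream.
#' @param orient_risk orient odds ratios to the case-enriched allele?
#' @param m_tests Bonferroni family size (default: panel size).
#' @return Data frame with one row per SNP in panel order: `rsid`,
#'   `minor_allele`, `maf_case`, `maf_control`, `chi2_allele`, `p_allele`,
#'   `p_genotype`, `or_value`, `ci_low`, `ci_high`, `p_hwe_controls`,
#'   `p_bonferroni` and (when `n_perm > 0`) `p_permutation`.
#' @export
associate <- function(case, control, n_perm = 0, seed = NULL,
                      orient_risk = TRUE, m_tests = NULL) {
  if (!identical(case$panel$rsid, control$panel$rsid)) {
    stop("case and control matrices must share the same panel")
  }
  panel <- case$panel
  if (is.null(m_tests)) m_tests <- nrow(panel)
  rows <- lapply(panel$rsid, function(rs) {
    ac <- allele_counts(case, control, rs)
    at <- allele_chi2_test(ac)
    gt <- genotype_chi2_test(genotype_counts(case, rs),
                             genotype_counts(control, rs))
    hw <- hwe_test(genotype_counts(control, rs))
    or <- allelic_odds_ratio(ac, orient_risk = orient_risk)
    data.frame(rsid = rs, minor_allele = ac$minor_allele,
               maf_case = ac$maf_case, maf_control = ac$maf_control,
               chi2_allele = at$chi2, p_allele = at$p,
               p_genotype = gt$p, or_value = or$or_value,
               ci_low = or$ci_low, ci_high = or$ci_high,
               p_hwe_controls = hw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- bonferroni_adjust(res$p_allele, m = m_tests)
  if (n_perm > 0) {
    perm <- permutation_adjust(case, control, n_perm = n_perm, seed = seed)
    res$p_permutation <- perm$p_perm[match(res$rsid, perm$rsid)]
  }
  res
}
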