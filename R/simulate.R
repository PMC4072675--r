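# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: diallelic
# genotypes under Hardy-Weinberg equilibrium at specified control MAFs,
# case cohorts under a per-allele (log-additive) odds model, LD-proxy SNP
# pairs at a target r-squared, per-genotype no-call rates, and tumor
# genotypes derived from germline calls by allele-specific LOH with a
# configurable rate, retention bias and tumor-purity-dependent miscall
# model. All generators are deterministic under a fixed seed.

#' Default 19-SNP study panel
#'
#' The colorectal-cancer susceptibility candidate panel: 19 markers with
#' their chromosome, position, case and control minor-allele frequencies,
#' and the per-SNP generative parameters for the paired-tumor simulator
#' (LOH rate among informative heterozygotes and the probability that the
#' retained allele is allele A). `allele_b` is the control minor allele.
#'
#' Allele pairs are illustrative fixture values (the assay's allele pairs
#' are not published), except rs4444235 whose preferentially retained
#' C allele is documented; its pair is C/T with risk allele C. Risk alleles
#' for the remaining markers are designated as the case-enriched allele
#' implied by the MAF columns, again a fixture convention.
#'
#' @return Panel data frame with columns `rsid`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `risk_allele`, `maf_case`, `maf_control`,
#'   `or_b` (generative per-allele odds ratio on allele B, signed:
#'   below 1 when allele B is protective), `loh_rate`, `retention_bias`.
#' @export
default_panel <- function() {
  panel <- data.frame(
    rsid = c("rs6687758", "rs10936599", "rs12657484", "rs11525793",
             "rs10505477", "rs6983267", "rs7014346", "rs7466603",
             "rs10795668", "rs1338565", "rs1665645", "rs3802842",
             "rs4631962", "rs4444235", "rs4779584", "rs9929218",
             "rs4939827", "rs10404811", "rs961253"),
    chrom = c("1", "3", "5", "7", "8", "8", "8", "9", "10", "10", "10",
              "11", "12", "14", "15", "16", "18", "19", "20"),
    pos = c(222164948L, 169492101L, 134503751L, 15648935L, 128407443L,
            128413305L, 128424792L, 94483198L, 8701219L, 44059676L,
            118487954L, 111171709L, 4373132L, 54410919L, 32994756L,
            68820946L, 46453463L, 58154807L, 6404281L),
    allele_a = c("A", "C", "G", "A", "C", "T", "A", "G", "C", "A", "T",
                 "G", "C", "C", "A", "G", "C", "A", "G"),
    allele_b = c("G", "T", "A", "G", "T", "C", "G", "A", "T", "G", "C",
                 "A", "T", "T", "G", "A", "T", "G", "A"),
    maf_case = c(0.203, 0.451, 0.331, 0.407, 0.446, 0.444, 0.324, 0.072,
                 0.35, 0.439, 0.288, 0.473, 0.328, 0.473, 0.192, 0.187,
                 0.304, 0.368, 0.076),
    maf_control = c(0.196, 0.457, 0.342, 0.412, 0.426, 0.428, 0.333,
                    0.077, 0.378, 0.476, 0.309, 0.453, 0.299, 0.497,
                    0.197, 0.195, 0.297, 0.366, 0.075),
    n_informative_ref = c(237L, 354L, 276L, 330L, 308L, 311L, 284L, 92L,
                          297L, 320L, 292L, 355L, 281L, 302L, 207L, 211L,
                          251L, 311L, 87L),
    n_homo_a_ref = c(2L, 6L, 37L, 10L, 8L, 9L, 8L, 1L, 5L, 5L, 10L, 21L,
                     8L, 27L, 15L, 6L, 55L, 7L, 5L),
    n_homo_b_ref = c(3L, 4L, 13L, 3L, 15L, 2L, 8L, 1L, 6L, 6L, 8L, 5L,
                     5L, 4L, 17L, 0L, 35L, 10L, 9L),
    stringsAsFactors = FALSE)
  # case-enriched allele (fixture designation of the risk allele)
  panel$risk_allele <- ifelse(panel$maf_case >= panel$maf_control,
                              panel$allele_b, panel$allele_a)
  odds <- function(p) p / (1 - p)
  panel$or_b <- odds(panel$maf_case) / odds(panel$maf_control)
  n_loh <- panel$n_homo_a_ref + panel$n_homo_b_ref
  panel$loh_rate <- n_loh / panel$n_informative_ref
  panel$retention_bias <- panel$n_homo_a_ref / n_loh
  panel <- panel[, c("rsid", "chrom", "pos", "allele_a", "allele_b",
                     "risk_allele", "maf_case", "maf_control", "or_b",
                     "loh_rate", "retention_bias")]
  validate_panel(panel)
  panel
}

#' Simulation configuration
#'
#' Bundles every generative parameter of a synthetic study. Per-SNP
#' parameters (`maf_control`, `or_b`, `loh_rate`, `retention_bias`) are
#' taken from the panel columns; scalar overrides here are recycled across
#' the panel.
#'
#' @param panel SNP panel with generative columns (default:
#'   [default_panel()]).
#' @param n_case,n_control cohort sizes (defaults: the study's 705 cases
#'   and 1802 controls).
#' @param loh_rate optional override: probability an informative
#'   heterozygote shows LOH in the tumor.
#' @param retention_bias optional override: probability the retained allele
#'   is allele A, given LOH.
#' @param no_call_rate per-genotype missing-call probability.
#' @param purity tumor-cell fraction in \[0.5, 1\]; with contamination by
#'   normal cells a true LOH event is called homozygous only with
#'   probability `2 * purity - 1`.
#' @param ld_r2 target r-squared when generating LD-proxy pairs.
#' @param seed integer seed used by the generators.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(panel = default_panel(), n_case = 705,
                       n_control = 1802, loh_rate = NULL,
                       retention_bias = NULL, no_call_rate = 0.02,
                       purity = 1, ld_r2 = 0.8, seed = NULL) {
  validate_panel(panel)
  stopifnot(n_case >= 1, n_control >= 1,
            no_call_rate >= 0, no_call_rate <= 1,
            purity >= 0.5, purity <= 1, ld_r2 >= 0, ld_r2 <= 1)
  m <- nrow(panel)
  get_vec <- function(override, column, default) {
    v <- if (!is.null(override)) override
    else if (column %in% names(panel)) panel[[column]]
    else default
    if (length(v) == 1) v <- rep(v, m)
    if (length(v) != m) stop(column, " must be scalar or one value per SNP")
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(column, " must lie in [0, 1]")
    v
  }
  cfg <- list(panel = panel, n_case = n_case, n_control = n_control,
              maf_control = get_vec(NULL, "maf_control", NA_real_),
              or_b = if ("or_b" %in% names(panel)) panel$or_b else
                rep(1, m),
              loh_rate = get_vec(loh_rate, "loh_rate", 0),
              retention_bias = get_vec(retention_bias, "retention_bias",
                                       0.5),
              no_call_rate = no_call_rate, purity = purity,
              ld_r2 = ld_r2, seed = seed)
  if (any(is.na(cfg$maf_control))) stop("panel must carry maf_control")
  if (any(cfg$or_b <= 0)) stop("generative odds ratios must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# HWE genotype draw: dosage ~ Binomial(2, freq of allele b), with no-calls.
draw_hwe <- function(n, maf_b, no_call_rate) {
  m <- length(maf_b)
  d <- matrix(stats::rbinom(n * m, 2, rep(maf_b, each = n)), nrow = n)
  if (no_call_rate > 0) {
    d[matrix(stats::runif(n * m) < no_call_rate, nrow = n)] <- NA_integer_
  }
  d
}

#' Simulate a control cohort
#'
#' Genotypes drawn per SNP under Hardy-Weinberg equilibrium at the panel's
#' control minor-allele frequency, with independent no-calls.
#'
#' @param config a [sim_config()].
#' @param seed seed override (default: the config's seed).
#' @return A `genotype_matrix` with cohort `control`.
#' @export
simulate_controls <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    d <- draw_hwe(config$n_control, config$maf_control,
                  config$no_call_rate)
    rownames(d) <- sprintf("control%05d", seq_len(config$n_control))
    genotype_matrix(d, config$panel, "control")
  })
}

#' Simulate a case (germline) cohort under a per-allele odds model
#'
#' Case allele-B frequency p' solves odds(p') = OR_b * odds(p) at the
#' panel's control frequency p; genotypes are drawn under Hardy-Weinberg
#' equilibrium at p' (log-additive risk model, matching the allelic odds
#' ratio the association module estimates).
#'
#' @param config a [sim_config()].
#' @param seed seed override.
#' @return A `genotype_matrix` with cohort `case_normal`; sample IDs are
#'   patient IDs shared with the paired tumor simulator.
#' @export
simulate_cases <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  odds <- config$maf_control / (1 - config$maf_control)
  case_odds <- config$or_b * odds
  maf_case_b <- case_odds / (1 + case_odds)
  with_seed(seed, {
    d <- draw_hwe(config$n_case, maf_case_b, config$no_call_rate)
    rownames(d) <- sprintf("patient%05d", seq_len(config$n_case))
    genotype_matrix(d, config$panel, "case_normal")
  })
}

#' Simulate tumor genotype calls paired to a germline cohort
#'
#' For each germline heterozygote, an LOH event occurs with the per-SNP
#' `loh_rate`; the retained allele is allele A with probability
#' `retention_bias`. The resulting tumor CALL is homozygous only with
#' probability `2 * purity - 1` (at purity 0.5 contamination by normal
#' cells restores the heterozygous call; at purity 1 calls are faithful),
#' otherwise the call stays heterozygous. Germline homozygotes are copied
#' unchanged -- hard-call LOH analysis cannot create heterozygosity -- and
#' no-calls are applied independently at the configured rate.
#'
#' @param germline `genotype_matrix` of `case_normal` samples.
#' @param config a [sim_config()].
#' @param seed seed override.
#' @return A `genotype_matrix` with cohort `case_tumor` and the germline's
#'   patient IDs.
#' @export
simulate_tumor_pairs <- function(germline, config, seed = config$seed) {
  stopifnot(inherits(germline, "genotype_matrix"),
            inherits(config, "sim_config"))
  if (!all(germline$cohort == "case_normal")) {
    stop("germline matrix must contain case_normal samples only")
  }
  if (!identical(germline$panel$rsid, config$panel$rsid)) {
    stop("germline matrix and config must share the same panel")
  }
  q_call <- max(0, min(1, 2 * config$purity - 1))
  with_seed(seed, {
    d <- germline$dosage
    for (j in seq_len(ncol(d))) {
      het <- which(!is.na(d[, j]) & d[, j] == 1L)
      if (length(het) == 0) next
      has_loh <- stats::runif(length(het)) < config$loh_rate[j]
      idx <- het[has_loh]
      if (length(idx) == 0) next
      retain_a <- stats::runif(length(idx)) < config$retention_bias[j]
      called_hom <- stats::runif(length(idx)) < q_call
      tumor_dos <- ifelse(called_hom, ifelse(retain_a, 0L, 2L), 1L)
      d[idx, j] <- tumor_dos
    }
    if (config$no_call_rate > 0) {
      nc <- matrix(stats::runif(length(d)) < config$no_call_rate,
                   nrow = nrow(d))
      d[nc] <- NA_integer_
    }
    genotype_matrix(d, germline$panel, "case_tumor")
  })
}

#' Largest linkage-disequilibrium r-squared achievable for two MAFs
#'
#' In the positive-D orientation used by [simulate_ld_pair()] (allele B of
#' one marker tags allele B of the other).
#'
#' @param maf1,maf2 allele-B frequencies of the two markers.
#' @return Maximum attainable squared allelic correlation.
#' @export
ld_r2_max <- function(maf1, maf2) {
  d_max <- min(maf1 * (1 - maf2), (1 - maf1) * maf2)
  d_max^2 / (maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

#' Simulate a pair of SNPs in linkage disequilibrium
#'
#' Draws individuals as pairs of two-locus haplotypes from the haplotype
#' distribution whose squared allelic correlation equals `r2_target`
#' (positive-D orientation). Infeasible (MAF, r-squared) combinations --
#' where the implied haplotype frequency would leave \[0, 1\] -- raise an
#' error naming the feasible maximum.
#'
#' @param maf1,maf2 allele-B frequencies of the two markers.
#' @param r2_target target squared correlation in \[0, 1\].
#' @param n number of diploid individuals.
#' @param seed integer seed.
#' @return List with integer dosage vectors `g1`, `g2`, the haplotype
#'   frequency vector `hap_freq` (BB, Bb, bB, bb order on alleles of SNP1
#'   and SNP2), and `r2_target`.
#' @export
simulate_ld_pair <- function(maf1, maf2, r2_target, n, seed = NULL) {
  stopifnot(maf1 > 0, maf1 < 1, maf2 > 0, maf2 < 1,
            r2_target >= 0, r2_target <= 1, n >= 1)
  denom <- maf1 * (1 - maf1) * maf2 * (1 - maf2)
  d <- sqrt(r2_target * denom)
  d_max <- min(maf1 * (1 - maf2), (1 - maf1) * maf2)
  if (d > d_max + 1e-12) {
    stop(sprintf(paste0("r2 = %.3f infeasible for MAFs (%.3f, %.3f); ",
                        "maximum feasible r2 in this orientation is %.3f"),
                 r2_target, maf1, maf2, d_max^2 / denom))
  }
  hap <- c(bb = maf1 * maf2 + d,
           bB = maf1 * (1 - maf2) - d,
           Bb = (1 - maf1) * maf2 - d,
           BB = (1 - maf1) * (1 - maf2) + d)
  hap <- pmax(hap, 0)
  hap <- hap / sum(hap)
  with_seed(seed, {
    h <- sample.int(4, 2 * n, replace = TRUE, prob = hap)
    carries_b1 <- h %in% c(1L, 2L)   # haplotypes carrying allele b at SNP1
    carries_b2 <- h %in% c(1L, 3L)
    g1 <- colSums(matrix(carries_b1, nrow = 2))
    g2 <- colSums(matrix(carries_b2, nrow = 2))
    list(g1 = as.integer(g1), g2 = as.integer(g2), hap_freq = hap,
         r2_target = r2_target)
  })
}

#' Simulate a panel of unlinked markers
#'
#' Independent SNPs with uniform-random MAFs in `maf_range`, genotyped
#' under Hardy-Weinberg equilibrium; the null input for PCA and
#' inflation-factor calibration.
#'
#' @param n_samples number of samples.
#' @param n_snps number of markers (>= 2).
#' @param maf_range range the per-SNP MAFs are drawn from.
#' @param seed integer seed.
#' @param cohort cohort label for the samples.
#' @return A `genotype_matrix` whose panel carries the drawn `maf_control`.
#' @export
simulate_unlinked_panel <- function(n_samples, n_snps,
                                    maf_range = c(0.1, 0.5), seed = NULL,
                                    cohort = "control") {
  stopifnot(n_snps >= 2, n_samples >= 1)
  with_seed(seed, {
    mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
    panel <- data.frame(
      rsid = sprintf("usnp%03d", seq_len(n_snps)),
      chrom = as.character(rep_len(1:22, n_snps)),
      pos = seq_len(n_snps) * 1000L,
      allele_a = "A", allele_b = "G", risk_allele = NA_character_,
      maf_control = mafs, stringsAsFactors = FALSE)
    d <- draw_hwe(n_samples, mafs, 0)
    rownames(d) <- sprintf("s%05d", seq_len(n_samples))
    genotype_matrix(d, panel, cohort)
  })
}
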