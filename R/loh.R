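# Loss-of-heterozygosity and allele-specific imbalance analysis of paired
# tumor / adjacent-normal genotypes.
#
# LOH is called only from hard genotype transitions: a patient is
# informative at a SNP when the adjacent-normal genotype is heterozygous
# (only then is allele loss detectable), and an LOH event is a tumor call
# that is homozygous at an informative site. No intensity or allelic-ratio
# modelling is attempted; calling from conservative hard genotypes is known
# to bias detection toward copy-number loss.

#' Informative tumor/normal pairs at one SNP
#'
#' Keeps patients whose adjacent-normal genotype is heterozygous and whose
#' tumor call is not missing. Heterozygous normals with a missing tumor
#' call carry no information and are dropped, not counted as LOH.
#'
#' @param normals,tumors paired `genotype_matrix` objects in identical
#'   sample order (see [pair_samples()]).
#' @param rsid marker.
#' @return Data frame with `patient_id`, `normal` and `tumor` dosages for
#'   the informative pairs (possibly zero rows).
#' @export
informative_pairs <- function(normals, tumors, rsid) {
  if (!identical(rownames(normals$dosage), rownames(tumors$dosage))) {
    stop("normals and tumors must be paired and in identical sample order")
  }
  j <- match(rsid, normals$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid)
  dn <- normals$dosage[, j]
  dt <- tumors$dosage[, j]
  keep <- !is.na(dn) & dn == 1L & !is.na(dt)
  data.frame(patient_id = rownames(normals$dosage)[keep],
             normal = dn[keep], tumor = dt[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify tumor calls of informative pairs into LOH counts
#'
#' Tumor dosage 0 is loss of allele B (homozygous A), dosage 2 is loss of
#' allele A (homozygous B), dosage 1 is a retained heterozygote.
#'
#' @param pairs data frame from [informative_pairs()] (tumor dosages must
#'   be non-missing; missing calls are a contract violation here).
#' @return List of class `loh_counts`: `n_informative`, `n_homo_a`,
#'   `n_homo_b`, `n_het_retained`, `n_loh`.
#' @export
call_loh <- function(pairs) {
  t_dos <- pairs$tumor
  if (any(is.na(t_dos))) {
    stop("missing tumor calls must be filtered by informative_pairs()")
  }
  counts <- loh_counts(n_homo_a = sum(t_dos == 0L),
                       n_homo_b = sum(t_dos == 2L),
                       n_het_retained = sum(t_dos == 1L))
  counts
}

#' Construct an LOH count record
#'
#' @param n_homo_a tumors homozygous for allele A among informative pairs.
#' @param n_homo_b tumors homozygous for allele B.
#' @param n_het_retained tumors still heterozygous.
#' @return List of class `loh_counts` with the three counts plus the
#'   derived `n_informative` (their sum) and `n_loh` (homozygous total).
#' @export
loh_counts <- function(n_homo_a, n_homo_b, n_het_retained) {
  stopifnot(n_homo_a >= 0, n_homo_b >= 0, n_het_retained >= 0)
  structure(list(n_informative = n_homo_a + n_homo_b + n_het_retained,
                 n_homo_a = n_homo_a, n_homo_b = n_homo_b,
                 n_het_retained = n_het_retained,
                 n_loh = n_homo_a + n_homo_b),
            class = "loh_counts")
}

#' LOH percentage
#'
#' Share of informative pairs whose tumor call is homozygous, as an integer
#' percentage (rounded half away from zero, matching printed-table style).
#'
#' @param counts `loh_counts`.
#' @return Integer percentage, or `NA` when there are no informative pairs.
#' @export
loh_percent <- function(counts) {
  if (counts$n_informative == 0) return(NA_real_)
  round_half_up(100 * counts$n_loh / counts$n_informative)
}

#' Major-genotype-shift percentage
#'
#' Among LOH tumors, the share carrying the more frequently retained
#' homozygous genotype; 50% means both alleles were lost equally often,
#' 100% means every LOH event retained the same allele.
#'
#' @param counts `loh_counts`.
#' @return Integer percentage, or `NA` when no LOH events were observed.
#' @export
major_shift_percent <- function(counts) {
  if (counts$n_loh == 0) return(NA_real_)
  round_half_up(100 * max(counts$n_homo_a, counts$n_homo_b) / counts$n_loh)
}

#' Fraction of LOH tumors retaining the designated risk allele
#'
#' @param counts `loh_counts`.
#' @param snp one-row panel data frame (or list) with `allele_a`,
#'   `allele_b` and `risk_allele` for the marker.
#' @return Fraction in \[0, 1\], or `NA` when no LOH events were observed
#'   or no risk allele is designated.
#' @export
risk_retention <- function(counts, snp) {
  if (counts$n_loh == 0 || is.na(snp$risk_allele)) return(NA_real_)
  if (snp$risk_allele == snp$allele_a) {
    counts$n_homo_a / counts$n_loh
  } else if (snp$risk_allele == snp$allele_b) {
    counts$n_homo_b / counts$n_loh
  } else {
    stop("risk_allele does not match the SNP's allele pair")
  }
}

#' Test for allele-specific retention bias among LOH events
#'
#' Default `"binomial"` mode: exact two-sided binomial test of the split of
#' LOH events between the two homozygous outcomes against the symmetric
#' 0.5 expectation (no allele preferentially retained). The
#' `"pooled_fisher"` mode instead runs Fisher's exact test of this SNP's
#' (homozygous-A, homozygous-B) split against a reference split pooled
#' over other markers, asking whether this SNP's retention pattern deviates
#' from the panel-wide one.
#'
#' @param counts `loh_counts` for the SNP.
#' @param mode `"binomial"` (default) or `"pooled_fisher"`.
#' @param pooled_reference `loh_counts` holding the pooled reference split
#'   (required for `"pooled_fisher"`).
#' @return Two-sided p-value, or `NA` when no LOH events were observed.
#' @export
retention_test <- function(counts, mode = c("binomial", "pooled_fisher"),
                           pooled_reference = NULL) {
  mode <- match.arg(mode)
  if (counts$n_loh == 0) return(NA_real_)
  if (mode == "binomial") {
    stats::binom.test(counts$n_homo_a, counts$n_loh, p = 0.5)$p.value
  } else {
    if (is.null(pooled_reference)) {
      stop("pooled_fisher mode requires a pooled_reference")
    }
    tab <- matrix(c(counts$n_homo_a, counts$n_homo_b,
                    pooled_reference$n_homo_a, pooled_reference$n_homo_b),
                  nrow = 2, byrow = TRUE)
    stats::fisher.test(tab)$p.value
  }
}

#' Per-SNP LOH and allele-specific imbalance table
#'
#' Runs the whole somatic analysis over a paired cohort: for every panel
#' SNP, informative-pair selection, LOH calling, LOH and major-shift
#' percentages, risk-allele retention, the retention-bias test, and
#' Bonferroni adjustment of the retention p-values at family size
#' `m_tests`. SNPs with no informative pairs or no LOH events yield `NA`
#' in the undefined columns without aborting the batch.
#'
#' @param normals,tumors `genotype_matrix` objects for the same patients;
#'   they are paired by patient ID internally via [pair_samples()].
#' @param mode retention-test mode passed to [retention_test()]; in
#'   `"pooled_fisher"` mode each SNP is tested against the homozygous split
#'   pooled over all other panel SNPs.
#' @param m_tests Bonferroni family size (default: panel size).
#' @return Data frame with one row per SNP in panel order: `rsid`,
#'   `n_informative`, `n_homo_a`, `n_homo_b`, `n_het_retained`, `n_loh`,
#'   `loh_percent`, `major_shift_percent`, `risk_retention`, `p_retention`,
#'   `p_retention_bonferroni`.
#' @export
loh_table <- function(normals, tumors, mode = c("binomial", "pooled_fisher"),
                      m_tests = NULL) {
  mode <- match.arg(mode)
  paired <- pair_samples(normals, tumors)
  normals <- paired$normals
  tumors <- paired$tumors
  panel <- normals$panel
  if (nrow(panel) < 1) stop("panel must contain at least one SNP")
  if (is.null(m_tests)) m_tests <- nrow(panel)
  counts_list <- lapply(panel$rsid, function(rs) {
    call_loh(informative_pairs(normals, tumors, rs))
  })
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    cts <- counts_list[[i]]
    ref <- NULL
    if (mode == "pooled_fisher" && nrow(panel) > 1) {
      others <- counts_list[-i]
      ref <- loh_counts(sum(vapply(others, `[[`, 0, "n_homo_a")),
                        sum(vapply(others, `[[`, 0, "n_homo_b")), 0)
    }
    p_ret <- if (mode == "pooled_fisher" && is.null(ref)) NA_real_ else
      retention_test(cts, mode = mode, pooled_reference = ref)
    data.frame(rsid = panel$rsid[i], n_informative = cts$n_informative,
               n_homo_a = cts$n_homo_a, n_homo_b = cts$n_homo_b,
               n_het_retained = cts$n_het_retained, n_loh = cts$n_loh,
               loh_percent = loh_percent(cts),
               major_shift_percent = major_shift_percent(cts),
               risk_retention = risk_retention(cts, panel[i, ]),
               p_retention = p_ret, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_retention_bonferroni <- ifelse(
    is.na(res$p_retention), NA_real_,
    pmin(1, res$p_retention * m_tests))
  res
}
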