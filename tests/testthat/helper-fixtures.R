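# Small in-code fixtures shared across test files.

# Minimal n-SNP panel with distinct allele pairs and allele_b as the
# designated risk allele.
tiny_panel <- function(n = 3) {
  pairs <- list(c("C", "T"), c("A", "G"), c("G", "A"), c("T", "C"),
                c("A", "C"), c("G", "T"))
  pairs <- pairs[rep_len(seq_along(pairs), n)]
  data.frame(rsid = sprintf("rs%d", seq_len(n)),
             chrom = as.character(rep_len(1:22, n)),
             pos = seq_len(n) * 100L,
             allele_a = vapply(pairs, `[`, "", 1),
             allele_b = vapply(pairs, `[`, "", 2),
             risk_allele = vapply(pairs, `[`, "", 2),
             stringsAsFactors = FALSE)
}

# Build a genotype_matrix from a plain dosage matrix (rows = samples).
make_gm <- function(dosage, panel = tiny_panel(ncol(dosage)),
                    cohort = "control", ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(dosage)))
  rownames(dosage) <- ids
  genotype_matrix(dosage, panel, cohort)
}

# Random case/control pair over a shared panel, HWE at shared MAFs
# (null: no association).
random_null_cohorts <- function(n_case, n_control, n_snps, seed) {
  gm <- simulate_unlinked_panel(n_case + n_control, n_snps, seed = seed)
  case <- genotype_matrix(gm$dosage[seq_len(n_case), , drop = FALSE],
                          gm$panel, "case_normal")
  control <- genotype_matrix(
    gm$dosage[n_case + seq_len(n_control), , drop = FALSE],
    gm$panel, "control")
  list(case = case, control = control)
}

# Exact two-sided binomial p-value by brute-force enumeration of all 2^n
# equally likely allele-loss outcomes (independent oracle for the
# retention test; feasible for n <= 12).
enumerate_binom_p <- function(k, n) {
  counts <- vapply(0:(2^n - 1), function(x) {
    sum(bitwAnd(x, 2^(0:(n - 1))) > 0)
  }, numeric(1))
  d_obs <- dbinom(k, n, 0.5)
  extreme <- dbinom(counts, n, 0.5) <= d_obs * (1 + 1e-7)
  mean(extreme)
}
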