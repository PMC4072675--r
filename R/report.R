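# Study driver and table rendering: runs the full association +
# LOH/imbalance + stratification workflow from a plain-text configuration
# and writes TSV outputs whose rounding mirrors published replication
# tables (ORs to 3 decimals, p-values to 4 significant digits, percentages
# as integers).

#' Read a run configuration from a key = value text file
#'
#' Recognised keys: `panel`, `control`, `case_normal`, `case_tumor`
#' (input paths), `out_dir`, `adjust` (`bonferroni`, `permutation` or
#' `both`), `n_perm`, `seed`, `retention_mode` (`binomial` or
#' `pooled_fisher`), `m_tests`, and optional `unlinked_control` /
#' `unlinked_case` paths for a dedicated unlinked-marker panel used by the
#' stratification stage. Lines starting with `#` are comments.
#'
#' @param path configuration file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  cfg <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  run_config(
    panel = cfg$panel, control = cfg$control,
    case_normal = cfg$case_normal, case_tumor = cfg$case_tumor,
    out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
    adjust = if (is.null(cfg$adjust)) "both" else cfg$adjust,
    n_perm = if (is.null(cfg$n_perm)) 1000L else as.integer(cfg$n_perm),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    retention_mode = if (is.null(cfg$retention_mode)) "binomial" else
      cfg$retention_mode,
    m_tests = if (is.null(cfg$m_tests)) NULL else as.integer(cfg$m_tests),
    unlinked_panel = cfg$unlinked_panel,
    unlinked_control = cfg$unlinked_control,
    unlinked_case = cfg$unlinked_case)
}

#' Construct a run configuration
#'
#' @param panel,control,case_normal,case_tumor input file paths (panel TSV
#'   and genotype TSVs).
#' @param out_dir output directory (created if absent).
#' @param adjust p-value adjustment(s) to run: `"bonferroni"`,
#'   `"permutation"` or `"both"`.
#' @param n_perm permutations for the max-T adjustment.
#' @param seed integer seed recorded in every output header.
#' @param retention_mode retention-test mode for [loh_table()].
#' @param m_tests Bonferroni family size (default: panel size).
#' @param unlinked_panel,unlinked_control,unlinked_case optional panel and
#'   genotype TSV paths for a dedicated unlinked-marker panel; when given,
#'   PCA and the inflation factor are computed from these markers instead
#'   of the analysis panel.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(panel, control, case_normal, case_tumor,
                       out_dir = ".", adjust = c("both", "bonferroni",
                                                 "permutation"),
                       n_perm = 1000L, seed = 1L,
                       retention_mode = "binomial", m_tests = NULL,
                       unlinked_panel = NULL, unlinked_control = NULL,
                       unlinked_case = NULL) {
  adjust <- match.arg(adjust)
  cfg <- list(panel = panel, control = control, case_normal = case_normal,
              case_tumor = case_tumor, out_dir = out_dir, adjust = adjust,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              retention_mode = retention_mode, m_tests = m_tests,
              unlinked_panel = unlinked_panel,
              unlinked_control = unlinked_control,
              unlinked_case = unlinked_case)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  # fingerprint of the analysis-relevant settings; out_dir deliberately
  # excluded so the same analysis hashes identically wherever it is written
  config <- config[setdiff(names(config), "out_dir")]
  flat <- vapply(config[!vapply(config, is.null, TRUE)],
                 function(x) paste(x, collapse = ","), "")
  fnv1a32(paste(names(flat), flat, sep = "=", collapse = ";"))
}

sig4 <- function(p) ifelse(is.na(p), NA, signif(p, 4))

header_lines <- function(config, extra = character()) {
  c(sprintf("# seed=%d config_hash=%s", config$seed, config_hash(config)),
    extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Render an association result table to TSV
#'
#' Columns mirror a published replication table: MAFs to 3 decimals, ORs
#' to 3 decimals with the 95% interval as a `low-high` string, p-values to
#' 4 significant digits.
#'
#' @param res data frame from [associate()].
#' @param panel panel the results refer to (for chrom/pos columns).
#' @param path output path.
#' @param header character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
render_assoc_table <- function(res, panel, path, header = character()) {
  i <- match(res$rsid, panel$rsid)
  out <- data.frame(
    rsid = res$rsid, chrom = panel$chrom[i], pos = panel$pos[i],
    minor_allele = res$minor_allele,
    maf_case = sprintf("%.3f", res$maf_case),
    maf_control = sprintf("%.3f", res$maf_control),
    p_allele = sig4(res$p_allele),
    p_bonferroni = sig4(res$p_bonferroni),
    stringsAsFactors = FALSE)
  if ("p_permutation" %in% names(res)) {
    out$p_permutation <- sig4(res$p_permutation)
  }
  out$or_value <- sprintf("%.3f", res$or_value)
  out$ci_95 <- sprintf("%.3f-%.3f", res$ci_low, res$ci_high)
  out$p_hwe_controls <- sig4(res$p_hwe_controls)
  out$p_genotype <- sig4(res$p_genotype)
  write_tsv_with_header(out, path, header)
}

#' Render an LOH result table to TSV
#'
#' Counts as integers, LOH and major-shift percentages as integer
#' percentages (`10%`, `87%`), retention fractions to 3 decimals,
#' p-values to 4 significant digits.
#'
#' @param res data frame from [loh_table()].
#' @param panel panel the results refer to.
#' @param path output path.
#' @param header character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
render_loh_table <- function(res, panel, path, header = character()) {
  i <- match(res$rsid, panel$rsid)
  pct <- function(x) ifelse(is.na(x), "NA", sprintf("%d%%", as.integer(x)))
  out <- data.frame(
    rsid = res$rsid, chrom = panel$chrom[i], pos = panel$pos[i],
    n_informative = res$n_informative, n_homo_a = res$n_homo_a,
    n_homo_b = res$n_homo_b, n_loh = res$n_loh,
    loh_percent = pct(res$loh_percent),
    major_shift_percent = pct(res$major_shift_percent),
    risk_retention = ifelse(is.na(res$risk_retention), "NA",
                            sprintf("%.3f", res$risk_retention)),
    p_retention = sig4(res$p_retention),
    p_retention_bonferroni = sig4(res$p_retention_bonferroni),
    stringsAsFactors = FALSE)
  write_tsv_with_header(out, path, header)
}

#' Run the full synthetic-study workflow
#'
#' Validates every input path, then runs the three analysis stages in
#' fixed order -- case-control association (with the configured p-value
#' adjustments), paired-tumor LOH/allelic-imbalance analysis, and
#' stratification diagnostics (genotype PCA over all samples plus the
#' genomic inflation factor of the allelic test statistics) -- and writes
#' five outputs to `out_dir`: `association.tsv`, `loh.tsv`,
#' `loh_summary.tsv` (the per-SNP LOH-percent / retention summary),
#' `pca_scores.tsv` and `run_log.txt`. Every output header carries the
#' seed and a configuration hash, so identical configurations produce
#' identical result content. If a stage fails, a `run_failed.txt` marker
#' is written before the error propagates, so partial output directories
#' are always recognisable.
#'
#' @param config a `run_config` (or path to a config file).
#' @return Invisibly, a list with `association`, `loh`, `pca`, `lambda`
#'   and the output file paths.
#' @export
run_full_study <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  inputs <- c(config$panel, config$control, config$case_normal,
              config$case_tumor, config$unlinked_panel,
              config$unlinked_control, config$unlinked_case)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0) {
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  marker <- file.path(config$out_dir, "run_failed.txt")
  ok <- FALSE
  on.exit(if (!ok) writeLines("run failed before completing all stages",
                              marker))

  panel <- read_panel(config$panel)
  control <- read_genotype_matrix(config$control, panel, "control")
  case_normal <- read_genotype_matrix(config$case_normal, panel,
                                      "case_normal")
  case_tumor <- read_genotype_matrix(config$case_tumor, panel,
                                     "case_tumor")

  n_perm <- if (config$adjust %in% c("permutation", "both"))
    config$n_perm else 0L
  assoc <- associate(case_normal, control, n_perm = n_perm,
                     seed = config$seed, m_tests = config$m_tests)
  if (config$adjust == "permutation") assoc$p_bonferroni <- NULL

  loh <- loh_table(case_normal, case_tumor, mode = config$retention_mode,
                   m_tests = config$m_tests)

  # stratification: dedicated unlinked markers when supplied, else the
  # analysis panel itself
  if (!is.null(config$unlinked_control)) {
    if (is.null(config$unlinked_panel)) {
      stop("unlinked_control requires an unlinked_panel path")
    }
    upanel <- read_panel(config$unlinked_panel)
    strat_control <- read_genotype_matrix(config$unlinked_control, upanel,
                                          "control")
    strat_case <- read_genotype_matrix(config$unlinked_case, upanel,
                                       "case_normal")
  } else {
    strat_control <- control
    strat_case <- case_normal
  }
  combined <- genotype_matrix(
    rbind(strat_case$dosage, strat_control$dosage), strat_control$panel,
    c(strat_case$cohort, strat_control$cohort))
  pca <- pca_genotypes(combined, n_components = 2)
  strat_assoc <- associate(strat_case, strat_control, n_perm = 0)
  lambda <- inflation_lambda(strat_assoc$chi2_allele)

  hdr <- header_lines(config)
  paths <- list(
    association = file.path(config$out_dir, "association.tsv"),
    loh = file.path(config$out_dir, "loh.tsv"),
    loh_summary = file.path(config$out_dir, "loh_summary.tsv"),
    pca_scores = file.path(config$out_dir, "pca_scores.tsv"),
    run_log = file.path(config$out_dir, "run_log.txt"))
  render_assoc_table(assoc, panel, paths$association, hdr)
  render_loh_table(loh, panel, paths$loh, hdr)
  write_tsv_with_header(
    data.frame(rsid = loh$rsid, loh_percent = loh$loh_percent,
               risk_retention = signif(loh$risk_retention, 4),
               p_retention = sig4(loh$p_retention)),
    paths$loh_summary, hdr)
  scores <- data.frame(sample_id = rownames(pca$scores),
                       cohort = combined$cohort,
                       PC1 = signif(pca$scores[, 1], 6),
                       PC2 = signif(pca$scores[, 2], 6))
  write_tsv_with_header(scores, paths$pca_scores, hdr)

  log_lines <- c(
    hdr,
    paste0("timestamp=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    paste0("lohassoc_version=",
           as.character(utils::packageVersion("lohassoc"))),
    paste0("n_snps=", nrow(panel)),
    paste0("n_case=", nrow(case_normal$dosage)),
    paste0("n_control=", nrow(control$dosage)),
    paste0("n_tumor=", nrow(case_tumor$dosage)),
    paste0("adjust=", config$adjust),
    paste0("n_perm=", n_perm),
    paste0("retention_mode=", config$retention_mode),
    paste0("inflation_lambda=", sprintf("%.3f", lambda)),
    paste0("pc1_explained=", sprintf("%.4f", pca$explained_variance[1])))
  writeLines(log_lines, paths$run_log)

  ok <- TRUE
  if (file.exists(marker)) file.remove(marker)
  invisible(list(association = assoc, loh = loh, pca = pca,
                 lambda = lambda, paths = paths))
}
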