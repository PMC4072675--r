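# Genotype and SNP-panel I/O.
#
# Genotypes are stored as allele-B dosages: the integer number of copies of
# the panel's allele_b carried by a sample at a SNP (0, 1 or 2), with NA for
# a missing (no-call) genotype. Panel alleles are taken as reported; no
# strand flipping or ambiguous-SNP (A/T, C/G) resolution is attempted --
# resolving strand is the caller's responsibility.

NUCLEOTIDES <- c("A", "C", "G", "T")
COHORTS <- c("case_normal", "case_tumor", "control")

#' Validate a SNP panel table
#'
#' A panel is a data frame with one row per marker and columns `rsid`,
#' `chrom`, `pos` (1-based physical position in bp), `allele_a`, `allele_b`
#' (distinct single-nucleotide symbols) and `risk_allele` (one of the two
#' alleles, or `NA` when no risk allele has been designated). Extra columns
#' (e.g. generative parameters added by [default_panel()]) are allowed and
#' preserved.
#'
#' @param panel data frame to validate.
#' @return The panel, invisibly, after validation.
#' @export
validate_panel <- function(panel) {
  required <- c("rsid", "chrom", "pos", "allele_a", "allele_b", "risk_allele")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$rsid)) {
    dup <- unique(panel$rsid[duplicated(panel$rsid)])
    stop("duplicate rsid(s) in panel: ", paste(dup, collapse = ", "))
  }
  bad_allele <- !(panel$allele_a %in% NUCLEOTIDES) |
    !(panel$allele_b %in% NUCLEOTIDES)
  if (any(bad_allele)) {
    stop("alleles must be single nucleotides A/C/G/T; offending rsid(s): ",
         paste(panel$rsid[bad_allele], collapse = ", "))
  }
  same <- panel$allele_a == panel$allele_b
  if (any(same)) {
    stop("allele_a equals allele_b for rsid(s): ",
         paste(panel$rsid[same], collapse = ", "))
  }
  risk_known <- !is.na(panel$risk_allele)
  bad_risk <- risk_known &
    panel$risk_allele != panel$allele_a & panel$risk_allele != panel$allele_b
  if (any(bad_risk)) {
    stop("risk_allele must be allele_a or allele_b; offending rsid(s): ",
         paste(panel$rsid[bad_risk], collapse = ", "))
  }
  if (any(is.na(panel$pos)) || any(panel$pos < 1)) {
    stop("pos must be a positive 1-based coordinate")
  }
  invisible(panel)
}

#' Read a SNP panel from a tab-separated file
#'
#' Expects a header line `rsid chrom pos allele_a allele_b risk_allele`
#' (tab-separated) followed by one row per marker. `risk_allele` may be
#' `.` or `unknown` for markers with no designated risk allele.
#'
#' @param path path to the panel TSV.
#' @return A validated panel data frame in file order.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("panel file is empty: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  expected <- c("rsid", "chrom", "pos", "allele_a", "allele_b", "risk_allele")
  if (!identical(header, expected)) {
    stop("panel header must be: ", paste(expected, collapse = " "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    panel <- data.frame(rsid = character(), chrom = character(),
                        pos = integer(), allele_a = character(),
                        allele_b = character(), risk_allele = character(),
                        stringsAsFactors = FALSE)
    return(validate_panel(panel))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 6L)) {
    bad <- which(n_fields != 6L)[1]
    stop("parse error at line ", bad + 1L, ": expected 6 tab-separated ",
         "fields, found ", n_fields[bad])
  }
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 3]))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1]
    stop("parse error at line ", bad + 1L, ": position '", m[bad, 3],
         "' is not an integer")
  }
  risk <- m[, 6]
  risk[risk %in% c(".", "unknown", "NA", "")] <- NA_character_
  panel <- data.frame(rsid = m[, 1], chrom = m[, 2], pos = pos,
                      allele_a = m[, 4], allele_b = m[, 5],
                      risk_allele = risk, stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Write a SNP panel to a tab-separated file
#'
#' @param panel validated panel data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- panel[, c("rsid", "chrom", "pos", "allele_a", "allele_b",
                   "risk_allele")]
  out$risk_allele[is.na(out$risk_allele)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a genotype matrix
#'
#' The central container: an integer matrix of allele-B dosages (samples in
#' rows, SNPs in columns, `NA` = missing call) together with its SNP panel
#' and a per-sample cohort label (`case_normal`, `case_tumor` or `control`).
#' Sample identifiers double as patient identifiers: a `case_tumor` sample
#' pairs with the `case_normal` sample of the same identifier.
#'
#' @param dosage integer matrix of 0/1/2/NA allele-B dosages with sample IDs
#'   as row names; columns must align with `panel` rows.
#' @param panel SNP panel data frame (see [validate_panel()]).
#' @param cohort single cohort label, or one label per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, panel, cohort) {
  validate_panel(panel)
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(panel)) {
    stop("dosage has ", ncol(dosage), " columns but panel has ",
         nrow(panel), " SNPs")
  }
  if (is.null(rownames(dosage))) {
    if (nrow(dosage) > 0) stop("dosage must have sample IDs as row names")
    rownames(dosage) <- character(0)
  }
  if (anyDuplicated(rownames(dosage))) {
    stop("duplicate sample ID(s): ",
         paste(unique(rownames(dosage)[duplicated(rownames(dosage))]),
               collapse = ", "))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0 && !all(vals %in% c(0L, 1L, 2L))) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- panel$rsid
  if (length(cohort) == 1) cohort <- rep(cohort, nrow(dosage))
  if (length(cohort) != nrow(dosage)) {
    stop("cohort must be length 1 or one label per sample")
  }
  if (!all(cohort %in% COHORTS)) {
    stop("cohort labels must be in: ", paste(COHORTS, collapse = ", "))
  }
  structure(list(dosage = dosage, panel = panel, cohort = cohort),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs\n")
  cat("cohorts:", paste(sprintf("%s (%d)", names(table(x$cohort)),
                                table(x$cohort)), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Convert one column of dosages to allele-pair genotype tokens.
dosage_to_token <- function(d, a, b) {
  out <- rep("NN", length(d))
  out[!is.na(d) & d == 0L] <- paste0(a, a)
  out[!is.na(d) & d == 1L] <- paste0(a, b)
  out[!is.na(d) & d == 2L] <- paste0(b, b)
  out
}

#' Write a genotype matrix as a genotype TSV
#'
#' One row per sample: the sample ID followed by one genotype token per
#' panel SNP, written as allele pairs (e.g. `CC`, `CT`, `TT`) with `NN` for
#' missing calls.
#'
#' @param mat a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  tok <- vapply(seq_len(ncol(mat$dosage)), function(j) {
    dosage_to_token(mat$dosage[, j], mat$panel$allele_a[j],
                    mat$panel$allele_b[j])
  }, character(nrow(mat$dosage)))
  tok <- matrix(tok, nrow = nrow(mat$dosage))
  out <- cbind(sample_id = rownames(mat$dosage), tok)
  colnames(out) <- c("sample_id", mat$panel$rsid)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Parse one genotype token at one SNP. Literal allele-pair interpretation
# takes precedence; generic AA/AB/BB codes are accepted when the token is
# not a valid allele pair for the SNP (relevant only when "A" or "B" is
# itself one of the SNP's alleles, where the literal reading wins).
parse_token <- function(token, a, b, rsid, line) {
  if (token %in% c("NN", "--")) return(NA_integer_)
  chars <- strsplit(token, "")[[1]]
  if (length(chars) != 2) {
    stop("parse error at line ", line, " (", rsid, "): genotype token '",
         token, "' is not two characters")
  }
  if (all(chars %in% c(a, b))) {
    return(sum(chars == b))
  }
  generic <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)
  if (token %in% names(generic)) return(generic[[token]])
  stop("validation error at line ", line, " (", rsid, "): token '", token,
       "' contains an allele not in the panel pair ", a, "/", b)
}

#' Read a genotype TSV into a genotype matrix
#'
#' Accepts allele-pair tokens (order-insensitive, validated against the
#' panel's allele pair) or generic `AA`/`AB`/`BB` codes; `NN` or `--` mark
#' missing calls.
#'
#' @param path path to a genotype TSV written in the layout of
#'   [write_genotype_matrix()].
#' @param panel SNP panel the columns correspond to.
#' @param cohort cohort label to attach to every sample.
#' @return A `genotype_matrix`.
#' @export
read_genotype_matrix <- function(path, panel, cohort) {
  validate_panel(panel)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("genotype file is empty: ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  m <- nrow(panel)
  n <- length(body)
  dosage <- matrix(NA_integer_, nrow = n, ncol = m)
  ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != m + 1L) {
      stop("parse error at line ", i + 1L, ": expected ", m + 1L,
           " columns, found ", length(fields))
    }
    ids[i] <- fields[1]
    for (j in seq_len(m)) {
      dosage[i, j] <- parse_token(fields[j + 1L], panel$allele_a[j],
                                  panel$allele_b[j], panel$rsid[j], i + 1L)
    }
  }
  rownames(dosage) <- ids
  genotype_matrix(dosage, panel, cohort)
}

#' Write a minimal VCF from a genotype matrix
#'
#' Emits a sites-by-samples VCF v4.2 with only the GT field, using the
#' panel's `allele_a` as REF and `allele_b` as ALT.
#'
#' @param mat a `genotype_matrix`.
#' @param path output path (plain text, not bgzipped).
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(mat, path) {
  stopifnot(inherits(mat, "genotype_matrix"))
  p <- mat$panel
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(mat$dosage)),
                     collapse = "\t")), con)
  for (j in seq_len(nrow(p))) {
    d <- mat$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(p$chrom[j], p$pos[j], p$rsid[j], p$allele_a[j],
                       p$allele_b[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Ingests only diallelic records whose ID matches a panel rsid (or, failing
#' that, whose chrom+pos matches a panel site). Genotypes are read from the
#' GT field; phase separators are ignored and `./.` becomes a missing call.
#' Records with multi-allelic ALT, or with an allele pair that does not
#' match the panel's, are skipped with a warning. Panel SNPs absent from
#' the file come back all-missing.
#'
#' @param path path to a VCF v4.x file.
#' @param panel SNP panel to ingest against.
#' @param cohort cohort label for all samples.
#' @return A `genotype_matrix`.
#' @export
read_vcf_minimal <- function(path, panel, cohort) {
  validate_panel(panel)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(panel),
                   dimnames = list(samples, panel$rsid))
  key_panel <- paste(panel$chrom, panel$pos)
  for (k in seq_len(nrow(fix))) {
    j <- match(fix$ID[k], panel$rsid)
    if (is.na(j)) j <- match(paste(fix$CHROM[k], fix$POS[k]), key_panel)
    if (is.na(j)) next
    if (grepl(",", fix$ALT[k], fixed = TRUE)) {
      warning("skipping multi-allelic record at panel site ",
              panel$rsid[j])
      next
    }
    ref <- fix$REF[k]; alt <- fix$ALT[k]
    a <- panel$allele_a[j]; b <- panel$allele_b[j]
    if (ref == a && alt == b) {
      flip <- FALSE
    } else if (ref == b && alt == a) {
      flip <- TRUE
    } else {
      warning("skipping record with allele pair ", ref, "/", alt,
              " not matching panel ", a, "/", b, " at ", panel$rsid[j])
      next
    }
    g <- gt[k, ]
    alt_count <- vapply(g, function(x) {
      if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_integer_)
      alleles <- strsplit(x, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles == "1")
    }, integer(1))
    dosage[, j] <- if (flip) 2L - alt_count else alt_count
  }
  genotype_matrix(dosage, panel, cohort)
}

#' Pair tumor samples with their germline (adjacent-normal) samples
#'
#' Matches samples across the two matrices by shared patient identifier.
#' Unpaired samples on either side are reported in a warning and excluded.
#'
#' @param normals `genotype_matrix` of germline (adjacent-normal) samples.
#' @param tumors `genotype_matrix` of tumor samples from the same patients.
#' @return A list with `normals` and `tumors` subset to the shared patients
#'   in identical (sorted) order, and `patient_id`, the shared identifiers.
#' @export
pair_samples <- function(normals, tumors) {
  stopifnot(inherits(normals, "genotype_matrix"),
            inherits(tumors, "genotype_matrix"))
  if (!identical(normals$panel$rsid, tumors$panel$rsid)) {
    stop("normal and tumor matrices must share the same SNP panel")
  }
  ids_n <- rownames(normals$dosage)
  ids_t <- rownames(tumors$dosage)
  shared <- sort(intersect(ids_n, ids_t))
  only_n <- setdiff(ids_n, ids_t)
  only_t <- setdiff(ids_t, ids_n)
  if (length(only_n) > 0 || length(only_t) > 0) {
    warning(length(only_n), " normal and ", length(only_t),
            " tumor sample(s) unpaired and excluded",
            if (length(shared) == 0) " (no shared patient IDs)" else "")
  }
  sub <- function(mat, ids) {
    genotype_matrix(mat$dosage[ids, , drop = FALSE], mat$panel,
                    mat$cohort[match(ids, rownames(mat$dosage))])
  }
  list(normals = sub(normals, shared), tumors = sub(tumors, shared),
       patient_id = shared)
}

#' Swap the allele labels of panel SNPs
#'
#' Relabels `allele_a` as `allele_b` (and vice versa) for the given SNPs and
#' recodes their dosages d -> 2 - d. Risk-allele designations keep their
#' nucleotide symbol. Mainly useful for symmetry checks.
#'
#' @param mat a `genotype_matrix`.
#' @param rsids SNPs to swap (default: all).
#' @return The relabelled `genotype_matrix`.
#' @export
swap_allele_labels <- function(mat, rsids = mat$panel$rsid) {
  stopifnot(inherits(mat, "genotype_matrix"))
  j <- match(rsids, mat$panel$rsid)
  if (any(is.na(j))) stop("unknown rsid(s): ",
                          paste(rsids[is.na(j)], collapse = ", "))
  panel <- mat$panel
  tmp <- panel$allele_a[j]
  panel$allele_a[j] <- panel$allele_b[j]
  panel$allele_b[j] <- tmp
  dosage <- mat$dosage
  dosage[, j] <- 2L - dosage[, j]
  genotype_matrix(dosage, panel, mat$cohort)
}
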