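# Population-stratification diagnostics: genotype PCA on unlinked markers
# and the genomic inflation factor.

# Median of the 1-df chi-square distribution, the genomic-control
# denominator. Fixed, not configurable.
CHISQ1_MEDIAN <- 0.4549364

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per SNP, each SNP column is centered
#' and scaled to unit variance (zero-variance columns are dropped), and the
#' principal components of the standardized matrix are extracted. Component
#' signs are fixed by forcing each component's largest-magnitude loading
#' positive, so output is deterministic.
#'
#' @param mat a `genotype_matrix`; typically a panel of unlinked markers
#'   genotyped across all cohorts.
#' @param n_components number of components to return.
#' @return List of class `pca_genotypes`: `scores` (samples x components,
#'   zero mean per component), `loadings`, `explained_variance`
#'   (per-component fraction of total variance, non-increasing),
#'   `n_components`, and `dropped` (rsids of zero-variance columns).
#' @export
pca_genotypes <- function(mat, n_components = 2) {
  stopifnot(inherits(mat, "genotype_matrix"))
  X <- mat$dosage
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (all(miss)) next
    X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2, stats::var)
  keep <- !is.na(v) & v > 0
  if (sum(keep) < 2) stop("no informative markers")
  dropped <- colnames(X)[!keep]
  X <- scale(X[, keep, drop = FALSE])
  n_components <- min(n_components, ncol(X), nrow(X) - 1)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- rownames(mat$dosage)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(n_components)],
                 n_components = n_components, dropped = dropped),
            class = "pca_genotypes")
}

#' Genomic inflation factor
#'
#' lambda = median of the observed 1-df association chi-square statistics
#' divided by the 1-df chi-square median (0.4549364). Values near 1
#' indicate no systematic inflation from population stratification.
#'
#' @param chi2_values non-negative 1-df chi-square statistics; at least 10
#'   are expected for a stable median (fewer give a warning).
#' @return lambda, rounded to 3 decimals (reporting precision).
#' @export
inflation_lambda <- function(chi2_values) {
  if (length(chi2_values) == 0) stop("no chi-square statistics supplied")
  if (any(is.na(chi2_values)) || any(chi2_values < 0)) {
    stop("chi-square statistics must be non-negative and non-missing")
  }
  if (length(chi2_values) < 10) {
    warning("fewer than 10 statistics; lambda estimate is unstable")
  }
  round(stats::median(chi2_values) / CHISQ1_MEDIAN, 3)
}
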