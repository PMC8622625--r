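# Exploratory structure analyses: PCA of the normalized corresponded-peak
# matrix, presence/absence co-occurrence, within-category sample
# subgrouping, and the 2x2 chi-squared contingency test used for the
# statin association check.

#' Principal component analysis of the sample intensity profiles
#'
#' Missing entries are replaced by the feature's mean observed value,
#' features are centered, and the scores are obtained from the singular
#' value decomposition of the samples-by-features matrix. Variance
#' explained is the squared singular value over the total variance.
#'
#' @param mat Numeric matrix, features x samples, `NA` = missing.
#' @param n_components Number of components to return.
#' @return List of class `"pca_result"` with `scores` (samples x
#'   components), `loadings` (features x components) and `var_explained`.
#' @export
pca_scores <- function(mat, n_components = 3L) {
  if (ncol(mat) < 2L) stop("need at least two samples")
  fm <- rowMeans(mat, na.rm = TRUE)
  fm[is.nan(fm)] <- 0
  filled <- mat
  for (i in seq_len(nrow(mat))) {
    miss <- is.na(filled[i, ])
    if (any(miss)) filled[i, miss] <- fm[i]
  }
  x <- t(filled)                      # samples x features
  x <- sweep(x, 2L, colMeans(x))
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(n_components)))
  loadings <- sv$v
  dimnames(loadings) <- list(rownames(mat), paste0("PC", seq_len(n_components)))
  total <- sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 var_explained = sv$d[seq_len(n_components)]^2 / total),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,",
      paste0(sprintf("PC%d %.1f%%", seq_along(x$var_explained),
                     100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Feature co-occurrence (Jaccard) matrix
#'
#' For features i and j: the number of samples in which both are observed
#' over the number of samples in which either is observed. The diagonal is
#' 1 for ever-observed features and `NaN` for never-observed ones.
#'
#' @param mat Numeric matrix, features x samples, `NA` = missing.
#' @return Symmetric features x features matrix in [0, 1].
#' @export
cooccurrence_matrix <- function(mat) {
  p <- !is.na(mat) * 1
  both <- p %*% t(p)
  n_obs <- rowSums(p)
  either <- outer(n_obs, n_obs, "+") - both
  out <- both / either            # 0/0 -> NaN for never-observed pairs
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

#' Partition samples by clustering on one lipid category
#'
#' Restricts the matrix to the features of one category, computes the
#' missing-aware Kendall-tau sample correlation, converts it to a
#' `1 - tau` distance, clusters hierarchically and cuts at `k` groups.
#'
#' @param mat Numeric matrix restricted to the category's features
#'   (features x samples, `NA` = missing); at least 2 features.
#' @param k Number of groups.
#' @param linkage Agglomeration method.
#' @return Named integer vector of cluster memberships.
#' @export
subgroup_samples <- function(mat, k = 2L, linkage = "average") {
  if (nrow(mat) < 2L) stop("need at least 2 features in the category")
  cm <- correlation_matrix(mat, axis = "samples")
  d <- 1 - cm
  d[!is.finite(d)] <- 1
  diag(d) <- 0
  if (all(abs(d[upper.tri(d)]) < 1e-12)) {
    warning("degenerate distance; returning a single cluster")
    return(stats::setNames(rep(1L, ncol(mat)), colnames(mat)))
  }
  cl <- cluster_samples(d, linkage = linkage)
  stats::cutree(cl$hclust, k = k)
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' Pearson statistic without continuity correction, one degree of
#' freedom.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_squared_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
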