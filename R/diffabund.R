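# Differential abundance between cancer and non-cancer samples, analyzed
# unpaired. Two complementary per-feature tests are combined by union:
# an empirical-Bayes moderated linear model with an instrument covariate
# (on imputed log2 data) and a two-part zero-inflated statistic that uses
# the missingness pattern itself as signal (on unimputed data).

#' Fit the moderated linear model (disease + instrument)
#'
#' Per-feature ordinary least squares on `~ class + instrument`, followed
#' by empirical-Bayes shrinkage of the residual variances toward a common
#' prior (scaled inverse chi-square, moment-matched on the log variances),
#' as in the limma moderated t-statistic. The reported effect is the
#' cancer minus non-cancer contrast in log2 units; instrument enters only
#' as a covariate.
#'
#' @param mat Imputed log2 intensity matrix (features x samples, no `NA`).
#' @param classes Per-sample disease labels (`"cancer"`/`"non-cancer"`).
#' @param instrument Optional per-sample instrument labels; omitted from
#'   the design when `NULL` or single-valued.
#' @return Data frame per feature: `feature_id`, `effect`, `t`,
#'   `p_value`, `t_ordinary`, `df_residual`, `df_prior`.
#' @export
fit_moderated_linear_model <- function(mat, classes, instrument = NULL) {
  stopifnot(length(classes) == ncol(mat))
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  cls <- factor(classes, levels = c("non-cancer", "cancer"))
  if (any(is.na(cls))) stop("unknown class label")
  if (any(table(cls) < 2L)) stop("fewer than 2 samples in a class")
  design <- cbind(Intercept = 1, cancer = as.integer(cls == "cancer"))
  if (!is.null(instrument) && length(unique(instrument)) > 1L) {
    ins <- factor(instrument)
    design <- cbind(design,
                    stats::model.matrix(~ins)[, -1, drop = FALSE])
  }
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank-deficient")
  if (ncol(mat) < ncol(design) + 1L) stop("too few samples for the design")
  fit <- limma::lmFit(mat, design)
  eb <- limma::eBayes(fit)
  ord_t <- fit$coefficients[, "cancer"] /
    (fit$sigma * fit$stdev.unscaled[, "cancer"])
  data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    effect = unname(fit$coefficients[, "cancer"]),
    t = unname(eb$t[, "cancer"]),
    p_value = unname(eb$p.value[, "cancer"]),
    t_ordinary = unname(ord_t),
    df_residual = unname(fit$df.residual),
    df_prior = rep(unname(eb$df.prior)[1], nrow(mat)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-part zero-inflated test for one feature
#'
#' Combines a presence/absence component and an abundance component into a
#' chi-square statistic (Lachenbruch-style): the binary part is the
#' two-proportion score statistic `z_B` on detection rates between classes
#' (degenerate, and dropped, when pooled presence is 0% or 100%); the
#' continuous part is the tie-corrected normal approximation `z_C` of the
#' Wilcoxon rank-sum test on observed values only (dropped when either
#' class has fewer than 2 observed values). `X^2 = z_B^2 + z_C^2` with df =
#' number of non-degenerate parts; p = 1 when both parts are degenerate.
#' Operates on pre-imputation data: the missingness is the signal of the
#' binary part.
#'
#' @param x,y Numeric vectors for the two classes, `NA` = not detected.
#' @return Named numeric `c(statistic, df, p_value)`.
#' @export
two_part_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per class")
  o1 <- x[!is.na(x)]; o2 <- y[!is.na(y)]
  k1 <- length(o1); k2 <- length(o2)
  zB <- 0; dfB <- 0L
  pbar <- (k1 + k2) / (n1 + n2)
  if (pbar > 0 && pbar < 1) {
    zB <- (k1 / n1 - k2 / n2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    dfB <- 1L
  }
  zC <- 0; dfC <- 0L
  if (k1 >= 2L && k2 >= 2L) {
    r <- rank(c(o1, o2))
    W <- sum(r[seq_len(k1)])
    mu <- k1 * (k1 + k2 + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((k1 + k2) * (k1 + k2 - 1))
    v <- k1 * k2 / 12 * (k1 + k2 + 1 - tie_term)
    if (v > 0) {
      zC <- (W - mu) / sqrt(v)
      dfC <- 1L
    }
  }
  df <- dfB + dfC
  stat <- zB^2 + zC^2
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  c(statistic = stat, df = df, p_value = p)
}

#' Two-part test over every feature of a matrix
#'
#' @param mat Unimputed log2 (or normalized) matrix, features x samples,
#'   `NA` = not detected.
#' @param classes Per-sample disease labels.
#' @return Data frame per feature: `feature_id`, `statistic`, `df`,
#'   `p_value`.
#' @export
two_part_test_all <- function(mat, classes) {
  stopifnot(length(classes) == ncol(mat))
  ix <- classes == "cancer"
  res <- t(apply(mat, 1L, function(v) two_part_test(v[ix], v[!ix])))
  data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    statistic = res[, "statistic"], df = as.integer(res[, "df"]),
    p_value = res[, "p_value"], stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")` after validating the inputs).
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Union of significant features from both tests
#'
#' A feature is called significant when its BH-adjusted p-value is at most
#' `alpha` in either the moderated linear model or the two-part test;
#' provenance records which test(s) called it.
#'
#' @param moderated Output of [fit_moderated_linear_model()].
#' @param two_part Output of [two_part_test_all()] on the same features.
#' @param alpha Adjusted-p cutoff.
#' @return Data frame per feature with adjusted p-values per test,
#'   significance flags, union flag and `provenance` in
#'   `c("both", "moderated", "two-part", "none")`.
#' @export
differential_features <- function(moderated, two_part, alpha = 0.01) {
  if (!setequal(moderated$feature_id, two_part$feature_id) ||
      nrow(moderated) != nrow(two_part)) {
    stop("feature universes differ between the two tests")
  }
  two_part <- two_part[match(moderated$feature_id, two_part$feature_id), ]
  out <- data.frame(
    feature_id = moderated$feature_id,
    effect = moderated$effect,
    p_moderated = moderated$p_value,
    p_two_part = two_part$p_value,
    adj_p_moderated = bh_adjust(moderated$p_value),
    adj_p_two_part = bh_adjust(two_part$p_value),
    stringsAsFactors = FALSE
  )
  out$sig_moderated <- out$adj_p_moderated <= alpha
  out$sig_two_part <- out$adj_p_two_part <= alpha
  out$significant <- out$sig_moderated | out$sig_two_part
  out$provenance <- ifelse(out$sig_moderated & out$sig_two_part, "both",
                    ifelse(out$sig_moderated, "moderated",
                    ifelse(out$sig_two_part, "two-part", "none")))
  out
}

#' Per-feature log2 fold changes (cancer minus non-cancer)
#'
#' Mean over cancer samples minus mean over non-cancer samples on the
#' imputed log2 matrix. Features observed in only one class inherit the
#' extreme fold changes induced by imputation at the censoring bound.
#'
#' @param mat Imputed log2 matrix (no `NA`).
#' @param classes Per-sample disease labels.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_changes <- function(mat, classes) {
  stopifnot(length(classes) == ncol(mat))
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  rowMeans(mat[, classes == "cancer", drop = FALSE]) -
    rowMeans(mat[, classes != "cancer", drop = FALSE])
}

#' Hierarchical clustering of samples on a 1 - tau distance
#'
#' Agglomerative clustering (average linkage by default) on a symmetric
#' distance matrix, typically one minus the missing-aware Kendall-tau
#' correlation. Dendrogram leaves are reordered smallest-first: at every
#' merge node the subtree with the smaller total within-subtree pairwise
#' distance is placed first, recursively.
#'
#' @param dist_mat Square symmetric matrix with zero diagonal.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust`, the reordered `dendrogram`, and `order`
#'   (leaf labels in display order).
#' @export
cluster_samples <- function(dist_mat, linkage = "average") {
  if (!isSymmetric(unname(dist_mat), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(dist_mat)) > 1e-8)) stop("distance diagonal must be zero")
  if (is.null(rownames(dist_mat))) {
    rownames(dist_mat) <- colnames(dist_mat) <- as.character(seq_len(nrow(dist_mat)))
  }
  hc <- stats::hclust(stats::as.dist(dist_mat), method = linkage)
  dnd <- .sort_smallest_first(stats::as.dendrogram(hc), dist_mat)
  list(hclust = hc, dendrogram = dnd, order = labels(dnd))
}

# recursively place the subtree with smaller total within-subtree pairwise
# distance first
.sort_smallest_first <- function(node, dist_mat) {
  if (is.leaf(node)) return(node)
  node[[1]] <- .sort_smallest_first(node[[1]], dist_mat)
  node[[2]] <- .sort_smallest_first(node[[2]], dist_mat)
  w <- vapply(1:2, function(i) {
    lv <- labels(node[[i]])
    sum(dist_mat[lv, lv, drop = FALSE]) / 2
  }, numeric(1))
  if (w[2] < w[1]) {
    node_rev <- node
    node_rev[[1]] <- node[[2]]
    node_rev[[2]] <- node[[1]]
    node <- node_rev
  }
  node
}
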