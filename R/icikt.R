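# Missing-value-aware Kendall-tau correlation and sample quality control.
# Missing entries are treated as left-censored: strictly below every
# observed value of their vector and mutually tied, so a missing-missing
# pair is a tie in that vector. With this substitution the statistic is the
# ordinary tau-b, so sparsity itself carries rank information instead of
# being discarded.

#' Missing-value-aware Kendall-tau correlation
#'
#' Kendall tau-b in which every missing entry of a vector is treated as a
#' value strictly lower than all observed entries of that vector, all
#' missing entries mutually tied:
#' `tau = (C - D) / sqrt((P - Tx)(P - Ty))` over all `n(n-1)/2` index
#' pairs, with `Tx`/`Ty` the tied-pair counts within each vector. Reduces
#' to classical tau-b when nothing is missing; invariant under strictly
#' increasing transforms of either vector.
#'
#' @param x,y Numeric vectors of equal length (`NA` = missing).
#' @return Correlation in [-1, 1]; `NaN` when a denominator factor is zero
#'   (e.g. a constant or all-missing vector).
#' @export
ici_kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  tau <- suppressWarnings(stats::cor(.censor_missing(x), .censor_missing(y),
                                     method = "kendall"))
  if (is.na(tau)) NaN else tau
}

# replace NA by a common value strictly below every observed entry
.censor_missing <- function(x) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  lo <- if (all(miss)) 0 else min(x[!miss]) - 1
  x[miss] <- lo
  x
}

#' Pairwise correlation matrix over samples or features
#'
#' Sample-axis correlations use the full missing-aware statistic
#' [ici_kendall_tau()] on each pair of sample columns. Feature-axis
#' correlations with `observed_only = TRUE` (the default for features) drop
#' indices missing in either vector and compute a standard tau-b on the
#' pairwise-complete observations.
#'
#' @param mat Numeric matrix, features x samples, `NA` = missing.
#' @param axis `"samples"` (columns) or `"features"` (rows).
#' @param observed_only Use pairwise-complete observations with classical
#'   tau-b instead of the missing-aware statistic.
#' @return Symmetric correlation matrix with unit diagonal where defined
#'   and `NaN` where undefined (fewer than 2 shared observations or a
#'   degenerate vector).
#' @export
correlation_matrix <- function(mat, axis = c("samples", "features"),
                               observed_only = axis[1] == "features") {
  axis <- match.arg(axis)
  m <- if (axis == "samples") mat else t(mat)
  p <- ncol(m)
  if (p < 2L) stop("need at least two vectors")
  out <- matrix(NaN, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) {
    xi <- m[, i]
    for (j in i:p) {
      yj <- m[, j]
      if (observed_only) {
        ok <- !is.na(xi) & !is.na(yj)
        tau <- if (sum(ok) < 2L) NaN else {
          v <- suppressWarnings(stats::cor(xi[ok], yj[ok], method = "kendall"))
          if (is.na(v)) NaN else v
        }
      } else {
        tau <- ici_kendall_tau(xi, yj)
      }
      out[i, j] <- out[j, i] <- tau
    }
  }
  out
}

#' Tukey box-plot fences
#'
#' Lower/upper hinges are the Tukey five-number-summary hinges (medians of
#' the lower and upper halves, the sample median belonging to both halves
#' when n is odd); the fences sit 1.5 interquartile ranges beyond them.
#'
#' @param values Numeric vector (missing values dropped).
#' @return Named numeric `c(lower, upper)`.
#' @export
tukey_fences <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  fn <- stats::fivenum(values)
  iqr <- fn[4] - fn[2]
  c(lower = fn[2] - 1.5 * iqr, upper = fn[4] + 1.5 * iqr)
}

#' Per-sample QC statistics: median within-class correlation and
#' outlier-lipid fraction
#'
#' For each sample: (i) the median missing-aware Kendall-tau correlation to
#' all other samples of the same disease class; (ii) the fraction of the
#' sample's observed features whose value falls outside the Tukey fences of
#' that feature's observed same-class distribution.
#'
#' @param mat Numeric matrix, features x samples, `NA` = missing.
#' @param classes Per-sample class labels (length = `ncol(mat)`).
#' @return Data frame with `sample_id`, `class`, `median_cor`,
#'   `outlier_frac`.
#' @export
sample_outlier_stats <- function(mat, classes) {
  stopifnot(length(classes) == ncol(mat))
  tab <- table(classes)
  if (any(tab < 3L)) stop("each class needs at least 3 samples")
  sids <- colnames(mat)
  if (is.null(sids)) sids <- as.character(seq_len(ncol(mat)))
  median_cor <- outlier_frac <- numeric(ncol(mat))
  for (cl in names(tab)) {
    cols <- which(classes == cl)
    sub <- mat[, cols, drop = FALSE]
    cm <- correlation_matrix(sub, axis = "samples")
    for (k in seq_along(cols)) {
      median_cor[cols[k]] <- stats::median(cm[k, -k], na.rm = TRUE)
    }
    fences <- t(apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(c(NA_real_, NA_real_))
      tukey_fences(v)
    }))
    lo <- matrix(fences[, 1], nrow(sub), ncol(sub))
    hi <- matrix(fences[, 2], nrow(sub), ncol(sub))
    out <- !is.na(sub) & (sub < lo | sub > hi)
    outlier_frac[cols] <- colSums(out, na.rm = TRUE) /
      pmax(colSums(!is.na(sub)), 1L)
  }
  data.frame(sample_id = sids, class = as.character(classes),
             median_cor = median_cor, outlier_frac = outlier_frac,
             stringsAsFactors = FALSE)
}

#' Flag outlier samples for removal
#'
#' Tukey fences are computed per class over the per-sample QC statistic
#' distributions; a sample is removed iff its median within-class
#' correlation lies below the lower fence AND its outlier-lipid fraction
#' lies above the upper fence (both criteria, conjunctively).
#'
#' @param stats_df Output of [sample_outlier_stats()].
#' @return The input with `cor_lower_fence`, `frac_upper_fence` and
#'   logical `remove` columns; removed sample ids in attribute
#'   `"removed"`.
#' @export
flag_outlier_samples <- function(stats_df) {
  stopifnot(all(c("sample_id", "class", "median_cor", "outlier_frac")
                %in% names(stats_df)))
  stats_df$cor_lower_fence <- NA_real_
  stats_df$frac_upper_fence <- NA_real_
  for (cl in unique(stats_df$class)) {
    idx <- stats_df$class == cl
    fc <- tukey_fences(stats_df$median_cor[idx])
    ff <- tukey_fences(stats_df$outlier_frac[idx])
    stats_df$cor_lower_fence[idx] <- fc["lower"]
    stats_df$frac_upper_fence[idx] <- ff["upper"]
  }
  stats_df$remove <- stats_df$median_cor < stats_df$cor_lower_fence &
    stats_df$outlier_frac > stats_df$frac_upper_fence
  attr(stats_df, "removed") <- stats_df$sample_id[stats_df$remove]
  stats_df
}
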