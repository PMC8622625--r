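# Intensity preprocessing: per-sample median normalization computed over
# ALL characterized peaks of a sample (not only corresponded ones), log2
# transformation, and per-class left-censored imputation used only for
# fold-change/linear-model analyses.

#' Per-sample median peak intensity
#'
#' The normalization denominator: the median raw intensity over all
#' characterized peaks of each sample (candidate multiplicity ignored; each
#' peak counts once). The median of an even count is the mean of the
#' central pair.
#'
#' @param peaklists Named list of assigned peak tables.
#' @return Named numeric vector of per-sample medians.
#' @export
sample_medians <- function(peaklists) {
  vapply(peaklists, function(pk) {
    un <- pk[!duplicated(pk$peak_id), , drop = FALSE]
    if (nrow(un) == 0L) stop("sample with zero peaks")
    stats::median(un$intensity)
  }, numeric(1))
}

#' Median-normalize per-sample peak intensities
#'
#' Divides every peak intensity by its sample's median intensity over all
#' peaks, making intensities unitless ratios with per-sample median 1.
#'
#' @param peaklists Named list of assigned peak tables.
#' @return The peak lists with normalized intensities; the medians used are
#'   attached as attribute `"medians"`.
#' @export
median_normalize <- function(peaklists) {
  med <- sample_medians(peaklists)
  out <- lapply(names(peaklists), function(sid) {
    pk <- peaklists[[sid]]
    pk$intensity <- pk$intensity / med[[sid]]
    pk
  })
  names(out) <- names(peaklists)
  attr(out, "medians") <- med
  out
}

#' Log2-transform an intensity matrix
#'
#' Elementwise log2; missing entries are preserved. All observed values
#' must be strictly positive.
#'
#' @param mat Numeric matrix (features x samples), `NA` = missing.
#' @return log2 matrix with attribute `stage = "log2"`.
#' @export
log2_transform <- function(mat) {
  stage <- attr(mat, "stage")
  if (!is.null(stage) && stage %in% c("log2", "imputed")) {
    stop("matrix is already on the log2 scale (stage ", stage, ")")
  }
  if (any(mat[!is.na(mat)] <= 0)) stop("non-positive observed intensity")
  out <- log2(mat)
  attr(out, "stage") <- "log2"
  out
}

#' Impute left-censored missing values per tissue class
#'
#' For each tissue class, all observed log2 intensities of that class are
#' pooled and the `q` quantile of the pool taken as the lower bound of the
#' class's intensity distribution (default: the lower end of the central
#' 95% interval). Every missing entry in that class is replaced by the log2
#' value of one half of the raw-scale bound, i.e. the bound minus 1 on the
#' log2 scale. The imputed matrix feeds fold changes and the moderated
#' linear model only; correlation and co-occurrence analyses use the
#' unimputed data.
#'
#' @param mat log2 intensity matrix (features x samples) with `NA` missing.
#' @param classes Character vector of per-sample class labels (length =
#'   `ncol(mat)`).
#' @param q Quantile defining the lower bound of each class's pooled
#'   distribution.
#' @return The imputed matrix (attribute `stage = "imputed"`); per-class
#'   log2 imputation values are attached as attribute `"thresholds"`
#'   (already including the minus-1 shift).
#' @export
impute_missing <- function(mat, classes, q = 0.025) {
  stopifnot(length(classes) == ncol(mat), q >= 0, q < 1)
  stage <- attr(mat, "stage")
  if (!is.null(stage) && stage != "log2") {
    stop("impute_missing expects a log2-stage matrix, got stage ", stage)
  }
  out <- mat
  thresholds <- numeric(0)
  for (cl in unique(classes)) {
    cols <- which(classes == cl)
    vals <- mat[, cols, drop = FALSE]
    obs <- vals[!is.na(vals)]
    if (length(obs) == 0L) stop("class '", cl, "' has no observed values")
    impute_at <- stats::quantile(obs, q, names = FALSE, type = 7) - 1
    sub <- out[, cols, drop = FALSE]
    sub[is.na(sub)] <- impute_at
    out[, cols] <- sub
    thresholds[cl] <- impute_at
  }
  attr(out, "stage") <- "imputed"
  attr(out, "thresholds") <- thresholds
  out
}
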