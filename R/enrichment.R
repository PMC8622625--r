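# Lipid-category enrichment of significant features. The universe is the
# set of singly categorized lipid features; sphingolipids additionally
# carry an SP-low / SP-high annotation split at m/z 700. The more- and
# less-abundant significant sets are tested independently with an exact
# upper-tail hypergeometric test, BH-adjusted across the 7 annotations
# within each direction.

.ANNOTATION_ORDER <- c("FA", "GP", "PR", "SP", "SP-low", "SP-high", "ST")

#' Annotate features with lipid-category terms
#'
#' Restricts to singly categorized lipid features (the enrichment
#' universe) and expands each sphingolipid with one of `SP-low`
#' (m/z < `mz_split`) or `SP-high` (m/z >= `mz_split`, boundary inclusive
#' on the high side) in addition to `SP`.
#'
#' @param features Data frame with `feature_id`, `category` and `mz`;
#'   an optional logical `lipid_single` column restricts the universe
#'   (otherwise rows with category `"multiple"`/`"not-lipid"` are
#'   dropped).
#' @param mz_split Sphingolipid m/z boundary.
#' @return Long annotation table (`feature_id`, `annotation`); universe
#'   feature ids in attribute `"universe"`.
#' @export
annotate_categories <- function(features, mz_split = 700) {
  stopifnot(all(c("feature_id", "category", "mz") %in% names(features)))
  if (anyNA(features$mz)) stop("feature without m/z")
  single <- if ("lipid_single" %in% names(features)) {
    features$lipid_single
  } else {
    !(features$category %in% c("multiple", "not-lipid"))
  }
  uni <- features[single & features$category %in% .LIPID_CATEGORIES, ,
                  drop = FALSE]
  ann <- data.frame(feature_id = uni$feature_id, annotation = uni$category,
                    stringsAsFactors = FALSE)
  sp <- uni[uni$category == "SP", , drop = FALSE]
  if (nrow(sp)) {
    ann <- rbind(ann, data.frame(
      feature_id = sp$feature_id,
      annotation = ifelse(sp$mz >= mz_split, "SP-high", "SP-low"),
      stringsAsFactors = FALSE
    ))
  }
  rownames(ann) <- NULL
  attr(ann, "universe") <- uni$feature_id
  ann
}

#' Exact upper-tail hypergeometric enrichment
#'
#' For a universe of `N` features of which `K` are significant, an
#' annotation of size `n` with `k` significant members has expected
#' overlap `n * K / N` and enrichment p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, computed by exact summation of the
#' probability mass function in log space.
#'
#' @param N Universe size.
#' @param K Number of significant features.
#' @param n Annotation size.
#' @param k Observed overlap.
#' @return List with `expected` and `p_value`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (n > N || K > N || k > min(n, K) || any(c(N, K, n, k) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  expected <- n * K / N
  if (n == 0 || K == 0) {
    return(list(expected = expected, p_value = 1))  # k is forced to 0 here
  }
  i <- k:min(n, K)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  p <- min(1, sum(exp(logp)))
  list(expected = expected, p_value = p)
}

#' Directional lipid-category enrichment table
#'
#' One exact hypergeometric test per annotation and direction, with BH
#' adjustment across the annotations within each direction. Rows are
#' emitted in the fixed order FA, GP, PR, SP, SP-low, SP-high, ST.
#'
#' @param annotations Long annotation table from [annotate_categories()]
#'   (attribute `"universe"` defines N).
#' @param sig_more,sig_less Feature ids significantly more / less
#'   abundant in cancer (intersected with the universe).
#' @return Data frame with per-direction `total`, `expected`, `observed`,
#'   `p_value` and `p_adjust` columns (Table-style shape).
#' @export
enrichment_table <- function(annotations, sig_more, sig_less) {
  universe <- attr(annotations, "universe")
  if (is.null(universe) || length(universe) == 0L) stop("empty universe")
  N <- length(universe)
  anns <- .ANNOTATION_ORDER
  out <- data.frame(annotation = anns, total = NA_integer_,
                    stringsAsFactors = FALSE)
  for (dir in c("more", "less")) {
    sig <- intersect(if (dir == "more") sig_more else sig_less, universe)
    K <- length(sig)
    exp_col <- obs_col <- p_col <- numeric(length(anns))
    for (a in seq_along(anns)) {
      members <- annotations$feature_id[annotations$annotation == anns[a]]
      n <- length(members)
      k <- length(intersect(members, sig))
      h <- hypergeometric_enrichment(N, K, n, k)
      exp_col[a] <- h$expected; obs_col[a] <- k; p_col[a] <- h$p_value
      out$total[a] <- n
    }
    out[[paste0("expected_", dir)]] <- exp_col
    out[[paste0("observed_", dir)]] <- obs_col
    out[[paste0("p_", dir)]] <- p_col
    out[[paste0("p_adjust_", dir)]] <- bh_adjust(p_col)
  }
  out
}

#' Enrichment table from differential-abundance results
#'
#' Splits the significant features of a [differential_features()] result
#' by fold-change direction and runs [enrichment_table()] on the
#' single-category universe.
#'
#' @param diff Result of [differential_features()].
#' @param log2fc Named per-feature log2 fold changes (cancer minus
#'   non-cancer).
#' @param features Feature annotation table (`feature_id`, `category`,
#'   `mz`, optional `lipid_single`).
#' @param mz_split Sphingolipid m/z boundary.
#' @return Enrichment table as in [enrichment_table()].
#' @export
enrich_from_diff <- function(diff, log2fc, features, mz_split = 700) {
  ann <- annotate_categories(features, mz_split)
  fc <- log2fc[diff$feature_id]
  sig_more <- diff$feature_id[diff$significant & fc > 0]
  sig_less <- diff$feature_id[diff$significant & fc < 0]
  enrichment_table(ann, sig_more, sig_less)
}
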