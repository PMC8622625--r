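# End-to-end orchestration: correspondence -> presence filter ->
# normalization -> sample QC -> imputation -> differential abundance ->
# category enrichment -> structure analyses. The pipeline is a pure
# function of (inputs, configuration); reruns are byte-identical.

#' Pipeline configuration
#'
#' Collects the analysis parameters with their study defaults: 5 ppm
#' correspondence tolerance, 25% per-class presence filter, 2.5% pooled
#' quantile for the imputation bound, adjusted-p cutoff 0.01, and the
#' m/z 700 sphingolipid split.
#'
#' @param tol_ppm Correspondence grouping tolerance (ppm).
#' @param min_support EMF-voting support threshold (proportion of a
#'   group's spectra, strict).
#' @param min_presence Per-class presence fraction filter.
#' @param impute_quantile Pooled-distribution quantile defining the
#'   imputation bound.
#' @param alpha Adjusted-p significance cutoff.
#' @param mz_split Sphingolipid m/z annotation boundary.
#' @param linkage Hierarchical clustering linkage.
#' @param run_qc Remove flagged outlier samples before testing.
#' @param run_structure Compute PCA/co-occurrence/subgrouping outputs.
#' @param refilter_after_qc Recompute the presence filter on the
#'   post-QC sample set.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(tol_ppm = 5, min_support = 0.5,
                            min_presence = 0.25, impute_quantile = 0.025,
                            alpha = 0.01, mz_split = 700,
                            linkage = "average", run_qc = TRUE,
                            run_structure = TRUE,
                            refilter_after_qc = FALSE) {
  stopifnot(tol_ppm > 0, min_support >= 0, min_support <= 1,
            min_presence >= 0, min_presence <= 1,
            impute_quantile >= 0, impute_quantile < 1,
            alpha > 0, alpha <= 1, mz_split > 0)
  structure(list(tol_ppm = tol_ppm, min_support = min_support,
                 min_presence = min_presence,
                 impute_quantile = impute_quantile, alpha = alpha,
                 mz_split = mz_split, linkage = linkage, run_qc = run_qc,
                 run_structure = run_structure,
                 refilter_after_qc = refilter_after_qc),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes correspondence, presence filtering, median normalization,
#' sample quality control, imputation, dual differential-abundance
#' testing, category enrichment and (optionally) the structure analyses
#' on a set of assigned peak lists. Intermediates are written as
#' tab-delimited tables when `out_dir` is given.
#'
#' @param peaklists Named list of assigned peak tables (long format), or a
#'   `lipid_study` from [generate_study()].
#' @param metadata Sample metadata (ignored when `peaklists` is a
#'   `lipid_study`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for delimited intermediates.
#' @return List of class `"pipeline_report"` with every stage's result and
#'   a `summary` of sample/feature counts.
#' @export
run_pipeline <- function(peaklists, metadata = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(peaklists, "lipid_study")) {
    metadata <- peaklists$metadata
    peaklists <- peaklists$peaklists
  }
  if (is.null(metadata)) stop("stage correspondence: metadata required")

  ## normalization (per-sample medians over all characterized peaks)
  normalized <- tryCatch(median_normalize(peaklists),
                         error = function(e) stop("stage normalize: ",
                                                  conditionMessage(e)))

  ## correspondence + presence filter
  corr <- tryCatch(
    build_corresponded_matrix(normalized, metadata,
                              tol_ppm = config$tol_ppm,
                              min_support = config$min_support),
    error = function(e) stop("stage correspondence: ", conditionMessage(e)))
  n_corresponded <- nrow(corr$intensity)
  filt <- filter_by_class_presence(corr, config$min_presence)
  n_filtered <- nrow(filt$intensity)

  ## sample QC on the filtered log2 matrix
  logmat <- log2_transform(filt$intensity)
  removed <- character(0)
  qc_stats <- NULL
  if (config$run_qc) {
    qc_stats <- tryCatch({
      st <- sample_outlier_stats(logmat, metadata$class)
      flag_outlier_samples(st)
    }, error = function(e) stop("stage qc: ", conditionMessage(e)))
    removed <- attr(qc_stats, "removed")
    if (length(removed)) {
      keep <- !(metadata$sample_id %in% removed)
      metadata <- metadata[keep, , drop = FALSE]
      filt$intensity <- filt$intensity[, metadata$sample_id, drop = FALSE]
      filt$metadata <- metadata
      if (config$refilter_after_qc) {
        pres <- .recompute_presence(filt)
        filt <- pres
      }
      logmat <- log2_transform(filt$intensity)
    }
  }
  classes <- metadata$class
  instrument <- metadata$instrument

  ## imputation + differential abundance
  imputed <- tryCatch(impute_missing(logmat, classes, config$impute_quantile),
                      error = function(e) stop("stage impute: ",
                                               conditionMessage(e)))
  mod <- tryCatch(fit_moderated_linear_model(imputed, classes, instrument),
                  error = function(e) stop("stage diffabund: ",
                                           conditionMessage(e)))
  tp <- two_part_test_all(logmat, classes)
  diff <- differential_features(mod, tp, config$alpha)
  log2fc <- log2_fold_changes(imputed, classes)
  diff$log2fc <- unname(log2fc[diff$feature_id])
  diff$direction <- ifelse(diff$log2fc > 0, "more",
                           ifelse(diff$log2fc < 0, "less", "none"))

  ## enrichment on the single-category universe
  enrich <- tryCatch(
    enrich_from_diff(diff, log2fc, filt$features, config$mz_split),
    error = function(e) stop("stage enrichment: ", conditionMessage(e)))

  ## structure analyses
  struct <- NULL
  if (config$run_structure) {
    struct <- tryCatch({
      pca <- pca_scores(logmat, n_components = 3L)
      samp_cor <- correlation_matrix(logmat, axis = "samples")
      d <- 1 - samp_cor
      d[!is.finite(d)] <- 1
      diag(d) <- 0
      clust <- cluster_samples(d, linkage = config$linkage)
      list(pca = pca, sample_correlation = samp_cor, clustering = clust)
    }, error = function(e) stop("stage structure: ", conditionMessage(e)))
  }

  report <- structure(list(
    corresponded = corr, filtered = filt, qc = qc_stats,
    removed_samples = removed, log2 = logmat, imputed = imputed,
    diff = diff, enrichment = enrich, structure = struct,
    config = config,
    summary = list(
      n_samples_in = length(peaklists),
      n_samples_after_qc = nrow(metadata),
      n_corresponded = n_corresponded,
      n_filtered = n_filtered,
      n_significant = sum(diff$significant),
      n_sig_moderated = sum(diff$sig_moderated),
      n_sig_two_part = sum(diff$sig_two_part)
    )), class = "pipeline_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.recompute_presence <- function(corresponded) {
  md <- corresponded$metadata
  sizes <- table(factor(md$class, levels = c("cancer", "non-cancer")))
  obs <- !is.na(corresponded$intensity)
  corresponded$features$presence_cancer <-
    rowSums(obs[, md$class == "cancer", drop = FALSE]) / max(sizes["cancer"], 1L)
  corresponded$features$presence_noncancer <-
    rowSums(obs[, md$class == "non-cancer", drop = FALSE]) / max(sizes["non-cancer"], 1L)
  filter_by_class_presence(corresponded, 0.25)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("Lipidomics pipeline report\n")
  cat(sprintf("  samples: %d in, %d after QC (%d removed)\n", s$n_samples_in,
              s$n_samples_after_qc, s$n_samples_in - s$n_samples_after_qc))
  cat(sprintf("  corresponded peaks: %d (%d pass the presence filter)\n",
              s$n_corresponded, s$n_filtered))
  cat(sprintf("  significant features: %d (moderated %d, two-part %d)\n",
              s$n_significant, s$n_sig_moderated, s$n_sig_two_part))
  invisible(x)
}

.write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$filtered$features, "corresponded_features.tsv")
  mat <- data.frame(feature_id = rownames(report$filtered$intensity),
                    report$filtered$intensity, check.names = FALSE)
  wt(mat, "intensity_matrix.tsv")
  if (!is.null(report$qc)) wt(report$qc, "qc_stats.tsv")
  wt(report$diff, "differential_abundance.tsv")
  wt(report$enrichment, "enrichment_table.tsv")
  invisible(out_dir)
}

#' Directional enrichment table from printed counts
#'
#' Counts-only entry point: computes the expected overlaps, exact
#' upper-tail hypergeometric p-values and per-direction BH-adjusted
#' p-values directly from a table of universe/annotation counts, without
#' any spectra or simulation.
#'
#' @param counts Data frame (or path to a tab-delimited file) with columns
#'   `annotation`, `n` (annotation size), `k_more`, `k_less` (observed
#'   significant overlaps per direction).
#' @param N Universe size; when `NULL`, the sum of `n` over the disjoint
#'   base categories (FA, GP, PR, SP, ST).
#' @param K_more,K_less Significant-set sizes per direction; when `NULL`,
#'   the sums of `k_more`/`k_less` over the disjoint base categories.
#' @return Data frame with one row per annotation: `total`, and per
#'   direction `expected`, `observed`, `p_value`, `p_adjust`.
#' @export
run_table1_check <- function(counts, N = NULL, K_more = NULL, K_less = NULL) {
  if (is.character(counts)) {
    counts <- utils::read.delim(counts, stringsAsFactors = FALSE,
                                comment.char = "#")
  }
  need <- c("annotation", "n", "k_more", "k_less")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "))
  }
  base <- counts$annotation %in% c("FA", "GP", "PR", "SP", "ST")
  if (is.null(N)) N <- sum(counts$n[base])
  if (is.null(K_more)) K_more <- sum(counts$k_more[base])
  if (is.null(K_less)) K_less <- sum(counts$k_less[base])
  out <- data.frame(annotation = counts$annotation, total = counts$n,
                    stringsAsFactors = FALSE)
  for (dir in c("more", "less")) {
    K <- if (dir == "more") K_more else K_less
    k <- counts[[paste0("k_", dir)]]
    res <- mapply(function(ni, ki) {
      h <- hypergeometric_enrichment(N, K, ni, ki)
      c(h$expected, h$p_value)
    }, counts$n, k)
    out[[paste0("expected_", dir)]] <- res[1, ]
    out[[paste0("observed_", dir)]] <- k
    out[[paste0("p_", dir)]] <- res[2, ]
    out[[paste0("p_adjust_", dir)]] <- bh_adjust(res[2, ])
  }
  out
}
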