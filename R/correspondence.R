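# Cross-spectrum peak correspondence. Peaks are pooled across spectra,
# chained into m/z groups by single linkage, and each group's spectra vote
# on the consensus elemental molecular formula (EMF). A corresponded peak is
# an isotopologue-level consensus feature with a per-sample intensity vector
# in which absence is a missing value.

#' Group peaks across spectra by m/z proximity
#'
#' Single-linkage chaining on the pooled, m/z-sorted peak list: two
#' consecutive pooled peaks join the same group iff their gap is at most
#' `tol_ppm` parts-per-million of their mean m/z. Each group may contain at
#' most one peak per spectrum: when two peaks of one spectrum land in a
#' group, the more intense one stays (ties broken by lower m/z) and the
#' others are demoted to singleton groups.
#'
#' @param spectra Named list of assigned peak tables (long format, one row
#'   per candidate; columns `peak_id`, `mz`, `intensity`, ...).
#' @param tol_ppm Chaining tolerance in ppm; must be positive.
#' @return Data frame of unique peaks with columns `sample`, `peak_id`,
#'   `mz`, `intensity`, `group` (integer group label).
#' @export
group_peaks_by_mz <- function(spectra, tol_ppm = 5) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  if (length(spectra) == 0L) {
    return(data.frame(sample = character(), peak_id = integer(),
                      mz = numeric(), intensity = numeric(),
                      group = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(names(spectra))) stop("spectra must be a named list")
  pooled <- do.call(rbind, lapply(names(spectra), function(sid) {
    pk <- spectra[[sid]]
    un <- pk[!duplicated(pk$peak_id), c("peak_id", "mz", "intensity"), drop = FALSE]
    if (nrow(un) == 0L) return(NULL)
    data.frame(sample = sid, un, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(data.frame(sample = character(), peak_id = integer(),
                      mz = numeric(), intensity = numeric(),
                      group = integer(), stringsAsFactors = FALSE))
  }
  pooled <- pooled[order(pooled$mz, pooled$sample, pooled$peak_id), , drop = FALSE]
  rownames(pooled) <- NULL
  n <- nrow(pooled)
  if (n == 1L) {
    pooled$group <- 1L
    return(pooled)
  }
  gap <- diff(pooled$mz)
  win <- tol_ppm * 1e-6 * (pooled$mz[-n] + pooled$mz[-1]) / 2
  pooled$group <- cumsum(c(1L, as.integer(gap > win)))

  # enforce one peak per spectrum per group
  key <- paste(pooled$group, pooled$sample)
  if (anyDuplicated(key)) {
    ord <- order(pooled$group, pooled$sample, -pooled$intensity, pooled$mz,
                 pooled$peak_id)
    keep_first <- !duplicated(key[ord])
    demote <- ord[!keep_first]
    next_group <- max(pooled$group)
    pooled$group[demote] <- next_group + seq_along(demote)
    pooled <- pooled[order(pooled$group, pooled$sample), , drop = FALSE]
    rownames(pooled) <- NULL
  }
  pooled
}

#' Elect a consensus assignment for one peak group by EMF voting
#'
#' Each spectrum in the group casts one ballot per distinct candidate EMF it
#' proposes for its peak. The EMF with the most ballots wins iff its ballot
#' count strictly exceeds `min_support` times the number of spectra in the
#' group. Ties are broken by smallest mean absolute ppm error of the
#' candidate's theoretical ion m/z, then lexicographically on the EMF
#' string. The winner's isotopologue index and adduct are the modal
#' (isotopologue, adduct) pair among its supporting candidates.
#'
#' @param group Data frame of candidate rows for one group: columns
#'   `sample`, `mz`, `emf`, `isotopologue`, `adduct`, `category`,
#'   `multi_class`.
#' @param min_support Required support as a proportion of the group's
#'   spectra (strict inequality).
#' @return List with `emf`, `isotopologue`, `adduct`, `category`,
#'   `support`, `n_spectra`, or `NULL` when no EMF reaches support.
#' @export
emf_vote <- function(group, min_support = 0.5) {
  if (is.null(group) || nrow(group) == 0L) stop("empty peak group")
  n_spectra <- length(unique(group$sample))
  ballots <- unique(group[, c("sample", "emf")])
  counts <- table(ballots$emf)
  top <- max(counts)
  if (top <= min_support * n_spectra) return(NULL)
  winners <- names(counts)[counts == top]
  if (length(winners) > 1L) {
    mean_err <- vapply(winners, function(e) {
      rows <- group[group$emf == e, , drop = FALSE]
      theo <- mapply(ion_mz, rows$emf, rows$isotopologue, rows$adduct)
      mean(abs((rows$mz - theo) / theo * 1e6))
    }, numeric(1))
    winners <- winners[order(mean_err, winners)]
  }
  win <- winners[1]
  sup <- group[group$emf == win, , drop = FALSE]
  combo <- paste(sup$isotopologue, sup$adduct, sep = "|")
  tabc <- table(combo)
  best <- names(tabc)[tabc == max(tabc)]
  best <- sort(best)[1]
  parts <- strsplit(best, "|", fixed = TRUE)[[1]]
  cats <- unique(sup$category)
  category <- if (any(sup$multi_class) || length(cats) > 1L) "multiple" else cats
  list(emf = win, isotopologue = as.integer(parts[1]), adduct = parts[2],
       category = category, support = unname(top), n_spectra = n_spectra)
}

#' Build the corresponded-peak matrix from assigned spectra
#'
#' Groups peaks by m/z across all spectra, elects consensus assignments by
#' EMF voting, and assembles a features-by-samples intensity matrix with
#' `NA` for samples whose spectrum has no (or a demoted) peak in the group.
#' Presence fractions per disease class are computed against the full class
#' sizes in `metadata`. The consensus category is the winning EMF's
#' classifier label; it is `"multiple"` when supporting candidates disagree
#' or carry the classifier-multiplicity flag, and such features (and
#' `"not-lipid"`) are flagged `lipid_single = FALSE` for exclusion from
#' category-level analyses.
#'
#' @param spectra Named list of assigned peak tables (long format).
#' @param metadata Sample table with `sample_id`, `class` (must cover every
#'   spectrum).
#' @param tol_ppm Grouping tolerance in ppm.
#' @param min_support Voting support threshold.
#' @return Object of class `"corresponded_peaks"`: list with `intensity`
#'   (matrix, features x samples, `NA` = absent), `features` (annotation
#'   table) and `metadata`.
#' @export
build_corresponded_matrix <- function(spectra, metadata, tol_ppm = 5,
                                      min_support = 0.5) {
  missing_meta <- setdiff(names(spectra), metadata$sample_id)
  if (length(missing_meta)) {
    stop("spectra missing from metadata: ", paste(missing_meta, collapse = ", "))
  }
  pooled <- group_peaks_by_mz(spectra, tol_ppm)
  samples <- metadata$sample_id
  class_sizes <- table(factor(metadata$class, levels = c("cancer", "non-cancer")))

  # candidate rows joined to group labels
  long <- do.call(rbind, lapply(names(spectra), function(sid) {
    pk <- spectra[[sid]]
    if (nrow(pk) == 0L) return(NULL)
    cbind(sample = sid, pk, stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(pooled) == 0L) {
    return(.empty_corresponded(metadata))
  }
  long$group <- pooled$group[match(paste(long$sample, long$peak_id),
                                   paste(pooled$sample, pooled$peak_id))]
  groups <- split(long, long$group)
  members <- split(pooled, pooled$group)

  rows <- vector("list", length(groups))
  inten <- vector("list", length(groups))
  j <- 0L
  for (g in names(groups)) {
    consensus <- emf_vote(groups[[g]], min_support)
    if (is.null(consensus)) next
    j <- j + 1L
    mem <- members[[g]]
    v <- rep(NA_real_, length(samples))
    names(v) <- samples
    v[mem$sample] <- mem$intensity
    pres <- metadata$class[match(mem$sample, metadata$sample_id)]
    rows[[j]] <- data.frame(
      feature_id = paste(consensus$emf, consensus$isotopologue,
                         consensus$adduct, sep = "|"),
      emf = consensus$emf, isotopologue = consensus$isotopologue,
      adduct = consensus$adduct, mz = stats::median(mem$mz),
      category = consensus$category,
      support = consensus$support, n_spectra = consensus$n_spectra,
      presence_cancer = sum(pres == "cancer") / max(class_sizes["cancer"], 1L),
      presence_noncancer = sum(pres == "non-cancer") / max(class_sizes["non-cancer"], 1L),
      stringsAsFactors = FALSE
    )
    inten[[j]] <- v
  }
  if (j == 0L) return(.empty_corresponded(metadata))
  features <- do.call(rbind, rows[seq_len(j)])
  mat <- do.call(rbind, inten[seq_len(j)])
  # disambiguate rare duplicate consensus ids (split m/z groups)
  if (anyDuplicated(features$feature_id)) {
    dup <- duplicated(features$feature_id) |
      duplicated(features$feature_id, fromLast = TRUE)
    features$feature_id[dup] <- paste0(features$feature_id[dup], "#",
                                       ave(seq_len(nrow(features)),
                                           features$feature_id,
                                           FUN = seq_along)[dup])
  }
  rownames(mat) <- features$feature_id
  rownames(features) <- NULL
  features$lipid_single <- !(features$category %in% c("multiple", "not-lipid"))
  structure(list(intensity = mat, features = features, metadata = metadata),
            class = "corresponded_peaks")
}

.empty_corresponded <- function(metadata) {
  mat <- matrix(numeric(0), nrow = 0, ncol = nrow(metadata),
                dimnames = list(NULL, metadata$sample_id))
  structure(list(
    intensity = mat,
    features = data.frame(feature_id = character(), emf = character(),
                          isotopologue = integer(), adduct = character(),
                          mz = numeric(), category = character(),
                          support = integer(), n_spectra = integer(),
                          presence_cancer = numeric(),
                          presence_noncancer = numeric(),
                          lipid_single = logical(), stringsAsFactors = FALSE),
    metadata = metadata), class = "corresponded_peaks")
}

#' @export
print.corresponded_peaks <- function(x, ...) {
  cat(sprintf("Corresponded peaks: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$intensity), ncol(x$intensity),
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' Filter corresponded peaks by per-class presence
#'
#' Keeps a feature iff it is present in at least `min_frac` of the cancer
#' samples or at least `min_frac` of the non-cancer samples (inclusive
#' threshold).
#'
#' @param peaks A `corresponded_peaks` object.
#' @param min_frac Presence fraction threshold.
#' @return The filtered `corresponded_peaks` object.
#' @export
filter_by_class_presence <- function(peaks, min_frac = 0.25) {
  stopifnot(inherits(peaks, "corresponded_peaks"))
  if (!all(peaks$metadata$class %in% c("cancer", "non-cancer"))) {
    stop("unknown class label in metadata")
  }
  keep <- peaks$features$presence_cancer >= min_frac |
    peaks$features$presence_noncancer >= min_frac
  peaks$intensity <- peaks$intensity[keep, , drop = FALSE]
  peaks$features <- peaks$features[keep, , drop = FALSE]
  rownames(peaks$features) <- NULL
  peaks
}
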