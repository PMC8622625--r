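# m/z grouping and EMF voting. Group chaining is checked against an
# exhaustive all-pairs single-linkage oracle, voting against hand-counted
# ballots, and full correspondence against the generator's ground truth.

test_that("two peaks group within tolerance and split outside it", {
  spectra <- list(s1 = make_peaks(700.0000), s2 = make_peaks(700.0014))
  g5 <- group_peaks_by_mz(spectra, tol_ppm = 5)
  expect_equal(length(unique(g5$group)), 1L)
  g1 <- group_peaks_by_mz(spectra, tol_ppm = 1)
  expect_equal(length(unique(g1$group)), 2L)
})

test_that("chained grouping matches the all-pairs single-linkage oracle", {
  spectra <- list(s1 = make_peaks(700.0000), s2 = make_peaks(700.0020),
                  s3 = make_peaks(700.0040))
  g <- group_peaks_by_mz(spectra, tol_ppm = 3)
  expect_equal(length(unique(g$group)), 1L)  # pairwise gaps ~2.9 ppm chain

  set.seed(81)
  for (r in 1:20) {
    mz <- sort(runif(15, 500, 500.02))
    spectra <- lapply(seq_along(mz), function(i) make_peaks(mz[i]))
    names(spectra) <- paste0("s", seq_along(mz))
    tol <- runif(1, 1, 8)
    got <- group_peaks_by_mz(spectra, tol)
    got <- got[order(got$mz), ]
    expected <- oracle_single_linkage(sort(mz), tol)
    expect_equal(as.integer(factor(got$group, levels = unique(got$group))),
                 expected)
  }
})

test_that("a spectrum contributes at most one peak per group, keeping the most intense", {
  spectra <- list(
    s1 = make_peaks(c(700.0000, 700.0005), intensity = c(1, 9)),
    s2 = make_peaks(700.0003)
  )
  g <- group_peaks_by_mz(spectra, tol_ppm = 5)
  main <- g$group[g$sample == "s2"]
  kept <- g[g$group == main & g$sample == "s1", ]
  expect_equal(kept$intensity, 9)
  demoted <- g[g$sample == "s1" & g$intensity == 1, ]
  expect_equal(sum(g$group == demoted$group), 1L)  # singleton group
})

test_that("grouping handles empty input and rejects bad tolerance", {
  expect_equal(nrow(group_peaks_by_mz(list())), 0L)
  expect_error(group_peaks_by_mz(list(s1 = make_peaks(700)), tol_ppm = -1),
               "positive")
})

test_that("EMF voting elects by ballots with strict majority support", {
  grp <- function(emfs_by_spectrum) {
    do.call(rbind, lapply(seq_along(emfs_by_spectrum), function(i) {
      make_peaks(rep(700.0, length(emfs_by_spectrum[[i]])),
                 emf = emfs_by_spectrum[[i]],
                 peak_id = rep(1L, length(emfs_by_spectrum[[i]]))) |>
        transform(sample = paste0("s", i))
    }))
  }
  # unanimity
  v <- emf_vote(grp(list("A", "A", "A", "A")))
  expect_equal(v$emf, "A")
  expect_equal(v$support, 4L)
  # 3 x {A}, 1 x {A, B}: A gets 4 ballots, B gets 1
  v <- emf_vote(grp(list("A", "A", "A", c("A", "B"))))
  expect_equal(v$emf, "A")
  expect_equal(v$support, 4L)
  # 2 x {A}, 2 x {B}: neither strictly exceeds half of 4
  expect_null(emf_vote(grp(list("A", "A", "B", "B"))))
  expect_error(emf_vote(make_peaks(numeric(0))), "empty")
})

test_that("voting ties break by smallest mean ppm error, then lexicographically", {
  # one spectrum proposing two EMFs: 1 ballot each; the peak m/z sits on
  # C40H80NO8P's [M+H]+, so that candidate has (near-)zero ppm error
  true_emf <- "C40H80NO8P"
  decoy <- "C39H78N2O8P"
  mz <- ion_mz(true_emf, 0L, "H")
  grp <- make_peaks(rep(mz, 2), emf = c(decoy, true_emf), peak_id = c(1L, 1L))
  grp$sample <- "s1"
  expect_equal(emf_vote(grp)$emf, true_emf)
  # one EMF proposed under two adducts: the modal (isotopologue, adduct)
  # tie is broken alphabetically
  mid <- (ion_mz("C6H12O6", 0L, "H") + ion_mz("C6H12O6", 0L, "NH4")) / 2
  grp2 <- make_peaks(rep(mid, 2), emf = c("C6H12O6", "C6H12O6"),
                     adduct = c("NH4", "H"), peak_id = c(1L, 1L))
  grp2$sample <- "s1"
  v2 <- emf_vote(grp2)          # one EMF, two candidate adducts: modal tie
  expect_equal(v2$emf, "C6H12O6")
  expect_equal(v2$adduct, "H")  # alphabetical tie-break on (iso, adduct)
})

test_that("voting is invariant to spectrum order", {
  st <- generate_study(sim_config(n_patients = 4, n_features = 30, seed = 13))
  md <- st$metadata
  a <- build_corresponded_matrix(st$peaklists, md)
  perm <- rev(names(st$peaklists))
  b <- build_corresponded_matrix(st$peaklists[perm], md)
  ord_a <- order(a$features$feature_id)
  ord_b <- order(b$features$feature_id)
  expect_equal(a$features$emf[ord_a], b$features$emf[ord_b])
  expect_equal(a$intensity[ord_a, colnames(a$intensity)],
               b$intensity[ord_b, colnames(a$intensity)])
})

test_that("raising tolerance never shrinks groups; raising support never adds consensus peaks", {
  st <- generate_study(sim_config(n_patients = 4, n_features = 40, seed = 17))
  g_lo <- group_peaks_by_mz(st$peaklists, 2)
  g_hi <- group_peaks_by_mz(st$peaklists, 10)
  expect_gte(length(unique(g_lo$group)), length(unique(g_hi$group)))

  n_lo <- nrow(build_corresponded_matrix(st$peaklists, st$metadata,
                                         min_support = 0.3)$intensity)
  n_hi <- nrow(build_corresponded_matrix(st$peaklists, st$metadata,
                                         min_support = 0.9)$intensity)
  expect_gte(n_lo, n_hi)
})

test_that("on ambiguity-free data the corresponded peaks equal the surviving ground truth", {
  cfg <- sim_config(n_patients = 5, n_features = 40, ambiguity_rate = 0,
                    multi_class_rate = 0, seed = 21)
  st <- generate_study(cfg)
  corr <- build_corresponded_matrix(st$peaklists, st$metadata)
  # surviving features: emitted in at least one sample
  emitted <- unique(unlist(lapply(st$peaklists, function(pk) {
    paste(pk$emf, pk$isotopologue, pk$adduct, sep = "|")
  })))
  expect_setequal(sub("#.*$", "", corr$features$feature_id), emitted)
  expect_equal(nrow(corr$intensity), length(emitted))
  # every consensus matches the ground-truth assignment of its peaks
  tt <- truth_table(st)
  expect_true(all(corr$features$emf %in% tt$emf))
})

test_that("single- and disjoint-spectrum inputs give per-class presence fractions", {
  md <- make_metadata(c("s1", "s2"), c("cancer", "non-cancer"))
  single <- build_corresponded_matrix(list(s1 = make_peaks(c(700, 800))),
                                      md[1, , drop = FALSE])
  expect_equal(nrow(single$intensity), 2L)
  expect_equal(single$features$presence_cancer, c(1, 1))

  disjoint <- build_corresponded_matrix(
    list(s1 = make_peaks(700), s2 = make_peaks(900)), md)
  expect_equal(disjoint$features$presence_cancer +
                 disjoint$features$presence_noncancer, c(1, 1))
  expect_error(build_corresponded_matrix(list(sX = make_peaks(700)), md),
               "missing from metadata")
})

test_that("the 25% presence filter is inclusive and per-class", {
  md <- make_metadata(paste0("s", 1:8), rep(c("cancer", "non-cancer"), each = 4))
  corr <- list(
    intensity = matrix(1, 3, 8, dimnames = list(c("a", "b", "c"), md$sample_id)),
    features = data.frame(
      feature_id = c("a", "b", "c"),
      presence_cancer = c(0.25, 0.24, 0.20),
      presence_noncancer = c(0.00, 0.24, 0.30), stringsAsFactors = FALSE),
    metadata = md)
  class(corr) <- "corresponded_peaks"
  out <- filter_by_class_presence(corr, 0.25)
  expect_equal(out$features$feature_id, c("a", "c"))
  # 10/10 split, 2 cancer + 3 non-cancer observed -> kept via non-cancer
  md2 <- make_metadata(paste0("t", 1:20), rep(c("cancer", "non-cancer"), each = 10))
  corr2 <- corr
  corr2$metadata <- md2
  corr2$intensity <- matrix(1, 1, 20, dimnames = list("x", md2$sample_id))
  corr2$features <- data.frame(feature_id = "x", presence_cancer = 0.2,
                               presence_noncancer = 0.3,
                               stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_class_presence(corr2, 0.25)$features), 1L)
})
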