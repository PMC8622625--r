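# Category enrichment: exact hypergeometric tails against a direct pmf
# oracle and the survival function, the m/z-700 sphingolipid split, and
# the published category-level expected counts.

table1_counts <- function() {
  data.frame(
    annotation = c("FA", "GP", "PR", "SP", "SP-low", "SP-high", "ST"),
    n = c(12, 205, 5, 281, 33, 248, 23),
    k_more = c(2, 37, 0, 79, 3, 76, 13),
    k_less = c(0, 88, 0, 81, 16, 65, 3),
    stringsAsFactors = FALSE)
}

test_that("sphingolipids split at m/z 700, boundary inclusive on the high side", {
  ft <- data.frame(feature_id = c("a", "b", "c"),
                   category = c("SP", "SP", "ST"),
                   mz = c(699.9, 700.0, 650), stringsAsFactors = FALSE)
  ann <- annotate_categories(ft)
  get <- function(id) sort(ann$annotation[ann$feature_id == id])
  expect_equal(get("a"), c("SP", "SP-low"))
  expect_equal(get("b"), c("SP", "SP-high"))
  expect_equal(get("c"), "ST")
  expect_setequal(attr(ann, "universe"), c("a", "b", "c"))
  expect_error(annotate_categories(transform(ft, mz = c(1, NA, 3))),
               "without m/z")
})

test_that("multiply classified and non-lipid features leave the universe", {
  ft <- data.frame(feature_id = c("a", "b", "c", "d"),
                   category = c("GP", "multiple", "not-lipid", "ST"),
                   mz = c(700, 700, 700, 700), stringsAsFactors = FALSE)
  expect_setequal(attr(annotate_categories(ft), "universe"), c("a", "d"))
})

test_that("hypergeometric tail matches direct pmf summation and phyper", {
  # C(4,3)C(6,2)/C(10,5) + C(4,4)C(6,1)/C(10,5) = 66/252
  h <- hypergeometric_enrichment(10, 4, 5, 3)
  expect_equal(h$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(h$expected, 2)
  expect_equal(hypergeometric_enrichment(526, 131, 23, 0)$expected,
               5.728, tolerance = 5e-4)
  expect_equal(hypergeometric_enrichment(100, 10, 0, 0)$p_value, 1)
  expect_error(hypergeometric_enrichment(10, 4, 5, 6), "inconsistent")

  set.seed(61)
  for (r in 1:100) {
    N <- sample(20:400, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    expect_equal(hypergeometric_enrichment(N, K, n, k)$p_value,
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the tail probability is monotone decreasing in the overlap", {
  p <- vapply(0:10, function(k) hypergeometric_enrichment(50, 10, 20, k)$p_value,
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("expected counts over the disjoint categories sum to K per direction", {
  cnt <- table1_counts()
  tab <- run_table1_check(cnt, N = 526, K_more = 131, K_less = 173)
  base <- tab$annotation %in% c("FA", "GP", "PR", "SP", "ST")
  expect_equal(sum(tab$expected_more[base]), 131)
  expect_equal(sum(tab$expected_less[base]), 173)
})

test_that("published expected counts reproduce to three decimals", {
  tab <- run_table1_check(table1_counts(), N = 526, K_more = 131, K_less = 173)
  expect_equal(round(tab$expected_more, 3),
               c(2.989, 51.055, 1.245, 69.983, 8.219, 61.764, 5.728))
  expect_equal(round(tab$expected_less[c(1, 2, 4, 5, 6)], 3),
               c(3.947, 67.424, 92.420, 10.854, 81.567))
})

test_that("degenerate directions give unit p-values", {
  cnt <- table1_counts()
  cnt$k_more <- 0; cnt$k_less <- 0
  tab <- run_table1_check(cnt, N = 526, K_more = 0, K_less = 0)
  expect_true(all(tab$expected_more == 0))
  expect_true(all(tab$p_more == 1))
  expect_true(all(tab$p_adjust_more == 1))
})

test_that("doubling all counts preserves expected ratios and sharpens enriched rows", {
  h1 <- hypergeometric_enrichment(100, 20, 10, 6)   # enriched row
  h2 <- hypergeometric_enrichment(200, 40, 20, 12)
  expect_equal(h2$expected / 200, h1$expected / 100)
  expect_lte(h2$p_value, h1$p_value)
})

test_that("enrichment from differential results splits by fold-change direction", {
  ft <- data.frame(feature_id = paste0("f", 1:40),
                   category = rep(c("ST", "GP"), each = 20),
                   mz = rep(650, 40), stringsAsFactors = FALSE)
  diff <- data.frame(feature_id = ft$feature_id,
                     significant = c(rep(TRUE, 15), rep(FALSE, 5),
                                     rep(TRUE, 10), rep(FALSE, 10)))
  fc <- setNames(c(rep(2, 20), rep(-2, 20)), ft$feature_id)
  tab <- enrich_from_diff(diff, fc, ft)
  st_row <- tab[tab$annotation == "ST", ]
  gp_row <- tab[tab$annotation == "GP", ]
  expect_equal(st_row$observed_more, 15)
  expect_equal(st_row$observed_less, 0)
  expect_equal(gp_row$observed_less, 10)
  expect_lt(st_row$p_adjust_more, 0.01)
  expect_lt(gp_row$p_adjust_less, 0.01)
})
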