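# Differential abundance: the moderated model is cross-checked against
# per-feature OLS fits, the two-part statistic against closed forms and
# wilcox.test, and the union/fold-change logic against hand fixtures.

make_classes <- function(n_per) rep(c("cancer", "non-cancer"), each = n_per)

test_that("a feature identical in both classes has zero effect and p = 1", {
  m <- rbind(rep(3, 20), rnorm(20))
  rownames(m) <- c("flat", "noisy")
  fit <- fit_moderated_linear_model(m, make_classes(10))
  expect_equal(fit$effect[1], 0)
  expect_equal(fit$p_value[1], 1)
})

test_that("unmoderated statistics equal per-feature OLS t-tests", {
  set.seed(51)
  m <- matrix(rnorm(50 * 20), 50, 20)
  rownames(m) <- paste0("f", 1:50)
  classes <- make_classes(10)
  instrument <- rep(c("Fusion1", "Fusion2"), 10)
  fit <- fit_moderated_linear_model(m, classes, instrument)
  cls <- factor(classes, levels = c("non-cancer", "cancer"))
  for (i in seq_len(nrow(m))) {
    ols <- summary(lm(m[i, ] ~ cls + factor(instrument)))$coefficients
    expect_equal(fit$effect[i], unname(ols["clscancer", "Estimate"]),
                 tolerance = 1e-10)
    expect_equal(fit$t_ordinary[i], unname(ols["clscancer", "t value"]),
                 tolerance = 1e-10)
  }
  # shrinkage changes t but not the effect estimate
  expect_false(isTRUE(all.equal(fit$t, fit$t_ordinary)))
  expect_gt(fit$df_prior[1], 0)
})

test_that("the design rejects rank deficiency and tiny classes", {
  m <- matrix(rnorm(20), 2, 10)
  expect_error(
    fit_moderated_linear_model(m, rep(c("cancer", "non-cancer"), each = 5),
                               instrument = rep(c("A", "B"), each = 5)),
    "rank-deficient")  # instrument aliases class
  expect_error(fit_moderated_linear_model(m[, 1:3], c("cancer", "cancer", "non-cancer")),
               "fewer than 2")
})

test_that("the instrument covariate absorbs a planted batch effect", {
  # instrument partially confounded with class (as when one clinic's
  # samples dominate one instrument): omitting the covariate loads the
  # batch shift onto the disease contrast
  set.seed(52)
  nfeat <- 400; n <- 40
  classes <- make_classes(n / 2)
  instrument <- c(rep("F2", 15), rep("F1", 5), rep("F2", 5), rep("F1", 15))
  batch <- rnorm(nfeat, 0, 1)
  m <- matrix(rnorm(nfeat * n), nfeat, n) +
    outer(batch, as.integer(instrument == "F2"))
  rownames(m) <- paste0("f", seq_len(nfeat))
  with_cov <- fit_moderated_linear_model(m, classes, instrument)
  without <- fit_moderated_linear_model(m, classes)
  err_with <- mean(with_cov$p_value < 0.05)
  err_without <- mean(without$p_value < 0.05)
  expect_lt(abs(err_with - 0.05), 0.03)
  expect_gt(err_without, err_with + 0.1)  # dropping the covariate inflates
})

test_that("two-part statistic combines presence and rank-sum parts correctly", {
  # fully observed, identical values: continuous part only, tied ranks
  r <- two_part_test(rep(2, 5), rep(2, 5))
  expect_equal(unname(r["df"]), 0)  # all ties: rank variance degenerate
  expect_equal(unname(r["p_value"]), 1)
  # fully observed, same distribution: df 1 (binary part degenerate at 100%)
  set.seed(53)
  r2 <- two_part_test(rnorm(10), rnorm(10))
  expect_equal(unname(r2["df"]), 1)
  # complete separation in presence: binary part dominates
  r3 <- two_part_test(rnorm(10), rep(NA_real_, 10))
  z <- (1 - 0) / sqrt(0.5 * 0.5 * (1 / 10 + 1 / 10))
  expect_equal(unname(r3["statistic"]), z^2, tolerance = 1e-12)
  expect_lt(unname(r3["p_value"]), 0.01)
  # all missing everywhere: no information
  expect_equal(unname(two_part_test(rep(NA_real_, 3), rep(NA_real_, 3))["p_value"]), 1)
  expect_error(two_part_test(1, 1:3), "at least 2")
})

test_that("the continuous part matches wilcox.test's normal approximation", {
  set.seed(54)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  r <- two_part_test(x, y)   # fully observed: df 1, continuous only
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(unname(r["p_value"]), w$p.value, tolerance = 1e-10)
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(55)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the union of significant sets keeps per-test provenance", {
  mod <- data.frame(feature_id = paste0("f", 1:6),
                    effect = rnorm(6),
                    p_value = c(0.0001, 0.5, 0.0001, 0.9, 0.9, 0.9))
  tp <- data.frame(feature_id = paste0("f", 1:6),
                   p_value = c(0.0001, 0.0001, 0.9, 0.9, 0.9, 0.9))
  out <- differential_features(mod, tp, alpha = 0.05)
  expect_equal(out$provenance[1:4], c("both", "two-part", "moderated", "none"))
  expect_true(all(out$significant == (out$sig_moderated | out$sig_two_part)))
  expect_true(all(out$adj_p_moderated >= out$p_moderated))
  expect_error(differential_features(mod, tp[1:5, ]), "universes differ")
})

test_that("log2 fold changes are class mean differences on imputed data", {
  m <- rbind(c(rep(4, 3), rep(3, 3)), rep(2, 6))
  expect_equal(unname(log2_fold_changes(m, make_classes(3))), c(1, 0))
  m[1, 1] <- NA
  expect_error(log2_fold_changes(m, make_classes(3)), "missing")
})

test_that("clustering recovers planted sample groups and orders leaves deterministically", {
  set.seed(56)
  prof1 <- rnorm(20); prof2 <- rnorm(20)
  m <- cbind(sapply(1:6, function(i) prof1 + rnorm(20, 0, 0.05)),
             sapply(1:6, function(i) prof2 + rnorm(20, 0, 0.05)))
  colnames(m) <- paste0("s", 1:12)
  d <- 1 - correlation_matrix(m, "samples")
  diag(d) <- 0
  cl <- cluster_samples(d)
  k2 <- cutree(cl$hclust, 2)
  expect_equal(length(unique(k2[1:6])), 1L)
  expect_equal(length(unique(k2[7:12])), 1L)
  expect_false(k2[1] == k2[7])
  expect_setequal(cl$order, colnames(m))
  # identical samples merge at height zero
  dz <- matrix(1, 3, 3) - diag(3); dz[1, 2] <- dz[2, 1] <- 0
  expect_equal(min(cluster_samples(dz)$hclust$height), 0)
  expect_error(cluster_samples(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("leaves are reordered smallest-total-distance-first", {
  # three tight samples (a,b,c) and two loose ones (d,e): the tight
  # subtree has the smaller internal distance and must come first
  d <- matrix(0.9, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  d[1:3, 1:3] <- 0.05
  d[4:5, 4:5] <- 0.4
  diag(d) <- 0
  cl <- cluster_samples(d)
  expect_equal(sort(cl$order[1:3]), c("a", "b", "c"))
})
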