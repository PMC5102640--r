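test_that("enumerate_subsets emits 2^p - 1 subsets in canonical order", {
  subs <- enumerate_subsets(feature_names())
  expect_length(subs, 2047)
  expect_length(unique(vapply(subs, paste, "", collapse = "+")), 2047)
  sizes <- vapply(subs, length, integer(1))
  expect_true(all(diff(sizes) >= 0))            # ordered by size
  expect_length(enumerate_subsets("CA"), 1)
  subs3 <- enumerate_subsets(c("a", "b", "c"))
  expect_equal(vapply(subs3, paste, "", collapse = ""),
               c("a", "b", "c", "ab", "ac", "bc", "abc"))
  expect_error(enumerate_subsets(letters), "20")
})

test_that("random_subsample_split is stratified, exhaustive and seeded", {
  labels <- rep(c(0L, 1L), c(31, 30))
  sp <- random_subsample_split(labels, seed = 3)
  expect_length(sp$train, 43)                   # 22 + 21
  expect_length(sp$test, 18)                    # 9 + 9
  expect_equal(sum(labels[sp$train] == 0L), 22)
  expect_equal(sum(labels[sp$train] == 1L), 21)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(random_subsample_split(labels, seed = 3), sp)
  expect_error(random_subsample_split(c(0L, 1L, 1L)), "at least 2")
})

test_that("confusion_metrics reproduces the per-class arithmetic", {
  m <- confusion_metrics(tp = 26, tn = 26, fp = 5, fn = 4)
  expect_equal(m[["accuracy"]], 52 / 61)
  expect_equal(m[["specificity"]], 26 / 31)
  expect_equal(m[["sensitivity"]], 26 / 30)
  perfect <- confusion_metrics(tp = 30, tn = 31, fp = 0, fn = 0)
  expect_equal(unname(perfect), c(1, 1, 1))
  # random counts against direct ratios
  set.seed(12)
  for (i in 1:10) {
    cts <- rpois(4, 8) + 1
    m2 <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m2[["accuracy"]], (cts[1] + cts[2]) / sum(cts))
    expect_equal(m2[["sensitivity"]], cts[1] / (cts[1] + cts[4]))
    expect_equal(m2[["specificity"]], cts[2] / (cts[2] + cts[3]))
    # prevalence-weighted identity linking the three metrics
    npos <- cts[1] + cts[4]
    nneg <- cts[2] + cts[3]
    expect_equal(m2[["accuracy"]],
                 (m2[["sensitivity"]] * npos + m2[["specificity"]] * nneg) /
                   (npos + nneg))
  }
  expect_error(confusion_metrics(0, 5, 3, 0), "absent")
})

test_that("evaluate_subset separates separable clouds and not noise", {
  set.seed(13)
  n <- 30
  tbl <- data.frame(CA = c(rnorm(n, 0), rnorm(n, 8)),
                    CF = rnorm(2 * n))
  labels <- rep(c(0L, 1L), each = n)
  sc <- evaluate_subset(tbl, labels, "CA", n_runs = 100, seed = 5)
  expect_gt(sc$metrics$accuracy[["mean"]], 0.95)
  # label permutation -> chance (3 SE, subject-level binomial scale)
  perm <- sample(labels)
  sc0 <- evaluate_subset(tbl, perm, "CA", n_runs = 200, seed = 5)
  se <- sqrt(0.25 / (2 * n))
  expect_lt(abs(sc0$metrics$accuracy[["mean"]] - 0.5), 3 * se)
  # duplicated feature column leaves the tree's metrics unchanged
  tbl2 <- tbl
  tbl2$CA2 <- tbl$CA
  sc_dup <- evaluate_subset(tbl2, labels, c("CA", "CA2"), n_runs = 50,
                            seed = 5)
  sc_one <- evaluate_subset(tbl, labels, "CA", n_runs = 50, seed = 5)
  expect_equal(sc_dup$metrics$accuracy[["mean"]],
               sc_one$metrics$accuracy[["mean"]])
})

test_that("wrapper_search recovers a planted subset and respects counts", {
  pt <- make_planted_table(n0 = 20, n1 = 20,
                           features = c("HM", "HV", "CA", "CF"),
                           planted = c("CA", "CF"), delta = 2.5, seed = 2)
  ws <- wrapper_search(pt$features, pt$labels,
                       feature_set = c("HM", "HV", "CA", "CF"),
                       n_runs = 100, seed = 9)
  expect_equal(nrow(ws$table), 15)
  best <- strsplit(ws$table$subset[ws$best], "+", fixed = TRUE)[[1]]
  expect_true(all(c("CA", "CF") %in% best))
  # single-feature table returns the singleton
  ws1 <- wrapper_search(pt$features["CA"], pt$labels, feature_set = "CA",
                        n_runs = 50, seed = 9)
  expect_equal(ws1$table$subset, "CA")
  # per-size optima exist for each size
  expect_length(ws$per_size_best, 4)
})

test_that("averaged_roc matches brute-force threshold enumeration", {
  # perfect ranking every run -> AUC 1
  runs_s <- replicate(5, c(0.1, 0.2, 0.8, 0.9), simplify = FALSE)
  runs_l <- replicate(5, c(0L, 0L, 1L, 1L), simplify = FALSE)
  expect_equal(averaged_roc(runs_s, runs_l)$auc, 1)
  # chance ranking -> AUC near 0.5
  set.seed(14)
  rs <- replicate(300, rnorm(20), simplify = FALSE)
  rl <- replicate(300, sample(rep(0:1, 10)), simplify = FALSE)
  auc0 <- averaged_roc(rs, rl)$auc
  expect_lt(abs(auc0 - 0.5), 3 * sqrt(0.25 / 300))
  # hand-built score set: AUC equals exhaustive threshold enumeration
  sc <- c(0.2, 0.6, 0.4, 0.9)
  lb <- c(0L, 1L, 0L, 1L)
  single <- averaged_roc(list(sc), list(lb),
                         fpr_grid = seq(0, 1, length.out = 2001))
  expect_equal(single$auc, brute_force_roc_auc(sc, lb), tolerance = 1e-3)
  # monotone nondecreasing, ends at (1,1)
  expect_true(all(diff(single$points$tpr) >= 0))
  expect_equal(single$points$tpr[nrow(single$points)], 1)
  # constant scores contribute the diagonal
  diag_roc <- averaged_roc(list(rep(0.5, 10)),
                           list(rep(0:1, 5)))
  expect_equal(diag_roc$auc, 0.5, tolerance = 1e-6)
})

test_that("metric identity holds per run and means stay in [0, 1]", {
  pt <- make_planted_table(n0 = 12, n1 = 12, features = c("CA", "CF"),
                           planted = "CA", delta = 1, seed = 4)
  sc <- evaluate_subset(pt$features, pt$labels, c("CA", "CF"),
                        n_runs = 50, seed = 2)
  for (m in sc$metrics) {
    expect_gte(m[["mean"]], 0)
    expect_lte(m[["mean"]], 1)
    expect_gte(m[["sd"]], 0)
  }
})
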