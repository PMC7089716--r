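make_toy_table <- function(n = 60, p = 10, effect = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n)
  y <- rep(0:1, length.out = n)
  if (effect > 0) X[, 3] <- X[, 3] + effect * y
  tab <- tibble::as_tibble(as.data.frame(X))
  tab$label <- y
  tab
}

test_that("auc is the Mann-Whitney statistic with the expected symmetry", {
  s <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  expect_equal(auc(s, y), 0.75)
  set.seed(2)
  s2 <- stats::rnorm(40)
  y2 <- rep(0:1, 20)
  expect_equal(auc(s2, y2), 1 - auc(-s2, y2))
  expect_error(auc(s, c(0, 0, 0, 0)), "both classes")
})

test_that("gini ranking puts an informative feature first", {
  cfg <- classify_config(n_trees = 150)
  hits <- vapply(1:20, function(seed) {
    tab <- make_toy_table(seed = seed)
    rank_by_gini(tab, cfg, seed = seed)$feature[1] == "V3"
  }, TRUE)
  expect_gte(sum(hits), 18)
  # pure noise: no feature dominates the top rank
  tops <- vapply(1:20, function(seed) {
    tab <- make_toy_table(effect = 0, seed = 100 + seed)
    rank_by_gini(tab, cfg, seed = seed)$feature[1]
  }, "")
  expect_lte(max(table(tops)), 8)
  # deterministic given a seed
  tab <- make_toy_table()
  expect_identical(rank_by_gini(tab, cfg, seed = 5),
                   rank_by_gini(tab, cfg, seed = 5))
})

test_that("forward selection keeps the informative feature, ties go small", {
  cfg <- classify_config(n_trees = 100)
  tab <- make_toy_table(effect = 3)
  rk <- rank_by_gini(tab, cfg, seed = 3)
  sel <- forward_select(tab, rk$feature, cfg, seed = 3, max_prefix = 6)
  expect_true("V3" %in% sel$features)
  # identical perfectly-separating columns: smallest prefix wins the tie
  sep <- tibble::tibble(a = rep(c(0, 1), each = 10),
                        b = rep(c(0, 1), each = 10),
                        c = rep(c(0, 1), each = 10),
                        label = rep(0:1, each = 10))
  sel2 <- forward_select(sep, c("a", "b", "c"), cfg, seed = 4)
  expect_equal(sel2$size, 1)
  expect_identical(forward_select(tab, rk$feature, cfg, seed = 9, max_prefix = 4),
                   forward_select(tab, rk$feature, cfg, seed = 9, max_prefix = 4))
  expect_error(forward_select(tab, c("nope"), cfg), "absent")
})

test_that("random forest separates a separable toy set and honors mtry rule", {
  expect_equal(max(1L, round(sqrt(28))), 5)
  cfg <- classify_config(n_trees = 200)
  set.seed(11)
  tr <- tibble::tibble(f1 = c(stats::runif(15, -3, -1), stats::runif(15, 1, 3)),
                       f2 = stats::rnorm(30),
                       label = rep(0:1, each = 15))
  te <- tibble::tibble(f1 = c(stats::runif(10, -3, -1), stats::runif(10, 1, 3)),
                       f2 = stats::rnorm(20),
                       label = rep(0:1, each = 10))
  pred <- hf_rf_fit_predict(tr, te, cfg, seed = 1)
  expect_equal(attr(pred, "auc"), 1.0)
  expect_error(hf_rf_fit_predict(tr, te[, c("f2", "label")], cfg), "differ")
})

test_that("label permutation drives AUC to chance", {
  tab <- make_toy_table(effect = 3, seed = 6)
  set.seed(7)
  tab$label <- sample(tab$label)
  cv <- twofold_cv(tab, classify_config(n_trees = 100), n_runs = 10, seed = 8)
  expect_gte(cv$auc_mean, 0.35)
  expect_lte(cv$auc_mean, 0.65)
})

test_that("two-fold cross-validation summarizes swapped-fold AUCs", {
  sep <- tibble::tibble(f = c(stats::rnorm(12, -4), stats::rnorm(12, 4)),
                        label = rep(0:1, each = 12))
  cv <- twofold_cv(sep, classify_config(n_trees = 100), n_runs = 7, seed = 2)
  expect_length(cv$per_run_aucs, 7)
  expect_equal(cv$auc_mean, 1.0)
  expect_equal(cv$auc_std, 0.0)
  # summary is exactly the per-run statistics
  expect_equal(cv$auc_mean, mean(cv$per_run_aucs))
  expect_equal(cv$auc_std, stats::sd(cv$per_run_aucs))
  td <- tidy(cv)
  expect_equal(nrow(td), 7)
  gl <- glance(cv)
  expect_named(gl, c("auc_mean", "auc_std", "n_runs"))
  expect_error(twofold_cv(sep[1:3, ], n_runs = 2), "4 samples")
})

test_that("cohort feature tables are well-formed and channel-selectable", {
  coh <- cohort_small()
  ft <- cohort_features(coh, levels = 8L, seed = 1)
  expect_equal(nrow(ft), 16)
  expect_equal(ncol(ft), 2 + 5 * 28)
  expect_false(anyNA(ft))
  e35 <- select_channels(ft, "E35")
  expect_equal(ncol(e35), 2 + 28)
  fd <- cohort_features(coh, scheme = "difference", levels = 8L, seed = 1)
  expect_equal(ncol(fd), 2 + 4 * 28)
  expect_true(any(grepl("^D35_45_", names(fd))))
  fv <- cohort_features(coh, input = "voxel-summary", seed = 1)
  expect_equal(ncol(fv), 2 + 5 * 5)
})
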