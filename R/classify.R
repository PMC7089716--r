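#' Area under the ROC curve
#'
#' Mann-Whitney form with midrank tie handling.
#' @param scores numeric scores (larger = more positive-like).
#' @param labels binary labels (logical, 0/1, or two-level factor/character
#'   whose second sorted level is the positive class).
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("labels must be binary", call. = FALSE)
  as.integer(as.character(labels) == lv[2])
}

#' Classifier configuration
#'
#' Defaults follow the texture-classification protocol: 3000 trees and
#' `round(sqrt(p))` candidate features per node (5 for the 28-feature
#' descriptor). Reduce `n_trees` for speed in exploratory runs.
#'
#' @param n_trees number of trees.
#' @param mtry per-node candidate feature count; NULL for `round(sqrt(p))`.
#' @param min_node minimum samples per child node.
#' @export
classify_config <- function(n_trees = 3000L, mtry = NULL, min_node = 1L) {
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node)),
            class = "classify_config")
}

check_feature_table <- function(table) {
  if (!"label" %in% names(table))
    stop("feature table needs a `label` column", call. = FALSE)
  feats <- setdiff(names(table), c("label", "id"))
  if (!length(feats)) stop("no feature columns", call. = FALSE)
  X <- as.matrix(table[feats])
  if (anyNA(X)) stop("feature table contains missing values", call. = FALSE)
  y <- as_binary_labels(table$label)
  if (min(table(y)) < 2) stop("need >= 2 samples per class", call. = FALSE)
  list(X = X, y = y, features = feats)
}

fit_forest <- function(X, y, cfg, seed) {
  mtry <- cfg$mtry %||% max(1L, round(sqrt(ncol(X))))
  local_seed(seed,
    rf_fit_cpp(X, as.integer(y), cfg$n_trees, as.integer(mtry), cfg$min_node))
}

#' Rank features by Gini importance
#'
#' Fits a seeded random forest on the whole table and orders features by
#' mean decrease in Gini impurity, the priority measure used ahead of
#' forward selection.
#'
#' @param table tibble/data.frame with a binary `label` column (and
#'   optional `id`), all other columns numeric features.
#' @param cfg a [classify_config()].
#' @param seed integer seed.
#' @return tibble: `feature`, `importance`, `rank` (importance-descending;
#'   ties broken by original column order).
#' @export
rank_by_gini <- function(table, cfg = classify_config(), seed = 1L) {
  ft <- check_feature_table(table)
  fit <- fit_forest(ft$X, ft$y, cfg, seed)
  ord <- order(-fit$importance, seq_along(fit$importance))
  tibble::tibble(feature = ft$features[ord],
                 importance = fit$importance[ord],
                 rank = seq_along(ord))
}

#' Forward stepwise feature selection on a Gini ranking
#'
#' Evaluates nested prefixes of the ranked feature list by out-of-bag AUC
#' and returns the prefix with the highest score; exact ties go to the
#' smallest prefix.
#'
#' @param table feature table (see [rank_by_gini()]).
#' @param ranking character vector of features in priority order
#'   (typically `rank_by_gini(...)$feature`).
#' @param cfg a [classify_config()].
#' @param seed integer seed.
#' @param max_prefix optional cap on evaluated prefix length.
#' @return list: `features` (selected prefix), `oob_auc` (per-prefix
#'   scores), `size`.
#' @export
forward_select <- function(table, ranking, cfg = classify_config(), seed = 1L,
                           max_prefix = length(ranking)) {
  ft <- check_feature_table(table)
  if (!all(ranking %in% ft$features))
    stop("ranking names features absent from the table", call. = FALSE)
  sizes <- seq_len(min(max_prefix, length(ranking)))
  oob_auc <- vapply(sizes, function(s) {
    fit <- fit_forest(ft$X[, ranking[seq_len(s)], drop = FALSE], ft$y, cfg,
                      derive_seed(seed, paste0("prefix", s)))
    ok <- !is.na(fit$oob_scores)
    auc(fit$oob_scores[ok], ft$y[ok])
  }, 0)
  best <- which.max(oob_auc)   # first maximum = smallest prefix on ties
  list(features = ranking[seq_len(best)], oob_auc = oob_auc, size = best)
}

#' Fit a random forest on a training table and score a test table
#'
#' @param train,test feature tables with identical feature columns.
#' @param cfg a [classify_config()].
#' @param seed integer seed.
#' @return tibble with `score` (class-1 probability), `label` for the test
#'   rows, plus an `auc` attribute.
#' @export
hf_rf_fit_predict <- function(train, test, cfg = classify_config(), seed = 1L) {
  ftr <- check_feature_table(train)
  fte <- check_feature_table(test)
  if (!identical(ftr$features, fte$features))
    stop("train and test feature columns differ", call. = FALSE)
  fit <- fit_forest(ftr$X, ftr$y, cfg, seed)
  scores <- rf_predict_cpp(fit$trees, fte$X)
  out <- tibble::tibble(score = scores, label = test$label)
  attr(out, "auc") <- auc(scores, fte$y)
  out
}

stratified_halves <- function(y) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(1:2, length(idx))
  }
  fold
}

#' Two-fold cross-validation with swapped folds, repeated
#'
#' Each run randomly (stratified) splits the cohort in half, trains on one
#' half and scores the other, swaps the roles, and averages the two AUCs;
#' the mean and standard deviation over `n_runs` runs summarize
#' performance.
#'
#' @param table feature table.
#' @param cfg a [classify_config()].
#' @param n_runs number of repeated runs (protocol default 100).
#' @param seed integer seed.
#' @return object of class `cv_result`: `auc_mean`, `auc_std`, `n_runs`,
#'   `per_run_aucs`.
#' @export
twofold_cv <- function(table, cfg = classify_config(), n_runs = 100L,
                       seed = 1L) {
  ft <- check_feature_table(table)
  if (nrow(table) < 4) stop("need at least 4 samples", call. = FALSE)
  per_run <- local_seed(seed, vapply(seq_len(n_runs), function(run) {
    fold <- stratified_halves(ft$y)
    fold_auc <- vapply(1:2, function(f) {
      tr <- fold != f
      fit <- fit_forest(ft$X[tr, , drop = FALSE], ft$y[tr], cfg,
                        derive_seed(seed, paste0("run", run, "f", f)))
      auc(rf_predict_cpp(fit$trees, ft$X[!tr, , drop = FALSE]), ft$y[!tr])
    }, 0)
    mean(fold_auc)
  }, 0))
  structure(list(auc_mean = mean(per_run), auc_std = sd(per_run),
                 n_runs = as.integer(n_runs), per_run_aucs = per_run),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> AUC %.3f +/- %.3f over %d two-fold runs\n",
              x$auc_mean, x$auc_std, x$n_runs))
  invisible(x)
}

#' Tidy a cross-validation result
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(run = seq_len(x$n_runs), auc = x$per_run_aucs)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(auc_mean = x$auc_mean, auc_std = x$auc_std, n_runs = x$n_runs)
}

#' Generic tidiers
#' @param x object to tidy.
#' @param ... passed on.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

summary_feature_names <- c("hu_mean", "hu_sd", "hu_p10", "hu_p90", "hu_iqr")

voxel_summary <- function(v) {
  q <- quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  out <- c(mean(v), sd(v), q[1], q[4], q[3] - q[2])
  names(out) <- summary_feature_names
  out
}

#' Extract per-lesion feature tables from a synthetic cohort
#'
#' Synthesizes the multi-energy image of every lesion, then per channel
#' (or per neighboring-channel difference image) computes either the
#' 28-entry Haralick descriptor inside the lesion mask or a first-order
#' voxel-summary baseline (mean, sd, 10th/90th percentiles, IQR). Columns
#' are prefixed by the channel energy (`E35_`...) or difference pair
#' (`D35_45_`...); multi-channel inputs are formed downstream by selecting
#' column prefixes.
#'
#' @param cohort a [make_lesion_cohort()] result.
#' @param energies_keV channel energies.
#' @param table an [energy_response_table()].
#' @param input "descriptor" (texture) or "voxel-summary" (baseline).
#' @param scheme "raw" channels or "difference" images.
#' @param levels gray levels for quantization.
#' @param displacement GLCM displacement.
#' @param noise_hu observation noise added at synthesis.
#' @param seed integer seed.
#' @return tibble: `id`, `label`, then one column per (channel, feature).
#' @export
cohort_features <- function(cohort, energies_keV = c(35, 45, 55, 65, 75),
                            table = default_response_table(),
                            input = c("descriptor", "voxel-summary"),
                            scheme = c("raw", "difference"),
                            levels = 32L, displacement = 1L,
                            noise_hu = 0, seed = 1L) {
  input <- match.arg(input)
  scheme <- match.arg(scheme)
  rows <- lapply(seq_along(cohort$samples), function(i) {
    s <- cohort$samples[[i]]
    img <- synthesize_spectral(s$volume, energies_keV, table,
                               noise_hu = noise_hu,
                               seed = derive_seed(seed, s$id))
    if (scheme == "difference") {
      img2 <- difference_images(img)
      prefixes <- paste0("D", gsub("-", "_", attr(img2, "pairs")))
      img <- img2
    } else {
      prefixes <- paste0("E", energies_keV)
    }
    mask <- s$volume$labels > 0L
    feats <- unlist(lapply(seq_along(prefixes), function(c) {
      ch <- channel(img, c)
      vox <- ch[mask]
      f <- if (input == "descriptor") {
        # ROI min-max quantization: bin edges from in-mask voxels only
        descriptor(quantize(ch, levels, range = range(vox)), mask,
                   displacement, levels)
      } else voxel_summary(vox)
      names(f) <- paste0(prefixes[c], "_", names(f))
      f
    }))
    c(list(id = s$id, label = s$label), as.list(feats))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE))))
}

#' Restrict a cohort feature table to one or more channel prefixes
#' @param table a [cohort_features()] table.
#' @param prefixes e.g. `"E35"` or `c("E35", "E75")`; NULL keeps all.
#' @export
select_channels <- function(table, prefixes = NULL) {
  if (is.null(prefixes)) return(table)
  keep <- names(table) %in% c("id", "label") |
    Reduce(`|`, lapply(paste0("^", prefixes, "_"), grepl, x = names(table)))
  table[keep]
}
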