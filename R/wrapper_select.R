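#' Enumerate all non-empty feature subsets
#'
#' @param features Character vector of feature names (at most 20).
#' @return List of character vectors, ordered by subset size then
#'   lexicographically in the order of `features`; length `2^p - 1`.
#' @export
enumerate_subsets <- function(features = feature_names()) {
  p <- length(features)
  if (p < 1 || p > 20) stop("between 1 and 20 features are supported")
  out <- vector("list", 2^p - 1)
  i <- 0L
  for (size in seq_len(p)) {
    idx <- utils::combn(p, size)
    for (k in seq_len(ncol(idx))) {
      i <- i + 1L
      out[[i]] <- features[idx[, k]]
    }
  }
  out
}

#' Stratified 70/30 random subsampling split
#'
#' Draws `train_frac` of each class (rounded to nearest, capped so at
#' least one member of each class remains in the test set) into the
#' training set; the remainder is the test set.
#'
#' @param labels 0/1 integer labels (1 = positive class).
#' @param train_frac Training fraction (default 0.70).
#' @param seed Optional RNG seed for a reproducible split.
#' @return List with integer index vectors `train` and `test`.
#' @export
random_subsample_split <- function(labels, train_frac = 0.70, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.integer(labels)
  if (any(tabulate(labels + 1L, 2L) < 2L)) {
    stop("each class needs at least 2 members")
  }
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    n_tr <- min(length(idx) - 1L, max(1L, round(train_frac * length(idx))))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`. TBI is the positive class.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("metrics undefined: a class is absent from the test set")
  }
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

# deterministic per-run seed sequence shared across subsets (paired
# comparisons through common random numbers); kept below 2^31
run_seed_sequence <- function(seed, n_runs) {
  (as.numeric(seed) * 48271 + 104729 * seq_len(n_runs)) %% 2147483647
}

#' Score one feature subset by repeated random-subsampling classification
#'
#' For each run: a stratified 70/30 split, classifier training on the
#' subset's columns (`HDFT` expands to its magnitude columns), prediction
#' on the held-out subjects, confusion metrics. Reports mean and SD of
#' each metric over runs. Run seeds are derived from the master seed
#' only, so different subsets see identical splits.
#'
#' @param features Data frame or matrix of feature columns (named as in
#'   [expand_feature_columns()]).
#' @param labels 0/1 labels (1 = TBI).
#' @param subset Character vector of atomic feature names.
#' @param classifier Classifier spec for [train_classifier()].
#' @param n_runs Number of subsampling runs (the study protocol uses 1000).
#' @param seed Master seed.
#' @param train_frac Training fraction.
#' @param n_coeff HDFT dimensionality used in column expansion.
#' @param keep_scores Keep per-run test scores/labels for ROC averaging.
#' @param ... Extra classifier options.
#' @return A `subset_score`: list with `subset`, `size`, `metrics`
#'   (mean/sd per metric), `n_runs`, `n_failed`, and optionally
#'   `run_scores`/`run_labels`.
#' @export
evaluate_subset <- function(features, labels, subset,
                            classifier = "decision_tree", n_runs = 1000,
                            seed = 1, train_frac = 0.70, n_coeff = 3,
                            keep_scores = FALSE, ...) {
  stopifnot(length(subset) >= 1)
  cols <- expand_feature_columns(subset, n_coeff)
  X <- as.matrix(as.data.frame(features)[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.integer(labels)
  seeds <- run_seed_sequence(seed, n_runs)
  acc <- sens <- spc <- rep(NA_real_, n_runs)
  run_scores <- if (keep_scores) vector("list", n_runs) else NULL
  run_labels <- if (keep_scores) vector("list", n_runs) else NULL
  n_failed <- 0L
  for (r in seq_len(n_runs)) {
    res <- tryCatch({
      split <- random_subsample_split(y, train_frac, seed = seeds[r])
      model <- train_classifier(classifier, X[split$train, , drop = FALSE],
                                y[split$train], ...)
      score <- predict(model, X[split$test, , drop = FALSE])
      ytest <- y[split$test]
      pos <- score > model$threshold
      m <- confusion_metrics(tp = sum(pos & ytest == 1L),
                             tn = sum(!pos & ytest == 0L),
                             fp = sum(pos & ytest == 0L),
                             fn = sum(!pos & ytest == 1L))
      list(m = m, score = score, ytest = ytest)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    acc[r] <- res$m["accuracy"]
    sens[r] <- res$m["sensitivity"]
    spc[r] <- res$m["specificity"]
    if (keep_scores) {
      run_scores[[r]] <- res$score
      run_labels[[r]] <- res$ytest
    }
  }
  if (n_failed > 0.01 * n_runs) {
    stop(n_failed, " of ", n_runs, " runs failed (> 1%)")
  }
  metrics <- list(
    accuracy = c(mean = mean(acc, na.rm = TRUE), sd = sd_or0(acc)),
    sensitivity = c(mean = mean(sens, na.rm = TRUE), sd = sd_or0(sens)),
    specificity = c(mean = mean(spc, na.rm = TRUE), sd = sd_or0(spc)))
  structure(list(subset = subset, size = length(subset), metrics = metrics,
                 n_runs = n_runs, n_failed = n_failed,
                 run_scores = run_scores, run_labels = run_labels),
            class = "subset_score")
}

sd_or0 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) 0 else stats::sd(x)
}

#' Exhaustive wrapper feature-subset search
#'
#' Evaluates every non-empty subset of the supplied features with
#' [evaluate_subset()] and reports the ranking, the best subset of each
#' size and the global optimum. Ties break toward the smaller subset,
#' then lexicographically (the enumeration order).
#'
#' @inheritParams evaluate_subset
#' @param feature_set Atomic feature names to search over.
#' @return A `wrapper_search` result: `table` (one row per subset with
#'   mean/SD metrics), `per_size_best` and `best` row indices, and the
#'   call parameters.
#' @export
wrapper_search <- function(features, labels,
                           feature_set = feature_names(),
                           classifier = "decision_tree", n_runs = 1000,
                           seed = 1, train_frac = 0.70, n_coeff = 3, ...) {
  subsets <- enumerate_subsets(feature_set)
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sc <- evaluate_subset(features, labels, subsets[[i]], classifier,
                          n_runs, seed, train_frac, n_coeff, ...)
    rows[[i]] <- data.frame(
      subset = paste(sc$subset, collapse = "+"), size = sc$size,
      acc_mean = sc$metrics$accuracy["mean"],
      acc_sd = sc$metrics$accuracy["sd"],
      sens_mean = sc$metrics$sensitivity["mean"],
      sens_sd = sc$metrics$sensitivity["sd"],
      spec_mean = sc$metrics$specificity["mean"],
      spec_sd = sc$metrics$specificity["sd"],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  per_size <- vapply(sort(unique(tab$size)), function(s) {
    idx <- which(tab$size == s)
    idx[which.max(tab$acc_mean[idx])]   # first max = lexicographic tie-break
  }, integer(1))
  best <- which.max(tab$acc_mean)       # enumeration order favors small size
  structure(list(table = tab, per_size_best = per_size, best = best,
                 subsets = subsets, classifier = classifier,
                 n_runs = n_runs, seed = seed),
            class = "wrapper_search")
}

#' Vertically averaged ROC curve over subsampling runs
#'
#' Per run, the ROC staircase over all score thresholds is computed; the
#' true-positive rate is then averaged across runs at each point of a
#' fixed false-positive-rate grid, and the AUC is the trapezoidal area
#' under the averaged curve. Runs with constant scores contribute the
#' chance diagonal.
#'
#' @param run_scores List of per-run score vectors (test subjects).
#' @param run_labels List of matching 0/1 label vectors.
#' @param fpr_grid Grid of false-positive rates (default 101 points).
#' @return A `roc_curve`: data.frame `points` (fpr, tpr) and scalar `auc`.
#' @export
averaged_roc <- function(run_scores, run_labels,
                         fpr_grid = seq(0, 1, length.out = 101)) {
  keep <- !vapply(run_scores, is.null, logical(1))
  run_scores <- run_scores[keep]
  run_labels <- run_labels[keep]
  stopifnot(length(run_scores) >= 1,
            length(run_scores) == length(run_labels))
  tpr_mat <- vapply(seq_along(run_scores), function(i) {
    roc_interpolate(run_scores[[i]], run_labels[[i]], fpr_grid)
  }, numeric(length(fpr_grid)))
  tpr <- rowMeans(tpr_mat)         # staircase always reaches (1,1); the
                                   # (0,0) anchor is part of every staircase
  auc <- sum(diff(fpr_grid) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr_grid, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' Single-run ROC points over all score thresholds
#'
#' @param scores Continuous positive-class scores.
#' @param labels 0/1 labels.
#' @return data.frame with columns `fpr`, `tpr`, sorted by `fpr`, starting
#'   at (0,0) and ending at (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  stopifnot(np > 0, nn > 0)
  if (length(unique(scores)) == 1L) {
    return(data.frame(fpr = c(0, 1), tpr = c(0, 1)))   # chance diagonal
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cut after each block of tied scores
  block_end <- which(diff(s) != 0)
  ends <- c(block_end, length(s))
  tp <- cumsum(y)[ends]
  fp <- ends - cumsum(y)[ends]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

roc_interpolate <- function(scores, labels, fpr_grid) {
  pts <- roc_points(scores, labels)
  if (nrow(pts) == 2 && all(pts$fpr == c(0, 1)) && all(pts$tpr == c(0, 1))) {
    return(fpr_grid)               # diagonal contribution
  }
  # follow the ordered operating-point path: between consecutive distinct
  # FPRs, interpolate from the top of the left vertical run to the bottom
  # of the right one (horizontal for a pure staircase, diagonal when both
  # rates move together); the trapezoid of this curve equals the standard
  # empirical AUC of the point sequence
  by_fpr <- split(pts$tpr, pts$fpr)
  u <- as.numeric(names(by_fpr))
  top <- vapply(by_fpr, max, numeric(1))
  bot <- vapply(by_fpr, min, numeric(1))
  if (u[length(u)] < 1) {
    u <- c(u, 1)
    top <- c(top, 1)
    bot <- c(bot, 1)
  }
  idx <- findInterval(fpr_grid, u)
  idx[idx < 1] <- 1L
  vapply(seq_along(fpr_grid), function(k) {
    i <- idx[k]
    g <- fpr_grid[k]
    if (i >= length(u)) return(top[length(u)])
    if (g <= u[i]) return(top[i])
    top[i] + (bot[i + 1] - top[i]) * (g - u[i]) / (u[i + 1] - u[i])
  }, numeric(1))
}

#' Task-load comparison with a fixed feature subset
#'
#' Reruns trial screening, feature extraction and subset evaluation for
#' each task condition using one fixed (typically the optimal) feature
#' subset, mirroring the comparison of classification performance across
#' task loads.
#'
#' @param hemo_list List of preprocessed `hemo_signals` (one per subject).
#' @param subset Atomic feature names to use.
#' @param conditions Conditions to compare.
#' @inheritParams evaluate_subset
#' @param reject Apply the trial screen.
#' @param reject_threshold Channel pruning threshold.
#' @return data.frame with one row per condition: n_subjects, accuracy,
#'   sensitivity, specificity (mean and SD); a condition with no
#'   analysable subjects is reported with NA metrics.
#' @export
task_load_comparison <- function(hemo_list, subset,
                                 conditions = c("Font", "LowComplexity",
                                                "HighComplexity"),
                                 classifier = "decision_tree",
                                 n_runs = 1000, seed = 1, n_coeff = 3,
                                 reject = TRUE, reject_threshold = 0.80,
                                 ...) {
  rows <- lapply(conditions, function(cond) {
    ft <- feature_table(hemo_list, condition = cond, reject = reject,
                        reject_threshold = reject_threshold,
                        n_coeff = n_coeff)
    na_row <- data.frame(condition = cond, n_subjects = nrow(ft$temporal),
                         acc_mean = NA_real_, acc_sd = NA_real_,
                         sens_mean = NA_real_, sens_sd = NA_real_,
                         spec_mean = NA_real_, spec_sd = NA_real_)
    if (is.null(ft$temporal) || nrow(ft$temporal) < 4 ||
        length(unique(ft$labels)) < 2) {
      na_row$n_subjects <- if (is.null(ft$temporal)) 0L else
        nrow(ft$temporal)
      return(na_row)
    }
    sc <- evaluate_subset(ft$temporal, ft$labels, subset, classifier,
                          n_runs, seed, n_coeff = n_coeff, ...)
    data.frame(condition = cond, n_subjects = nrow(ft$temporal),
               acc_mean = sc$metrics$accuracy["mean"],
               acc_sd = sc$metrics$accuracy["sd"],
               sens_mean = sc$metrics$sensitivity["mean"],
               sens_sd = sc$metrics$sensitivity["sd"],
               spec_mean = sc$metrics$specificity["mean"],
               spec_sd = sc$metrics$specificity["sd"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
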