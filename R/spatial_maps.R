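#' Spatio-temporal single-feature classification
#'
#' Classifies subjects from the per-channel values of one feature at a
#' time (up to 16 values per subject, NA where the channel was pruned),
#' using the same repeated random-subsampling protocol as the temporal
#' wrapper. The decision tree handles the missing entries natively; LDA
#' and the SVM fall back to training-mean imputation.
#'
#' @param spatio Subjects x (channel x column) matrix from
#'   [feature_table()] (`spatiotemporal` element).
#' @param labels 0/1 labels (1 = TBI).
#' @param features Atomic feature names to evaluate (default all 11).
#' @param max_missing A feature whose columns exceed this overall missing
#'   fraction is reported as not evaluable (default 0.9).
#' @inheritParams evaluate_subset
#' @return data.frame, one row per feature, with mean/SD accuracy,
#'   sensitivity and specificity and the missing fraction; not-evaluable
#'   features carry NA metrics.
#' @export
classify_spatiotemporal <- function(spatio, labels,
                                    features = feature_names(),
                                    classifier = "decision_tree",
                                    n_runs = 1000, seed = 1, n_coeff = 3,
                                    max_missing = 0.9, ...) {
  rows <- lapply(features, function(f) {
    cols <- as.vector(outer(expand_feature_columns(f, n_coeff),
                            channel_names(),
                            function(x, ch) paste(ch, x, sep = ".")))
    cols <- intersect(cols, colnames(spatio))
    X <- spatio[, cols, drop = FALSE]
    miss <- mean(is.na(X))
    if (miss > max_missing) {
      return(data.frame(feature = f, missing_frac = miss,
                        acc_mean = NA_real_, acc_sd = NA_real_,
                        sens_mean = NA_real_, sens_sd = NA_real_,
                        spec_mean = NA_real_, spec_sd = NA_real_))
    }
    sc <- evaluate_subset(X, labels, subset = cols, classifier = classifier,
                          n_runs = n_runs, seed = seed, n_coeff = n_coeff,
                          ...)
    data.frame(feature = f, missing_frac = miss,
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

#' Population activity map for one spatio-temporal feature
#'
#' Missing-aware per-channel mean of a feature across the subjects of one
#' population, with the number of contributing subjects per channel.
#'
#' @param spatio Spatio-temporal matrix from [feature_table()].
#' @param feature Atomic feature name (scalar features only).
#' @param rows Logical or integer subject selector (the population).
#' @return An `activity_map`: data.frame with `channel`, `mean`, `n`;
#'   channels with no contributor carry NA means.
#' @export
activity_map <- function(spatio, feature, rows = TRUE) {
  cols <- paste(channel_names(), feature, sep = ".")
  missing_cols <- setdiff(cols, colnames(spatio))
  if (length(missing_cols)) {
    stop("feature columns not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- spatio[rows, cols, drop = FALSE]
  if (nrow(X) == 0) stop("empty population")
  m <- colMeans(X, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  structure(data.frame(
    channel = channel_names(),
    mean = m,
    n = colSums(!is.na(X)),
    row.names = NULL
  ), class = c("activity_map", "data.frame"))
}

#' Default channel-to-hemisphere layout
#'
#' The study montage's channel coordinates are not published; this
#' synthetic stand-in assigns channels 1-8 to the left hemisphere and
#' 9-16 to the right, matching the generator's lateralized effects.
#' @return Named character vector, one of `"left"`/`"right"` per channel.
#' @export
default_layout <- function() {
  stats::setNames(rep(c("left", "right"), each = 8), channel_names())
}

#' Hemispheric contrast of an activity map
#'
#' @param map An [activity_map()].
#' @param layout Named hemisphere assignment per channel.
#' @return List with `left`, `right` (missing-aware hemisphere means) and
#'   `difference` (left - right).
#' @export
hemisphere_contrast <- function(map, layout = default_layout()) {
  if (!all(map$channel %in% names(layout))) {
    stop("layout is missing channels: ",
         paste(setdiff(map$channel, names(layout)), collapse = ", "))
  }
  side <- layout[map$channel]
  left <- mean(map$mean[side == "left"], na.rm = TRUE)
  right <- mean(map$mean[side == "right"], na.rm = TRUE)
  list(left = left, right = right, difference = left - right)
}
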