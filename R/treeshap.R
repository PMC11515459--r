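#' Exact per-class SHAP values for a ranger probability forest
#'
#' Computes exact path-dependent tree SHAP values for every test sample,
#' feature and class. Within each tree the conditional expectation given
#' a feature subset follows the split when the feature is in the subset
#' and otherwise averages the children weighted by their in-bag cover;
#' Shapley values over the features the tree uses are obtained by direct
#' subset enumeration (exact; trees grown on a handful of samples use at
#' most a few features). Values average over trees, so local accuracy
#' holds: for every test sample and class,
#' `base + sum(shap) = predicted class probability`.
#'
#' @param rf A `ranger` fit with `probability = TRUE` and
#'   `keep.inbag = TRUE`.
#' @param x_train Training feature matrix the forest was grown on
#'   (same row order as the in-bag counts).
#' @param x_test Feature matrix of samples to explain.
#' @return List with `values` (tibble: `sample`, `class`, `protein`,
#'   `value`), `base` (named per-class base values), and `predicted`
#'   (tibble of per-class predicted probabilities per sample).
#' @export
treeshap_ranger <- function(rf, x_train, x_test) {
  if (!inherits(rf, "ranger")) abort("`rf` must be a ranger model.")
  f <- rf$forest
  if (is.null(f) || f$treetype != "Probability estimation") {
    abort("`rf` must be a probability forest (probability = TRUE).")
  }
  if (is.null(rf$inbag.counts)) {
    abort("`rf` must be fitted with keep.inbag = TRUE.")
  }
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  feats <- f$independent.variable.names
  x_train <- x_train[, feats, drop = FALSE]
  x_test <- x_test[, feats, drop = FALSE]

  res <- treeshap_forest_cpp(
    lapply(f$child.nodeIDs, `[[`, 1L),
    lapply(f$child.nodeIDs, `[[`, 2L),
    f$split.varIDs, f$split.values, f$terminal.class.counts,
    rf$inbag.counts, x_train, x_test)

  classes <- f$levels[f$class.values]
  samples <- rownames(x_test) %||% as.character(seq_len(nrow(x_test)))
  values <- tibble::tibble(
    sample = rep(samples, each = length(classes) * length(feats)),
    protein = rep(rep(feats, each = length(classes)), times = nrow(x_test)),
    class = rep(classes, times = length(feats) * nrow(x_test)),
    value = as.vector(res$shap))
  predicted <- tibble::as_tibble(t(res$pred), .name_repair = ~classes)
  predicted <- dplyr::bind_cols(tibble::tibble(sample = samples), predicted)
  list(values = values,
       base = stats::setNames(as.numeric(res$base), classes),
       predicted = predicted)
}
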