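#' Fit the package's random forest
#'
#' Binary-classification CART forest (Gini splits, bootstrap resampling,
#' per-node feature subsampling). Returns impurity-based feature importance,
#' out-of-bag class-1 vote fractions for the training rows, and vote
#' fractions for optional test rows. Draws from R's RNG stream, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param X numeric matrix, rows = samples.
#' @param y binary labels: 0/1 vector or two-level factor (second level is
#'   the positive class).
#' @param ntree number of trees.
#' @param Xtest optional matrix with the same columns as `X`.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples per leaf.
#' @param max_depth depth cap.
#' @return list(importance (named, sums to 1 when any split occurred),
#'   oob_prob, test_prob).
#' @export
rf_fit <- function(X, y, ntree = 500, Xtest = NULL, mtry = NULL,
                   min_node = 1, max_depth = 25) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(y) == nrow(X))
  if (length(unique(y)) < 2L)
    stop("rf_fit: both classes must be present")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (is.null(Xtest)) Xtest <- X[0, , drop = FALSE]
  fit <- rf_fit_cpp(X, y, as.matrix(Xtest), as.integer(ntree),
                    as.integer(mtry), as.integer(min_node),
                    as.integer(max_depth))
  imp <- fit$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  list(importance = imp, oob_prob = fit$oob_prob, test_prob = fit$test_prob)
}
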