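# Diagnostic-modelling protocol: random-forest feature ranking, elbow-point
# candidate cutoff, AIC forward selection over cumulative top-ranked subsets,
# stratified 5-fold cross-validation repeated 5 times with per-fold selection
# and majority-undersampled training, and per-participant majority voting.

#' Build a participant x feature matrix from a measure table
#'
#' Pivots the long measure table wide for one task and one binary contrast
#' (a PD severity group vs controls). Feature sets: `trial1` and `trial2`
#' use one trial's measures; `both` uses trial-1 columns, trial-2 columns and
#' their per-feature means. Missing values are imputed with the column
#' median; all-missing or constant columns are dropped.
#'
#' @param measures long measure table (see [extract_all()]).
#' @param task task label to use.
#' @param positive_group group treated as class 1.
#' @param control_group group treated as class 0.
#' @param feature_set one of `"trial1"`, `"trial2"`, `"both"`.
#' @return list(X = matrix, y = 0/1 integer vector, participant_id).
#' @export
build_feature_matrix <- function(measures, task, positive_group,
                                 control_group = "control",
                                 feature_set = c("trial1", "trial2",
                                                 "both")) {
  feature_set <- match.arg(feature_set)
  sub <- measures[measures$task == task &
                    measures$group %in% c(positive_group, control_group), ]
  if (nrow(sub) == 0L) stop("build_feature_matrix: no rows for task ", task)
  wide_trial <- function(tr) {
    s <- sub[sub$trial == tr, ]
    w <- stats::reshape(s[, c("participant_id", "measure_name", "value")],
                        idvar = "participant_id", timevar = "measure_name",
                        direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    w
  }
  w1 <- wide_trial(1); w2 <- wide_trial(2)
  common <- intersect(w1$participant_id, w2$participant_id)
  w1 <- w1[match(common, w1$participant_id), , drop = FALSE]
  w2 <- w2[match(common, w2$participant_id), , drop = FALSE]
  m1 <- as.matrix(w1[, -1, drop = FALSE])
  m2 <- as.matrix(w2[, -1, drop = FALSE])
  X <- switch(feature_set,
    trial1 = m1,
    trial2 = m2,
    both = {
      feats <- intersect(colnames(m1), colnames(m2))
      cbind(`colnames<-`(m1[, feats, drop = FALSE], paste0(feats, "_t1")),
            `colnames<-`(m2[, feats, drop = FALSE], paste0(feats, "_t2")),
            `colnames<-`((m1[, feats, drop = FALSE] +
                            m2[, feats, drop = FALSE]) / 2,
                         paste0(feats, "_mean")))
    })
  rownames(X) <- common
  # impute column medians, drop useless columns
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  keep <- apply(X, 2, function(v) !anyNA(v) && stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  grp <- sub$group[match(common, sub$participant_id)]
  list(X = X, y = as.integer(grp == positive_group), participant_id = common)
}

#' Rank features with random-forest importance
#'
#' @param X feature matrix (>= 2 columns).
#' @param y binary labels.
#' @param seed integer seed.
#' @param ntree trees for the ranking forest.
#' @return data.frame(feature, importance) in descending importance.
#' @export
rank_features <- function(X, y, seed = 1, ntree = 500) {
  if (ncol(X) < 2L) stop("rank_features: need >= 2 features")
  if (length(unique(y)) < 2L) stop("rank_features: degenerate labels")
  if (!is.null(seed)) set.seed(seed)
  fit <- rf_fit(X, y, ntree = ntree)
  ord <- order(fit$importance, decreasing = TRUE)
  data.frame(feature = colnames(X)[ord],
             importance = unname(fit$importance[ord]),
             stringsAsFactors = FALSE)
}

#' Elbow point of a descending importance curve
#'
#' The index farthest (perpendicular distance) from the chord joining the
#' first and last points of the curve `(i, v_i)`. Ties, including perfectly
#' collinear curves, resolve to the smallest index.
#'
#' @param values descending numeric values, length >= 3.
#' @return integer cutoff index; features ranked at or before it are the
#'   candidate set.
#' @export
find_elbow <- function(values) {
  k <- length(values)
  if (k < 3L) stop("find_elbow: need >= 3 points")
  x1 <- 1; y1 <- values[1]; x2 <- k; y2 <- values[k]
  i <- seq_len(k)
  d <- abs((y2 - y1) * (i - x1) - (x2 - x1) * (values - y1)) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(d > max(d) - 1e-15) # first index attaining the max
}

#' Forward selection of cumulative top-ranked features by AIC
#'
#' Fits a forest on the top-j candidate features for each j and scores it
#' with `AIC_j = 2j - 2 ln L_j`, where the likelihood uses out-of-bag
#' predicted probabilities of each sample's true class, clipped to
#' `[1e-6, 1 - 1e-6]` (a random forest has no native likelihood; this
#' documented surrogate is seeded and swappable). Smallest AIC wins; ties go
#' to the smaller subset.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param candidates ordered character vector of candidate feature names.
#' @param seed integer seed.
#' @param ntree trees per candidate fit.
#' @return character vector: the selected feature subset.
#' @export
select_by_aic <- function(X, y, candidates, seed = 1, ntree = 500) {
  if (length(candidates) == 0L) stop("select_by_aic: no candidates")
  if (length(candidates) == 1L) return(candidates)
  if (!is.null(seed)) set.seed(seed)
  aics <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    fit <- rf_fit(X[, candidates[seq_len(j)], drop = FALSE], y,
                  ntree = ntree)
    p1 <- fit$oob_prob
    p1[is.na(p1)] <- 0.5
    ptrue <- ifelse(y == 1L, p1, 1 - p1)
    ptrue <- pmin(pmax(ptrue, 1e-6), 1 - 1e-6)
    aics[j] <- 2 * j - 2 * sum(log(ptrue))
  }
  jbest <- which.min(aics) # which.min returns the first (smallest j) on ties
  candidates[seq_len(jbest)]
}

# stratified fold assignment: within each class, shuffle then deal
# round-robin
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

# undersample the majority class to the minority size (without replacement)
undersample_idx <- function(y) {
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  m <- min(length(i0), length(i1))
  sort(c(sample(i0, m), sample(i1, m)))
}

# per-fold feature selection: rank -> elbow -> AIC. Falls back to all
# features when there are too few for an elbow.
select_features_fold <- function(Xtr, ytr, ntree) {
  if (ncol(Xtr) < 3L) return(colnames(Xtr))
  ranked <- rank_features(Xtr, ytr, seed = NULL, ntree = ntree)
  cutoff <- find_elbow(ranked$importance)
  candidates <- ranked$feature[seq_len(cutoff)]
  select_by_aic(Xtr, ytr, candidates, seed = NULL, ntree = ntree)
}

#' Cross-validated diagnostic evaluation
#'
#' The full protocol: `nrep` replicates of stratified `nfolds`-fold
#' cross-validation (replicate r reseeds the RNG with `seed + r`). Within
#' each training fold, features are selected by rank -> elbow -> AIC using
#' training data only; the training majority class is undersampled to the
#' minority size; a random forest (default 10,000 trees; tests use fewer)
#' is fit and the held-out fold predicted. Each participant receives one
#' prediction per replicate; the final class is the majority of the `nrep`
#' votes (ties, impossible for odd `nrep`, would fall to the positive
#' class). Accuracy is the percentage of correct final votes.
#'
#' @param X feature matrix (participants x features).
#' @param y binary labels (both classes >= 5).
#' @param seed integer base seed.
#' @param ntree trees for the final per-fold forest and the selection
#'   forests.
#' @param nfolds folds per replicate.
#' @param nrep replicates.
#' @param classifier `"forest"` or `"logistic"` (the duration-only model).
#' @param select run per-fold feature selection (disabled for logistic).
#' @return object of class `model_evaluation`: list(accuracy (percent),
#'   votes (n x nrep 0/1 matrix), final, y, selected (features per
#'   replicate x fold), fold_class_counts, n).
#' @export
evaluate <- function(X, y, seed = 1, ntree = 10000, nfolds = 5, nrep = 5,
                     classifier = c("forest", "logistic"), select = NULL) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < nfolds)
    stop("evaluate: smallest class (n = ", min(table(y)),
         ") must have at least nfolds = ", nfolds, " members")
  if (is.null(select)) select <- classifier == "forest"
  n <- nrow(X)
  votes <- matrix(NA_integer_, n, nrep)
  selected <- list()
  fold_counts <- list()
  for (r in seq_len(nrep)) {
    set.seed(seed + r)
    fold <- stratified_folds(y, nfolds)
    for (f in seq_len(nfolds)) {
      tr <- which(fold != f); te <- which(fold == f)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      feats <- if (select) select_features_fold(Xtr, ytr, ntree) else
        colnames(X)
      us <- undersample_idx(ytr)
      fold_counts[[length(fold_counts) + 1L]] <- data.frame(
        rep = r, fold = f, n0 = sum(ytr[us] == 0L), n1 = sum(ytr[us] == 1L),
        minority = min(table(ytr)))
      Xus <- Xtr[us, feats, drop = FALSE]; yus <- ytr[us]
      pred <- if (classifier == "forest") {
        fit <- rf_fit(Xus, yus, ntree = ntree,
                      Xtest = X[te, feats, drop = FALSE])
        as.integer(fit$test_prob > 0.5)
      } else {
        d <- data.frame(y = yus, Xus)
        g <- suppressWarnings(stats::glm(y ~ ., data = d,
                                         family = stats::binomial()))
        nd <- as.data.frame(X[te, feats, drop = FALSE])
        names(nd) <- names(d)[-1]
        as.integer(suppressWarnings(
          stats::predict(g, newdata = nd, type = "response")) > 0.5)
      }
      votes[te, r] <- pred
      selected[[paste0("rep", r, "_fold", f)]] <- feats
    }
  }
  final <- as.integer(rowMeans(votes) >= 0.5)
  structure(list(
    accuracy = 100 * mean(final == y),
    votes = votes, final = final, y = y,
    selected = selected,
    fold_class_counts = do.call(rbind, fold_counts),
    n = n, nrep = nrep, classifier = classifier
  ), class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> %s: accuracy %.1f%% (n = %d, %d votes)\n",
              x$classifier, x$accuracy, x$n, x$nrep))
  invisible(x)
}

#' Duration-only logistic benchmark
#'
#' Same cross-validation, undersampling and majority-vote protocol as
#' [evaluate()], but the classifier is a logistic regression on a single
#' predictor: each participant's mean total duration across both trials.
#'
#' @param mean_durations numeric vector, one per participant.
#' @param y binary labels.
#' @param seed,ntree,nfolds,nrep as in [evaluate()] (`ntree` unused).
#' @return a `model_evaluation`.
#' @export
duration_only_model <- function(mean_durations, y, seed = 1, ntree = NULL,
                                nfolds = 5, nrep = 5) {
  if (length(unique(y)) < 2L)
    stop("duration_only_model: both classes must be present")
  X <- matrix(mean_durations, ncol = 1,
              dimnames = list(NULL, "mean_total_duration"))
  evaluate(X, y, seed = seed, ntree = 0, nfolds = nfolds, nrep = nrep,
           classifier = "logistic", select = FALSE)
}

#' Compare trial-wise model accuracies
#'
#' Given per-(task, group, feature_set) accuracies, computes each cell's
#' difference from the matching trial-1 model and the mean difference per
#' feature set across cells, mirroring the layout of a trial-comparison
#' table.
#'
#' @param accuracies data.frame with columns task, group, feature_set
#'   (levels trial1, trial2, both, duration), accuracy (percent).
#' @return list(table = per-cell data.frame with `diff_vs_trial1`,
#'   mean_diffs = named numeric for trial2, both, duration).
#' @export
compare_trial_models <- function(accuracies) {
  need <- c("task", "group", "feature_set", "accuracy")
  stopifnot(all(need %in% names(accuracies)))
  cells <- unique(accuracies[, c("task", "group")])
  sets <- setdiff(unique(accuracies$feature_set), "trial1")
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- accuracies[accuracies$task == cells$task[i] &
                        accuracies$group == cells$group[i], ]
    base <- sub$accuracy[sub$feature_set == "trial1"]
    missing_sets <- setdiff(c("trial1", sets), sub$feature_set)
    if (length(base) != 1L || length(missing_sets))
      stop("compare_trial_models: unmatched cell ", cells$task[i], "/",
           cells$group[i], if (length(missing_sets))
             paste0(" (missing: ", paste(missing_sets, collapse = ", "), ")"))
    sub$diff_vs_trial1 <- sub$accuracy - base
    rows[[i]] <- sub
  }
  tab <- do.call(rbind, rows)
  mean_diffs <- vapply(sets, function(s) {
    mean(tab$diff_vs_trial1[tab$feature_set == s])
  }, numeric(1))
  list(table = tab, mean_diffs = mean_diffs)
}
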