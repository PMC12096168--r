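#' Hyperparameter ranges for the bagged-tree ensemble
#'
#' The search space used by [random_search_forest()]: number of trees
#' 1-500, maximum depth 1-20, minimum samples to split an internal node
#' 2-20, minimum samples per leaf 1-10.
#'
#' @return Named list of `c(lower, upper)` integer ranges.
#' @export
table4_ranges <- function() {
  list(n_estimators = c(1L, 500L), max_depth = c(1L, 20L),
       min_samples_split = c(2L, 20L), min_samples_leaf = c(1L, 10L))
}

#' Bagged-forest configuration
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param min_samples_split minimum node size to attempt a split.
#' @param min_samples_leaf minimum leaf size.
#' @param mtry number of features offered to each tree (a per-tree random
#'   subspace); `NULL` uses all features (pure bagging).
#' @param mode `"regression"` fits regression trees on the 0/1 outcome and
#'   scores OOB error as mean squared error; `"classification"` fits
#'   classification trees and scores misclassification rate.
#' @param seed seed fixing bootstrap draws (and, via [oob_importance()],
#'   permutations).
#' @return A `forest_config` list (ranges validated against
#'   [table4_ranges()]).
#' @export
forest_config <- function(n_estimators = 100, max_depth = 10,
                          min_samples_split = 2, min_samples_leaf = 1,
                          mtry = NULL,
                          mode = c("regression", "classification"),
                          seed = 1L) {
  mode <- match.arg(mode)
  rng <- table4_ranges()
  chk <- function(v, nm) {
    if (v < rng[[nm]][1] || v > rng[[nm]][2]) {
      stop(sprintf("config error: %s = %s outside range [%d, %d]", nm,
                   format(v), rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
    }
    as.integer(v)
  }
  structure(list(n_estimators = chk(n_estimators, "n_estimators"),
                 max_depth = chk(max_depth, "max_depth"),
                 min_samples_split = chk(min_samples_split, "min_samples_split"),
                 min_samples_leaf = chk(min_samples_leaf, "min_samples_leaf"),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 mode = mode, seed = as.integer(seed)),
            class = "forest_config")
}

.as_feature_frame <- function(X) {
  if (inherits(X, "design_matrix")) {
    X <- as.data.frame(unclass(X)[, attr(X, "assign") != "(Intercept)",
                                  drop = FALSE])
  } else {
    X <- as.data.frame(X)
  }
  names(X) <- make.names(names(X))
  X
}

.oob_err <- function(pred, y, mode) {
  if (mode == "regression") mean((pred - y)^2) else mean(pred != y)
}

.tree_predict <- function(tree, newdata, mode) {
  if (mode == "regression") {
    as.numeric(stats::predict(tree, newdata = newdata))
  } else {
    as.numeric(as.character(stats::predict(tree, newdata = newdata,
                                           type = "class")))
  }
}

#' Fit a bagged decision-tree ensemble with OOB bookkeeping
#'
#' Trains `n_estimators` CART trees (via \pkg{rpart}), each on a bootstrap
#' resample of the data, recording the out-of-bag (OOB) row set of every
#' tree. Prediction is the tree mean (regression mode) or majority vote
#' (classification mode).
#'
#' @param X feature matrix or data.frame (integer-coded factors or a
#'   `design_matrix`; the intercept column is dropped automatically).
#' @param y binary 0/1 outcome.
#' @param config a [forest_config()].
#' @return A `bagged_forest`: list with `trees`, `oob_sets`, `feature_sets`,
#'   `config`, `feature_names`, `n`.
#' @export
fit_forest <- function(X, y, config = forest_config()) {
  X <- .as_feature_frame(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2 || p < 1) stop("need at least 2 rows and 1 feature", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: single class", call. = FALSE)
  }
  mode <- config$mode
  dat <- X
  dat$.y <- if (mode == "classification") factor(y, levels = sort(unique(y)))
    else as.numeric(y)
  ctrl <- rpart::rpart.control(maxdepth = config$max_depth,
                               minsplit = config$min_samples_split,
                               minbucket = config$min_samples_leaf,
                               cp = 0, xval = 0, maxsurrogate = 0,
                               maxcompete = 0)
  method <- if (mode == "classification") "class" else "anova"
  mtry <- if (is.null(config$mtry)) p else min(config$mtry, p)

  set.seed(config$seed)
  trees <- vector("list", config$n_estimators)
  oob_sets <- vector("list", config$n_estimators)
  feature_sets <- vector("list", config$n_estimators)
  for (i in seq_len(config$n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob_sets[[i]] <- setdiff(seq_len(n), idx)
    feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    feature_sets[[i]] <- feats
    fml <- stats::as.formula(paste(".y ~", paste(names(X)[feats],
                                                 collapse = " + ")))
    trees[[i]] <- rpart::rpart(fml, data = dat[idx, c(feats, p + 1)],
                               method = method, control = ctrl)
  }
  structure(list(trees = trees, oob_sets = oob_sets,
                 feature_sets = feature_sets, config = config,
                 feature_names = names(X), n = n, mode = mode),
            class = "bagged_forest")
}

#' Predict from a bagged forest
#'
#' @param object a `bagged_forest`.
#' @param newdata feature data.frame/matrix.
#' @param ... unused.
#' @return numeric vector: mean tree prediction (regression mode) or
#'   majority-vote class (classification mode).
#' @export
predict.bagged_forest <- function(object, newdata, ...) {
  newdata <- .as_feature_frame(newdata)
  preds <- vapply(object$trees,
                  function(tr) .tree_predict(tr, newdata, object$mode),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(newdata))
  if (object$mode == "regression") {
    rowMeans(preds)
  } else {
    apply(preds, 1, function(z) as.numeric(names(which.max(table(z)))))
  }
}

#' Ensemble out-of-bag error
#'
#' Mean per-tree OOB error (each tree evaluated on its own out-of-bag rows).
#'
#' @param forest a `bagged_forest`.
#' @param X,y the training features and outcome.
#' @return scalar error (MSE on 0/1 in regression mode, misclassification
#'   rate in classification mode).
#' @export
oob_error <- function(forest, X, y) {
  X <- .as_feature_frame(X)
  errs <- mapply(function(tr, oob) {
    if (length(oob) == 0) return(NA_real_)
    .oob_err(.tree_predict(tr, X[oob, , drop = FALSE], forest$mode),
             y[oob], forest$mode)
  }, forest$trees, forest$oob_sets)
  mean(errs, na.rm = TRUE)
}

#' Out-of-bag permutation importance
#'
#' For each feature and each tree: the tree's baseline OOB error
#' (`err_oob1`), the OOB error after randomly permuting that feature's
#' values over the tree's OOB rows (`err_oob2`), and the importance score
#' `mean(err_oob2 - err_oob1)` over the N trees. Trees with an empty OOB
#' set are skipped and N decremented.
#'
#' @param forest a `bagged_forest` from [fit_forest()].
#' @param X,y the training features and outcome.
#' @param seed seed for the permutation draws.
#' @return A `forest_importance`: list with `err_oob1`/`err_oob2` (feature x
#'   tree matrices), `oob_store` (named score vector), `n_trees` (N used),
#'   `ranking` (features by descending score).
#' @export
oob_importance <- function(forest, X, y, seed = forest$config$seed) {
  X <- .as_feature_frame(X)
  stopifnot(identical(names(X), forest$feature_names))
  set.seed(seed)
  keep <- which(lengths(forest$oob_sets) > 0)
  n_skipped <- length(forest$trees) - length(keep)
  if (n_skipped > 0) {
    message(n_skipped, " tree(s) with empty OOB set skipped")
  }
  p <- length(forest$feature_names)
  N <- length(keep)
  err1 <- matrix(NA_real_, p, N,
                 dimnames = list(forest$feature_names, NULL))
  err2 <- err1
  for (ti in seq_along(keep)) {
    i <- keep[ti]
    oob <- forest$oob_sets[[i]]
    Xo <- X[oob, , drop = FALSE]
    yo <- y[oob]
    base <- .oob_err(.tree_predict(forest$trees[[i]], Xo, forest$mode), yo,
                     forest$mode)
    for (j in seq_len(p)) {
      err1[j, ti] <- base
      Xp <- Xo
      Xp[[j]] <- Xp[[j]][sample.int(nrow(Xp))]
      err2[j, ti] <- .oob_err(.tree_predict(forest$trees[[i]], Xp,
                                            forest$mode), yo, forest$mode)
    }
  }
  score <- rowMeans(err2 - err1)
  structure(list(err_oob1 = err1, err_oob2 = err2, oob_store = score,
                 n_trees = N,
                 ranking = names(sort(score, decreasing = TRUE))),
            class = "forest_importance")
}

#' @export
print.forest_importance <- function(x, ...) {
  cat(sprintf("<forest_importance> N = %d trees\n", x$n_trees))
  print(data.frame(feature = x$ranking,
                   oob_store = unname(x$oob_store[x$ranking]),
                   rank = seq_along(x$ranking)), row.names = FALSE)
  invisible(x)
}

#' Export an importance table
#' @param imp a `forest_importance`.
#' @param path optional CSV path.
#' @return data.frame `feature`, `oob_store`, `rank` (invisibly written to
#'   `path` if given).
#' @export
importance_table <- function(imp, path = NULL) {
  df <- data.frame(feature = imp$ranking,
                   oob_store = unname(imp$oob_store[imp$ranking]),
                   rank = seq_along(imp$ranking))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

# stratified fold assignment: shuffles within each class, then deals folds
# round-robin so every fold sees both classes whenever feasible
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Randomized hyperparameter search with k-fold cross-validation
#'
#' Draws `n_iter` configurations uniformly over the [table4_ranges()] search
#' space, scores each by stratified k-fold cross-validated accuracy, and
#' returns the best configuration together with the full trial log.
#'
#' @param X,y features and binary outcome.
#' @param ranges search space, see [table4_ranges()].
#' @param n_iter number of random draws.
#' @param k_folds folds for cross-validation.
#' @param mode forest mode; accuracy thresholds regression predictions at
#'   0.5.
#' @param seed seed for draws and folds.
#' @return list with `best` (a [forest_config()]), `best_accuracy`, and
#'   `log` (data.frame of every trial's parameters and fold accuracies).
#' @export
random_search_forest <- function(X, y, ranges = table4_ranges(), n_iter = 10,
                                 k_folds = 5,
                                 mode = c("classification", "regression"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_iter >= 1)
  X <- .as_feature_frame(X)
  if (min(table(y)) < k_folds) {
    stop("fold error: cannot stratify ", k_folds, " folds with a class of ",
         min(table(y)), " rows", call. = FALSE)
  }
  set.seed(seed)
  folds <- stratified_folds(y, k_folds)
  draws <- data.frame(
    n_estimators = sample(ranges$n_estimators[1]:ranges$n_estimators[2],
                          n_iter, replace = TRUE),
    max_depth = sample(ranges$max_depth[1]:ranges$max_depth[2], n_iter,
                       replace = TRUE),
    min_samples_split = sample(ranges$min_samples_split[1]:ranges$min_samples_split[2],
                               n_iter, replace = TRUE),
    min_samples_leaf = sample(ranges$min_samples_leaf[1]:ranges$min_samples_leaf[2],
                              n_iter, replace = TRUE))
  acc <- matrix(NA_real_, n_iter, k_folds)
  for (t in seq_len(n_iter)) {
    cfg <- forest_config(draws$n_estimators[t], draws$max_depth[t],
                         draws$min_samples_split[t], draws$min_samples_leaf[t],
                         mode = mode, seed = seed + t)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      fit <- fit_forest(X[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      if (mode == "regression") pred <- as.numeric(pred >= 0.5)
      acc[t, f] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  best_t <- which.max(mean_acc)
  log <- cbind(draws, acc, mean_accuracy = mean_acc)
  names(log)[4 + seq_len(k_folds)] <- paste0("fold", seq_len(k_folds))
  list(best = forest_config(draws$n_estimators[best_t],
                            draws$max_depth[best_t],
                            draws$min_samples_split[best_t],
                            draws$min_samples_leaf[best_t],
                            mode = mode, seed = seed + best_t),
       best_accuracy = mean_acc[best_t],
       folds = folds,
       log = log)
}
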