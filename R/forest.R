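#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over class proportions; 0 for a pure node, 0.5 at the
#' two-class symmetry maximum.
#'
#' @param class_counts non-negative per-class sample counts, sum > 0.
#' @return the impurity, in \[0, 0.5\] for two classes.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) <= 0)
    stopf("class counts must be non-negative with positive sum")
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

mtry_from_rule <- function(max_features, p) {
  if (is.numeric(max_features)) {
    if (max_features <= 0 || max_features > 1)
      stopf("numeric max_features must be a fraction in (0, 1]")
    return(max(1L, as.integer(ceiling(max_features * p))))
  }
  switch(max_features,
         sqrt = max(1L, as.integer(floor(sqrt(p)))),
         log2 = max(1L, as.integer(floor(log2(p)))),
         all = p,
         stopf("unknown max_features rule '%s'", max_features))
}

as_matrix_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Grow a single CART decision tree
#'
#' Recursive best-split search maximizing the Gini impurity decrease
#' `imp(parent) - (n_L/n) imp(L) - (n_R/n) imp(R)` over a per-node random
#' feature subset; candidate thresholds are midpoints between consecutive
#' distinct sorted values. Growth stops on purity, on `max_depth`, or when no
#' split has positive gain. Ties are broken toward the lowest feature index,
#' then the lowest threshold, so growth is deterministic given the RNG state.
#'
#' @param X numeric matrix (samples x features).
#' @param y integer 0/1 labels.
#' @param max_depth maximum tree depth (`Inf` for unlimited; a root-only
#'   tree has depth 0).
#' @param max_features `"all"` (default), `"sqrt"`, `"log2"`, or a fraction
#'   in (0, 1\]: the per-node feature subsample rule.
#' @param sample_idx row indices to grow on (with multiplicity, for
#'   bootstrap); defaults to all rows.
#' @return a `famtrait_tree`: flat parallel node vectors `feature` (0-based
#'   split feature, -1 at leaves), `threshold`, `left`/`right` (1-based child
#'   indices, 0 at leaves), `n_samples`, `n0`, `n1`, `impurity`, `value`
#'   (class-1 fraction).
#' @export
grow_tree <- function(X, y, max_depth = Inf, max_features = "all",
                      sample_idx = seq_len(nrow(X))) {
  X <- as_matrix_X(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (!length(sample_idx)) stopf("sample_idx must be non-empty")
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  tree <- cpp_grow_tree(X, y, as.integer(sample_idx), md,
                        mtry_from_rule(max_features, ncol(X)))
  tree$features <- colnames(X)
  class(tree) <- "famtrait_tree"
  tree
}

#' Fit a random forest of CART trees
#'
#' Each tree is grown on a bootstrap sample (`n` draws with replacement) with
#' per-node feature subsampling. Training is single-threaded and fully
#' reproducible: all randomness flows from `seed`.
#'
#' @inheritParams grow_tree
#' @param n_estimators number of trees.
#' @param max_depth maximum depth per tree.
#' @param max_features per-node feature rule (see [grow_tree()]).
#' @param bootstrap draw bootstrap samples per tree (default TRUE).
#' @param seed integer seed.
#' @return an object of class `forest_model`.
#' @export
fit_forest <- function(X, y, n_estimators = 500L, max_depth = 10,
                       max_features = "sqrt", bootstrap = TRUE, seed = 1L) {
  X <- as_matrix_X(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2L)
    stopf("y contains a single class; a classifier needs both")
  if (!all(y %in% c(0L, 1L))) stopf("y must be binary 0/1")
  n <- nrow(X)
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  mtry <- mtry_from_rule(max_features, ncol(X))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_estimators), function(b) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tr <- cpp_grow_tree(X, y, as.integer(idx), md, mtry)
      class(tr) <- "famtrait_tree"
      tr
    })
  })
  structure(
    list(trees = trees, feature_order = colnames(X),
         hyperparams = list(n_estimators = as.integer(n_estimators),
                            max_depth = max_depth,
                            max_features = max_features,
                            bootstrap = bootstrap),
         seed = as.integer(seed), class_order = c(0L, 1L), n_train = n),
    class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "<forest_model> %d trees, max_depth %s, max_features %s, %d features, seed %d\n",
    length(x$trees), format(x$hyperparams$max_depth),
    format(x$hyperparams$max_features), length(x$feature_order), x$seed))
  invisible(x)
}

align_features <- function(model, X) {
  X <- as_matrix_X(X)
  miss <- setdiff(model$feature_order, colnames(X))
  if (length(miss))
    stopf("X lacks model feature(s): %s", paste(head(miss, 5), collapse = ", "))
  X[, model$feature_order, drop = FALSE]
}

#' Predicted class-1 probability
#'
#' Mean over trees of the reached leaf's class-1 training fraction.
#'
#' @param model a [fit_forest()] model.
#' @param X a matrix whose columns include the model's features (any order).
#' @return a numeric vector in \[0, 1\], one value per row of `X`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "forest_model"))
  X <- align_features(model, X)
  probs <- vapply(model$trees, function(tr) cpp_predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
  setNames(rowMeans(probs), rownames(X))
}

tree_importance <- function(tree, p) {
  imp <- numeric(p)
  internal <- which(tree$feature >= 0L)
  if (!length(internal)) return(imp)
  n_root <- tree$n_samples[1]
  for (i in internal) {
    l <- tree$left[i]; r <- tree$right[i]
    delta <- tree$impurity[i] -
      (tree$n_samples[l] / tree$n_samples[i]) * tree$impurity[l] -
      (tree$n_samples[r] / tree$n_samples[i]) * tree$impurity[r]
    f <- tree$feature[i] + 1L
    imp[f] <- imp[f] + (tree$n_samples[i] / n_root) * delta
  }
  imp
}

#' Gini importance of every feature
#'
#' Per tree, each internal node contributes its sample-weighted impurity
#' decrease `(n_node/n_root) * delta` to its split feature; contributions are
#' summed within trees, averaged over trees, and normalized to sum to 1.
#'
#' @param model a [fit_forest()] model.
#' @return a data frame `family`, `importance`, `rank`, sorted by decreasing
#'   importance (ties broken by family identifier). If no tree contains a
#'   split, all importances are zero and a warning is raised.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  p <- length(model$feature_order)
  imp <- rowMeans(vapply(model$trees, tree_importance, numeric(p), p = p))
  if (sum(imp) == 0) {
    warnf("forest contains no splits; importances are all zero")
  } else {
    imp <- imp / sum(imp)
  }
  out <- data.frame(family = model$feature_order, importance = imp)
  out <- out[order(-out$importance, out$family), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the most important features by a selection forest
#'
#' Fits a forest on the supplied (training) data and returns the `n_select`
#' families with the largest Gini importance, ties broken by family
#' identifier.
#'
#' @inheritParams fit_forest
#' @param n_select number of features to keep.
#' @param n_estimators,max_depth,max_features hyperparameters of the
#'   selection forest.
#' @return character vector of family identifiers, importance-ranked.
#' @export
select_top_features <- function(X, y, n_select = 50L, n_estimators = 500L,
                                max_depth = 10, max_features = "sqrt",
                                seed = 1L) {
  if (n_select > ncol(X))
    stopf("n_select (%d) exceeds the number of features (%d)",
          n_select, ncol(X))
  model <- fit_forest(X, y, n_estimators = n_estimators,
                      max_depth = max_depth, max_features = max_features,
                      seed = seed)
  head(gini_importance(model)$family, n_select)
}

# ---- metrics --------------------------------------------------------------

#' ROC curve and area by threshold sweep
#'
#' @param scores predicted class-1 scores.
#' @param labels true 0/1 labels (both classes must be present).
#' @return a list with `fpr`, `tpr` (threshold sweep over the unique scores,
#'   from (0,0) to (1,1)) and `auc` (trapezoidal area).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # pool tied scores into one threshold step
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[keep]; fp <- cumsum(1L - l)[keep]
  tpr <- c(0, tp / sum(l)); fpr <- c(0, fp / sum(1L - l))
  list(fpr = fpr, tpr = tpr,
       auc = sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2))
}

#' Precision-recall curve and area
#'
#' @inheritParams roc_curve
#' @return a list with `recall`, `precision` and `auc` (trapezoidal area over
#'   the recall axis).
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(l)[keep]
  n_pred <- seq_along(l)[keep]
  precision <- tp / n_pred
  recall <- tp / sum(l)
  # anchor at the first point's precision for recall 0
  recall <- c(0, recall); precision <- c(precision[1], precision)
  list(recall = recall, precision = precision,
       auc = sum(diff(recall) *
                   (head(precision, -1) + tail(precision, -1)) / 2))
}

#' Threshold classification metrics
#'
#' Precision, recall and F1 (`2PR/(P+R)`) at a fixed probability threshold,
#' plus the row-normalized ("balanced") 2 x 2 confusion matrix: row `i`,
#' column `j` is the fraction of true-class-`i` instances predicted as `j`.
#'
#' @inheritParams roc_curve
#' @param threshold decision threshold on the class-1 score (default 0.5).
#' @return list with `precision`, `recall`, `f1`, `confusion` (row-stochastic
#'   matrix, rows/cols named `0`,`1`).
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  conf <- rbind(`0` = c(tn, fp) / max(tn + fp, 1L),
                `1` = c(fn, tp) / max(fn + tp, 1L))
  colnames(conf) <- c("0", "1")
  list(precision = precision, recall = recall, f1 = f1, confusion = conf)
}

# interpolate a step ROC onto a fixed FPR grid (right-continuous step)
interp_roc <- function(roc, grid) {
  vapply(grid, function(g) max(roc$tpr[roc$fpr <= g]), 0)
}

# ---- grid search & replicated evaluation ----------------------------------

#' Default hyperparameter grid
#'
#' @return a data frame of candidate cells over `n_estimators`,
#'   `max_features` and `max_depth` (`Inf` = unlimited).
#' @export
default_grid <- function() {
  expand.grid(n_estimators = c(100L, 500L, 1000L),
              max_features = c("sqrt", "log2", "0.25", "0.5"),
              max_depth = c(3, 5, 10, Inf),
              stringsAsFactors = FALSE)
}

parse_max_features <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Full grid search by cross-validated F1
#'
#' Evaluates every grid cell by mean out-of-fold F1 over the supplied folds
#' and returns the argmax; ties go to the smaller model (fewer trees, then
#' shallower depth).
#'
#' @param X,y training matrix and 0/1 labels (rownames of `X` name species).
#' @param folds list of species vectors (the validation fold members).
#' @param grid data frame with columns `n_estimators`, `max_features`,
#'   `max_depth` (see [default_grid()]).
#' @param seed integer seed for the fold fits.
#' @return list with `best` (one-row data frame) and `cv_table` (the grid
#'   with a `mean_f1` column).
#' @export
grid_search <- function(X, y, folds, grid = default_grid(), seed = 1L) {
  if (!nrow(grid)) stopf("grid must be non-empty")
  X <- as_matrix_X(X)
  mean_f1 <- vapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    f1s <- vapply(seq_along(folds), function(j) {
      val <- intersect(folds[[j]], rownames(X))
      tr <- setdiff(rownames(X), val)
      model <- fit_forest(X[tr, , drop = FALSE], y[tr],
                          n_estimators = cell$n_estimators,
                          max_depth = cell$max_depth,
                          max_features = parse_max_features(cell$max_features),
                          seed = seed + j)
      threshold_metrics(predict_proba(model, X[val, , drop = FALSE]),
                        y[val])$f1
    }, 0)
    mean(f1s)
  }, 0)
  cv_table <- cbind(grid, mean_f1 = mean_f1)
  ord <- order(-cv_table$mean_f1, cv_table$n_estimators, cv_table$max_depth)
  list(best = cv_table[ord[1], , drop = FALSE], cv_table = cv_table)
}

#' Replicated holdout/cross-validation evaluation protocol
#'
#' For each replicate `r` (seed = `base_seed + r`): make a balanced holdout
#' split and stratified folds, select the top features on the training
#' partition only, grid-search hyperparameters by CV F1, refit on all
#' training species, and score the holdout test predictions. Validation
#' metrics come from pooled out-of-fold predictions under *nested* feature
#' selection: each fold's features are re-selected on the training species
#' outside that fold, so that with pure-noise features the validation AUC is
#' null-calibrated (selecting features once before cross-validating would
#' leak the held-out fold into the screen and inflate validation metrics
#' even for random labels). The replicate-level selection still defines the
#' reported feature set, the final model and the test metrics. Confusion
#' matrices are row-normalized before averaging; the mean ROC is each
#' replicate's curve interpolated onto a fixed FPR grid with the per-point
#' SD.
#'
#' @param instances a list with `X` (species x families) and `y` (named 0/1),
#'   as from [build_instance_table()].
#' @param n_replicates number of independent replicates.
#' @param holdout_frac,k holdout fraction and fold count for [make_split()].
#' @param n_select number of features kept by the selection forest.
#' @param select_n_estimators,select_max_depth,select_max_features
#'   selection-forest hyperparameters; the default per-node feature fraction
#'   of 0.25 is deliberately larger than the classifier's `sqrt` rule so
#'   that informative families compete directly in most nodes, which
#'   stabilizes the importance ranking used for screening.
#' @param cv_select_n_estimators trees of the per-fold nested selection
#'   forests (smaller than the replicate-level forest: they guard metric
#'   honesty, not the reported ranking).
#' @param grid hyperparameter grid (a single-row grid skips model
#'   comparison and just uses that cell).
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @param pooled if `TRUE` (default) validation metrics are computed on
#'   pooled out-of-fold predictions; otherwise averaged per fold.
#' @return an object of class `evaluation_report`: per-replicate metric data
#'   frame (`metrics`), mean balanced confusion matrices, mean ROC with SD,
#'   per-replicate selected features, and the settings used.
#' @export
evaluate_replicates <- function(instances, n_replicates = 100L,
                                holdout_frac = 0.1, k = 10L, n_select = 50L,
                                select_n_estimators = 500L,
                                select_max_depth = 10,
                                select_max_features = 0.25,
                                cv_select_n_estimators = 100L,
                                grid = data.frame(n_estimators = 500L,
                                                  max_features = "sqrt",
                                                  max_depth = 10),
                                base_seed = 0L, pooled = TRUE) {
  X <- as_matrix_X(instances$X)
  y <- instances$y[rownames(X)]
  fpr_grid <- seq(0, 1, by = 0.01)
  rows <- list(); confs <- list(); rocs <- list(); selected <- list()
  for (r in seq_len(n_replicates)) {
    seed <- base_seed + r
    plan <- make_split(y, holdout_frac = holdout_frac, k = k, seed = seed)
    train_sp <- sort(unlist(plan$folds))
    feats <- select_top_features(
      X[train_sp, , drop = FALSE], y[train_sp], n_select = n_select,
      n_estimators = select_n_estimators, max_depth = select_max_depth,
      max_features = select_max_features, seed = seed)
    Xs <- X[, feats, drop = FALSE]
    if (nrow(grid) > 1L) {
      gs <- grid_search(Xs[train_sp, , drop = FALSE], y[train_sp],
                        plan$folds, grid = grid, seed = seed)
      best <- gs$best
    } else {
      best <- grid
    }
    # pooled out-of-fold validation predictions under the winning cell,
    # with per-fold (nested) feature re-selection
    val_scores <- setNames(numeric(length(train_sp)), train_sp)
    fold_metrics <- list()
    for (j in seq_along(plan$folds)) {
      val <- plan$folds[[j]]
      tr <- setdiff(train_sp, val)
      feats_j <- select_top_features(
        X[tr, , drop = FALSE], y[tr], n_select = n_select,
        n_estimators = cv_select_n_estimators, max_depth = select_max_depth,
        max_features = select_max_features, seed = seed + j)
      m <- fit_forest(X[tr, feats_j, drop = FALSE], y[tr],
                      n_estimators = best$n_estimators,
                      max_depth = best$max_depth,
                      max_features = parse_max_features(best$max_features),
                      seed = seed + j)
      val_scores[val] <- predict_proba(m, X[val, feats_j, drop = FALSE])
      fold_metrics[[j]] <- list(scores = val_scores[val], labels = y[val])
    }
    final <- fit_forest(Xs[train_sp, , drop = FALSE], y[train_sp],
                        n_estimators = best$n_estimators,
                        max_depth = best$max_depth,
                        max_features = parse_max_features(best$max_features),
                        seed = seed)
    test_scores <- predict_proba(final, Xs[plan$test_species, , drop = FALSE])
    test_labels <- y[plan$test_species]

    if (pooled) {
      val_roc <- roc_curve(val_scores, y[train_sp])
      val_auc <- val_roc$auc
      val_pr <- pr_curve(val_scores, y[train_sp])$auc
    } else {
      per <- vapply(fold_metrics, function(fm)
        c(roc_curve(fm$scores, fm$labels)$auc,
          pr_curve(fm$scores, fm$labels)$auc), numeric(2))
      val_auc <- mean(per[1, ]); val_pr <- mean(per[2, ])
      val_roc <- roc_curve(val_scores, y[train_sp])
    }
    vm <- threshold_metrics(val_scores, y[train_sp])
    tm <- threshold_metrics(test_scores, test_labels)
    rows[[r]] <- data.frame(
      replicate = r, seed = seed,
      val_auc_roc = val_auc, val_auc_pr = val_pr, val_f1 = vm$f1,
      val_precision = vm$precision, val_recall = vm$recall,
      test_auc_roc = roc_curve(test_scores, test_labels)$auc,
      test_auc_pr = pr_curve(test_scores, test_labels)$auc,
      test_f1 = tm$f1, test_precision = tm$precision, test_recall = tm$recall,
      n_estimators = best$n_estimators, max_depth = best$max_depth,
      max_features = as.character(best$max_features))
    confs[[r]] <- vm$confusion
    rocs[[r]] <- interp_roc(val_roc, fpr_grid)
    selected[[r]] <- feats
  }
  metrics <- do.call(rbind, rows)
  roc_mat <- do.call(rbind, rocs)
  structure(
    list(metrics = metrics,
         mean_confusion = Reduce(`+`, confs) / length(confs),
         mean_roc = data.frame(fpr = fpr_grid,
                               tpr = colMeans(roc_mat),
                               tpr_sd = apply(roc_mat, 2, sd)),
         selected_features = selected,
         n_replicates = n_replicates,
         settings = list(holdout_frac = holdout_frac, k = k,
                         n_select = n_select, base_seed = base_seed,
                         pooled = pooled,
                         validation_auc = if (pooled)
                           "pooled out-of-fold" else "per-fold average")),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> %d replicate(s); validation AUC-ROC %.3f, ",
           "F1 %.3f; test AUC-ROC %.3f, F1 %.3f (%s validation AUC)\n"),
    x$n_replicates, mean(x$metrics$val_auc_roc), mean(x$metrics$val_f1),
    mean(x$metrics$test_auc_roc), mean(x$metrics$test_f1),
    x$settings$validation_auc))
  invisible(x)
}

# ---- serialization --------------------------------------------------------

#' Serialize a forest model to JSON
#'
#' @param model a [fit_forest()] model.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_forest <- function(model, path) {
  obj <- unclass(model)
  obj$trees <- lapply(obj$trees, unclass)
  if (is.infinite(obj$hyperparams$max_depth))
    obj$hyperparams$max_depth <- NULL  # JSON has no Inf; reader restores it
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a forest model written by [write_forest()]
#'
#' @param path the JSON file.
#' @return a `forest_model`.
#' @export
read_forest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) vapply(v, function(x)
    if (is.null(x)) NA_real_ else as.numeric(x), 0)
  trees <- lapply(raw$trees, function(tr) {
    out <- list(feature = as.integer(num(tr$feature)),
                threshold = num(tr$threshold),
                left = as.integer(num(tr$left)),
                right = as.integer(num(tr$right)),
                n_samples = as.integer(num(tr$n_samples)),
                n0 = as.integer(num(tr$n0)), n1 = as.integer(num(tr$n1)),
                impurity = num(tr$impurity), value = num(tr$value))
    class(out) <- "famtrait_tree"
    out
  })
  structure(
    list(trees = trees,
         feature_order = unlist(raw$feature_order),
         hyperparams = list(
           n_estimators = as.integer(raw$hyperparams$n_estimators),
           max_depth = as.numeric(raw$hyperparams$max_depth %||% Inf),
           max_features = raw$hyperparams$max_features,
           bootstrap = isTRUE(raw$hyperparams$bootstrap)),
         seed = as.integer(raw$seed),
         class_order = as.integer(unlist(raw$class_order)),
         n_train = as.integer(raw$n_train)),
    class = "forest_model")
}

#' Consensus selected features across replicates
#'
#' The stable feature set of a replicated run: families ranked by how often
#' they appear in the per-replicate top-`n_select` lists (ties by mean
#' within-replicate rank, then identifier).
#'
#' @param report an [evaluate_replicates()] result.
#' @param n_select how many consensus features to return (default: the
#'   per-replicate selection size).
#' @return character vector of family identifiers.
#' @export
consensus_features <- function(report,
                               n_select = length(report$selected_features[[1]])) {
  sel <- report$selected_features
  freq <- table(unlist(sel))
  mean_rank <- tapply(
    unlist(lapply(sel, seq_along)), unlist(sel), mean)
  fams <- names(freq)
  ord <- order(-as.integer(freq), mean_rank[fams], fams)
  head(fams[ord], n_select)
}
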