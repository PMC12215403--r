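test_that("gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(c(3, 3)), 0.5)
  expect_equal(gini_impurity(c(5, 0)), 0)
  expect_equal(gini_impurity(c(2, 6)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "positive sum")
})

test_that("a single tree finds the exhaustive best split on 1-D data", {
  tr <- grow_tree(matrix(c(0, 0, 5, 5), 4), c(0L, 0L, 1L, 1L))
  expect_equal(tr$feature[1], 0L)
  expect_equal(tr$threshold[1], 2.5)
  leaves <- which(tr$feature < 0L)
  expect_equal(sort(tr$impurity[leaves]), c(0, 0))
})

test_that("pure labels give a single leaf of depth zero", {
  tr <- grow_tree(matrix(1:6, 3), rep(1L, 3))
  expect_length(tr$feature, 1)
  expect_equal(tr$feature, -1L)
  expect_equal(tr$value, 1)
})

test_that("the first split matches a brute-force oracle on random data", {
  for (seed in 1:40) {
    fx <- random_instances(n = sample(4:10, 1), p = sample(2:4, 1),
                           seed = seed)
    tr <- grow_tree(fx$X, fx$y, max_depth = 1)
    oracle <- oracle_best_split(fx$X, fx$y)
    if (is.na(oracle$feature)) {
      expect_equal(tr$feature[1], -1L)
    } else {
      expect_equal(tr$feature[1] + 1L, oracle$feature)
      expect_equal(tr$threshold[1], oracle$threshold)
    }
  }
})

test_that("forests are deterministic, reducible, and fit separable data", {
  fx <- random_instances(n = 20, p = 5, seed = 11)
  m1 <- fit_forest(fx$X, fx$y, n_estimators = 10, max_depth = 5, seed = 3)
  m2 <- fit_forest(fx$X, fx$y, n_estimators = 10, max_depth = 5, seed = 3)
  expect_equal(predict_proba(m1, fx$X), predict_proba(m2, fx$X))

  # one tree, no bootstrap, all features = a plain CART on the full data
  m3 <- fit_forest(fx$X, fx$y, n_estimators = 1, max_features = "all",
                   bootstrap = FALSE, max_depth = 4, seed = 5)
  t3 <- grow_tree(fx$X, fx$y, max_depth = 4, max_features = "all")
  expect_equal(m3$trees[[1]]$feature, t3$feature)
  expect_equal(m3$trees[[1]]$threshold, t3$threshold)

  # linearly separable 1-D data is fit perfectly
  X <- matrix(c(1:10), 10)
  y <- as.integer(X[, 1] > 5)
  m4 <- fit_forest(X, y, n_estimators = 25, max_depth = 5, seed = 1)
  expect_equal(as.integer(predict_proba(m4, X) > 0.5), y)

  expect_error(fit_forest(X, rep(1L, 10), n_estimators = 2), "single class")
})

test_that("predicted probabilities respect label complementation", {
  fx <- random_instances(n = 16, p = 4, seed = 21)
  m <- fit_forest(fx$X, fx$y, n_estimators = 15, max_depth = 4, seed = 9)
  mc <- fit_forest(fx$X, 1L - fx$y, n_estimators = 15, max_depth = 4,
                   seed = 9)
  expect_equal(predict_proba(m, fx$X), 1 - predict_proba(mc, fx$X),
               tolerance = 1e-12)
})

test_that("Gini importance matches a hand-computed stump fixture", {
  # single deterministic tree: root split on f1 (perfect 4/4 -> leaves with
  # one mislabelled sample on the right), then a second split on f2
  X <- cbind(f1 = c(0, 0, 0, 0, 1, 1, 1, 1),
             f2 = c(0, 1, 0, 1, 0, 0, 1, 1))
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 1L)
  tr <- grow_tree(X, y, max_depth = Inf, max_features = "all")
  m <- structure(
    list(trees = list(tr), feature_order = colnames(X),
         hyperparams = list(n_estimators = 1L, max_depth = Inf,
                            max_features = "all", bootstrap = FALSE),
         seed = 0L, class_order = c(0L, 1L), n_train = 8L),
    class = "forest_model")
  imp <- gini_importance(m)
  # by hand: root impurity 0.46875, split f1 -> (4:0, 1:3)
  # delta_root = 0.46875 - 0.5*0 - 0.5*0.375 = 0.28125, weight 8/8
  # right node (n=4, imp 0.375) splits f2 -> (0,2 imp 0) and (1,1 imp 0.5)
  # delta = 0.375 - 0.5*0 - 0.5*0.5 = 0.125, weight 4/8 -> 0.0625
  raw <- c(f1 = 0.28125, f2 = 0.0625)
  expect_equal(setNames(imp$importance, imp$family), raw / sum(raw))
  expect_equal(sum(imp$importance), 1)
})

test_that("importance is zero for unused features and one for a lone split", {
  X <- cbind(a = c(0, 0, 5, 5), b = c(1, 1, 1, 1))
  y <- c(0L, 0L, 1L, 1L)
  m <- fit_forest(X, y, n_estimators = 5, max_features = "all",
                  max_depth = 3, seed = 2)
  imp <- gini_importance(m)
  expect_equal(imp$importance[imp$family == "a"], 1)
  expect_equal(imp$importance[imp$family == "b"], 0)
})

test_that("feature selection ranks all features when n_select = p", {
  fx <- random_instances(n = 20, p = 6, seed = 31)
  sel <- select_top_features(fx$X, fx$y, n_select = 6, n_estimators = 20,
                             seed = 4)
  expect_setequal(sel, colnames(fx$X))
  expect_equal(select_top_features(fx$X, fx$y, 3, n_estimators = 20,
                                   seed = 4),
               select_top_features(fx$X, fx$y, 3, n_estimators = 20,
                                   seed = 4))
  expect_error(select_top_features(fx$X, fx$y, 9, n_estimators = 5),
               "exceeds")
})

test_that("ROC/PR/threshold metrics agree with hand counts and edge cases", {
  # 4-sample hand case: 3 of 4 label-score pairs concordant
  roc <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(roc$auc, 0.75)
  expect_equal(roc_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")

  pr <- pr_curve(c(4, 3, 2, 1), c(1, 1, 0, 0))
  expect_equal(pr$auc, 1)

  tm <- threshold_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(tm$precision, 0.5)
  expect_equal(tm$recall, 0.5)
  expect_equal(tm$f1, 0.5)
  expect_equal(rowSums(tm$confusion), c(`0` = 1, `1` = 1))
})

test_that("metrics agree with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    scores <- runif(40)
    labels <- rbinom(40, 1, plogis(3 * (scores - 0.5)))
  })
  if (length(unique(labels)) < 2) labels[1] <- 1 - labels[1]
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("forest predictions track an established RF on a shared fixture", {
  skip_if_not_installed("randomForest")
  withr::with_seed(13, {
    X <- matrix(sample(0:5, 60 * 8, replace = TRUE), 60, 8)
    colnames(X) <- paste0("OG", 1:8)
    y <- as.integer(X[, 1] + X[, 2] + rnorm(60) > 5)
  })
  ours <- predict_proba(
    fit_forest(X, y, n_estimators = 300, max_depth = 10, seed = 1), X)
  rf <- randomForest::randomForest(X, factor(y), ntree = 300)
  theirs <- predict(rf, X, type = "prob")[, "1"]
  # sanity harness, not exact-match: the two implementations must broadly
  # agree on which species look resistant
  expect_gt(cor(ours, theirs), 0.85)
})

test_that("grid search returns the single cell or the dominant cell", {
  fx <- random_instances(n = 24, p = 4, seed = 41)
  names(fx$y) <- rownames(fx$X) <- sprintf("s%02d", 1:24)
  folds <- split(rownames(fx$X), rep(1:3, length.out = 24))
  one <- data.frame(n_estimators = 10L, max_features = "sqrt", max_depth = 3)
  gs <- grid_search(fx$X, fx$y, folds, grid = one, seed = 2)
  expect_equal(gs$best$n_estimators, 10L)
  expect_equal(nrow(gs$cv_table), 1)

  grid <- data.frame(n_estimators = c(10L, 25L),
                     max_features = "sqrt", max_depth = c(3, 5))
  gs2 <- grid_search(fx$X, fx$y, folds, grid = grid, seed = 2)
  expect_equal(nrow(gs2$cv_table), 2)
  expect_equal(gs2$best$mean_f1, max(gs2$cv_table$mean_f1))
})

test_that("replicated evaluation is reproducible and exact on easy data", {
  # perfectly separable fixture
  withr::with_seed(17, {
    X <- cbind(sig = rep(c(0, 10), each = 20),
               noise = matrix(sample(0:3, 40 * 5, TRUE), 40, 5))
    colnames(X) <- c("sig", paste0("n", 1:5))
    rownames(X) <- sprintf("s%02d", 1:40)
  })
  y <- setNames(rep(c(0L, 1L), each = 20), rownames(X))
  rep1 <- evaluate_replicates(
    list(X = X, y = y), n_replicates = 2, holdout_frac = 0.1, k = 3,
    n_select = 3, select_n_estimators = 30, cv_select_n_estimators = 30,
    grid = data.frame(n_estimators = 20L, max_features = "all",
                      max_depth = 5),
    base_seed = 5)
  expect_equal(mean(rep1$metrics$val_auc_roc), 1)
  expect_equal(mean(rep1$metrics$test_f1), 1)
  expect_equal(unname(rep1$mean_confusion), diag(2))
  expect_true(all(rep1$metrics$val_f1 == 1))

  rep2 <- evaluate_replicates(
    list(X = X, y = y), n_replicates = 2, holdout_frac = 0.1, k = 3,
    n_select = 3, select_n_estimators = 30, cv_select_n_estimators = 30,
    grid = data.frame(n_estimators = 20L, max_features = "all",
                      max_depth = 5),
    base_seed = 5)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$mean_roc, rep2$mean_roc)

  # consensus features surface the signal column first
  expect_equal(consensus_features(rep1)[1], "sig")
})

test_that("random labels give chance-level validation AUC", {
  withr::with_seed(29, {
    X <- matrix(sample(0:4, 60 * 30, TRUE), 60, 30)
    colnames(X) <- paste0("OG", 1:30)
    rownames(X) <- sprintf("s%02d", 1:60)
    y <- setNames(sample(rep(c(0L, 1L), each = 30)), rownames(X))
  })
  rep <- evaluate_replicates(
    list(X = X, y = y), n_replicates = 10, holdout_frac = 0.1, k = 5,
    n_select = 10, select_n_estimators = 50, cv_select_n_estimators = 50,
    grid = data.frame(n_estimators = 40L, max_features = "sqrt",
                      max_depth = 5),
    base_seed = 7)
  expect_gte(mean(rep$metrics$val_auc_roc), 0.35)
  expect_lte(mean(rep$metrics$val_auc_roc), 0.65)
})

test_that("forest models survive a JSON round-trip", {
  fx <- random_instances(n = 15, p = 4, seed = 51)
  m <- fit_forest(fx$X, fx$y, n_estimators = 4, max_depth = 4, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_forest(m, f)
  back <- read_forest(f)
  expect_equal(predict_proba(back, fx$X), predict_proba(m, fx$X))
  expect_equal(back$feature_order, m$feature_order)
  expect_equal(gini_importance(back), gini_importance(m))
})
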