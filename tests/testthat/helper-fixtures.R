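# Shared fixtures and independent oracles, built in code at test time.

make_curve <- function(species = "spA", dose = 0, replicate = 1L,
                       times = 0:10, od = rep(0.5, 11),
                       condition = "stressor") {
  growth_curve(species, condition, dose, replicate, times, od)
}

# deterministic phenotype table with distinct values: species sp001..spN,
# relative growth at both doses strictly increasing with species index
synthetic_phenotypes <- function(n) {
  sp <- sprintf("sp%03d", seq_len(n))
  data.frame(
    species = rep(sp, 2),
    dose_mM = rep(c(1, 2), each = n),
    relative_growth = c(seq(0.01, 0.99, length.out = n),
                        seq(0.02, 0.98, length.out = n)),
    n_replicates = 3L)
}

random_instances <- function(n = 8, p = 3, seed = 1, max_count = 5) {
  withr::with_seed(seed, {
    X <- matrix(sample(0:max_count, n * p, replace = TRUE), n, p)
    colnames(X) <- paste0("OG", seq_len(p))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) == 1L) y[1] <- 1L - y[1]
    list(X = X, y = y)
  })
}

# independent exhaustive CART oracle: best first split over all features and
# all midpoints of consecutive distinct values
oracle_best_split <- function(X, y) {
  n <- nrow(X)
  gini <- function(yy) {
    m <- length(yy)
    p0 <- sum(yy == 0) / m
    p1 <- sum(yy == 1) / m
    1 - p0 * p0 - p1 * p1
  }
  parent <- gini(y)
  best <- list(gain = 1e-12, feature = NA, threshold = NA)
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- v[i] + (v[i + 1] - v[i]) / 2
      left <- X[, f] <= thr
      gain <- parent - sum(left) / n * gini(y[left]) -
        sum(!left) / n * gini(y[!left])
      if (gain > best$gain) best <- list(gain = gain, feature = f,
                                         threshold = thr)
    }
  }
  best
}

# upper-tail hypergeometric by direct enumeration with choose()
oracle_hyper_upper <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# small forest on few distinct features, for SHAP oracle comparisons
small_random_forest <- function(seed, n = 30, p = 6, n_trees = 4,
                                max_depth = 3) {
  withr::with_seed(seed, {
    X <- matrix(sample(0:4, n * p, replace = TRUE), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    y <- as.integer(X[, 1] + X[, 2] * runif(1) + rnorm(n) > 2.5)
    if (length(unique(y)) == 1L) y[1] <- 1L - y[1]
  })
  fit_forest(X, y, n_estimators = n_trees, max_depth = max_depth,
             max_features = "sqrt", seed = seed + 1)
  }
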