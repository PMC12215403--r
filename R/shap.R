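#' Conditional expectation of a single tree given a feature subset
#'
#' Descends the tree: at a node whose split feature is in `S` it follows
#' `x`'s branch; otherwise it averages both branches weighted by their
#' training sample counts. With `S` equal to all features this is the tree's
#' ordinary prediction; with `S` empty it is the training-weighted mean of
#' the leaf values (the tree's base value).
#'
#' @param tree a `famtrait_tree` (see [grow_tree()]).
#' @param x numeric feature vector in the tree's training column order.
#' @param S integer vector of conditioned feature indices (1-based).
#' @return the expected class-1 probability.
#' @export
tree_expected_value <- function(tree, x, S = integer(0)) {
  rec <- function(node) {
    f <- tree$feature[node] + 1L
    if (f == 0L) return(tree$value[node])
    if (f %in% S) {
      child <- if (x[f] <= tree$threshold[node]) tree$left[node]
               else tree$right[node]
      return(rec(child))
    }
    l <- tree$left[node]; r <- tree$right[node]
    (tree$n_samples[l] * rec(l) + tree$n_samples[r] * rec(r)) /
      tree$n_samples[node]
  }
  rec(1L)
}

used_features <- function(model) {
  sort(unique(unlist(lapply(model$trees,
                            function(tr) tr$feature[tr$feature >= 0L])))) + 1L
}

#' Exact Shapley values by subset enumeration
#'
#' The classical Shapley formula applied to the forest's path-dependent
#' conditional expectation value function: an exponential-time oracle for
#' [shap_tree()], usable when the model touches at most 20 distinct features.
#'
#' @param model a [fit_forest()] model.
#' @param x numeric feature vector in `model$feature_order` order.
#' @return list with `phi` (named attribution vector over all model
#'   features; features unused by every tree get exactly 0) and `base_value`.
#' @export
shap_bruteforce <- function(model, x) {
  stopifnot(inherits(model, "forest_model"))
  U <- used_features(model)
  m <- length(U)
  if (m > 20L)
    stopf("%d distinct features used; enumeration capped at 20 - use shap_tree()",
          m)
  v_of <- function(S) mean(vapply(model$trees, tree_expected_value, 0,
                                  x = x, S = S))
  nsub <- bitwShiftL(1L, m)
  v <- numeric(nsub)
  for (mask in seq_len(nsub) - 1L) {
    S <- U[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    v[mask + 1L] <- v_of(S)
  }
  fact <- factorial(0:max(m, 1))
  phi <- setNames(numeric(length(model$feature_order)), model$feature_order)
  for (i in seq_len(m)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in seq_len(nsub) - 1L) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L))
      w <- fact[s + 1L] * fact[m - s] / fact[m + 1L]
      phi[U[i]] <- phi[U[i]] +
        w * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
    }
  }
  list(phi = phi, base_value = v[1L])
}

# Path-dependent TreeSHAP for one tree and one instance (Lundberg et al.'s
# EXTEND/UNWIND recursion over training-weighted paths). Path state m is a
# list of parallel vectors: d (feature index, 0 = root dummy), z (zero
# fraction), o (one fraction), w (permutation weight).
treeshap_one <- function(tree, x, p) {
  phi <- numeric(p)

  extend <- function(m, pz, po, pi) {
    l <- length(m$d)
    m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
    m$w <- c(m$w, if (l == 0L) 1 else 0)
    if (l > 0L) for (i in l:1) {
      m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / (l + 1)
      m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
    }
    m
  }

  unwind <- function(m, i) {
    l <- length(m$d)
    n <- m$w[l]
    if (l > 1L) for (j in (l - 1L):1L) {
      if (m$o[i] != 0) {
        t <- m$w[j]
        m$w[j] <- n * l / (j * m$o[i])
        n <- t - m$w[j] * m$z[i] * (l - j) / l
      } else {
        m$w[j] <- m$w[j] * l / (m$z[i] * (l - j))
      }
    }
    if (i < l) for (j in i:(l - 1L)) {
      m$d[j] <- m$d[j + 1L]; m$z[j] <- m$z[j + 1L]; m$o[j] <- m$o[j + 1L]
    }
    m$d <- m$d[-l]; m$z <- m$z[-l]; m$o <- m$o[-l]; m$w <- m$w[-l]
    m
  }

  unwound_sum <- function(m, i) sum(unwind(m, i)$w)

  recurse <- function(node, m, pz, po, pi) {
    m <- extend(m, pz, po, pi)
    f <- tree$feature[node] + 1L
    if (f == 0L) {  # leaf
      l <- length(m$d)
      if (l >= 2L) for (i in 2L:l) {
        w <- unwound_sum(m, i)
        phi[m$d[i]] <<- phi[m$d[i]] +
          w * (m$o[i] - m$z[i]) * tree$value[node]
      }
      return(invisible(NULL))
    }
    lchild <- tree$left[node]; rchild <- tree$right[node]
    if (x[f] <= tree$threshold[node]) {
      hot <- lchild; cold <- rchild
    } else {
      hot <- rchild; cold <- lchild
    }
    iz <- 1; io <- 1
    k <- match(f, m$d)
    if (!is.na(k)) {
      iz <- m$z[k]; io <- m$o[k]
      m <- unwind(m, k)
    }
    rj <- tree$n_samples[node]
    recurse(hot, m, iz * tree$n_samples[hot] / rj, io, f)
    recurse(cold, m, iz * tree$n_samples[cold] / rj, 0, f)
    invisible(NULL)
  }

  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0)), 1, 1, 0L)
  phi
}

#' Exact TreeSHAP attributions for every instance
#'
#' Polynomial-time path-dependent TreeSHAP: per tree, Shapley values of the
#' training-weighted conditional expectation; per-tree attributions and base
#' values are averaged over the forest (whose prediction is the mean of its
#' trees). Satisfies local accuracy: for every row,
#' `base_value + sum(phi) == predict_proba()` to numerical precision.
#'
#' @param model a [fit_forest()] model.
#' @param X matrix of instances (columns must include the model features).
#' @return an object of class `shap_matrix`: list with `phi` (instances x
#'   model features), `base_value` (scalar), `model_output` (per-instance
#'   predicted probability), `species` (rownames of `X`).
#' @export
shap_tree <- function(model, X) {
  stopifnot(inherits(model, "forest_model"))
  X <- align_features(model, X)
  p <- ncol(X)
  phi <- matrix(0, nrow(X), p,
                dimnames = list(rownames(X), model$feature_order))
  for (s in seq_len(nrow(X))) {
    x <- X[s, ]
    acc <- numeric(p)
    for (tr in model$trees) acc <- acc + treeshap_one(tr, x, p)
    phi[s, ] <- acc / length(model$trees)
  }
  base <- mean(vapply(model$trees, function(tr) tr$value[1L], 0))
  structure(
    list(phi = phi, base_value = base,
         model_output = predict_proba(model, X),
         species = rownames(X)),
    class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d instance(s) x %d feature(s), base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' Write a SHAP matrix to TSV
#'
#' @param shap a [shap_tree()] result.
#' @param path destination TSV (species, one column per feature, plus
#'   `base_value` and `model_output`).
#' @return `path`, invisibly.
#' @export
write_shap <- function(shap, path) {
  df <- data.frame(species = rownames(shap$phi), shap$phi,
                   base_value = shap$base_value,
                   model_output = shap$model_output, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Pair SHAP values with gene-family counts for one family
#'
#' Per-species (count, phi) pairs plus, when one exists, the minimal
#' separating count `c_star` such that `phi > 0` exactly for species with
#' `count >= c_star` (the "two or more copies" pattern).
#'
#' @param shap a [shap_tree()] result.
#' @param counts species x family count matrix.
#' @param family the family (orthogroup) identifier.
#' @return list with `pairs` (data frame `species`, `count`, `phi`) and
#'   `c_star` (minimal separating count, or `NA` when none exists, e.g. when
#'   phi is identically zero or the pattern is not monotone).
#' @export
shap_vs_count <- function(shap, counts, family) {
  if (!family %in% colnames(shap$phi))
    stopf("family '%s' not among explained features", family)
  if (!family %in% colnames(counts))
    stopf("family '%s' not in the count matrix", family)
  sp <- intersect(rownames(shap$phi), rownames(counts))
  pairs <- data.frame(species = sp,
                      count = counts[sp, family],
                      phi = shap$phi[sp, family])
  rownames(pairs) <- NULL
  c_star <- NA_real_
  if (any(pairs$phi > 0)) {
    for (cand in sort(unique(pairs$count))) {
      if (all((pairs$phi > 0) == (pairs$count >= cand))) {
        c_star <- cand
        break
      }
    }
  }
  list(pairs = pairs, c_star = c_star)
}
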