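#' Read a rooted Newick tree
#'
#' Thin wrapper around `ape::read.tree` with validation: tip labels must be
#' unique, branch lengths present and finite. Internal support values are
#' retained (as `node.label`) but never used.
#'
#' @param path a Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stopf("could not parse Newick in '%s'", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip label(s): %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stopf("branch lengths must be finite and non-negative")
  tree
}

#' Write a tree to Newick
#'
#' @param tree an `ape::phylo` tree.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Prune a tree to a species subset
#'
#' Restricts the tree to `keep`; unary internal nodes left behind are
#' collapsed with their branch lengths summed, so tip-to-tip path lengths
#' are preserved.
#'
#' @param tree an `ape::phylo` tree.
#' @param keep character vector of tip labels to retain.
#' @return the pruned tree.
#' @export
prune <- function(tree, keep) {
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss))
    stopf("species not in tree: %s", paste(miss, collapse = ", "))
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Brownian-motion covariance matrix of a tree
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `V[i, i]` is the root-to-tip length. Symmetric positive semidefinite; the
#' expected trait covariance under unit-rate Brownian motion.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return a species x species matrix in tip-label order.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y = b0 + b1 x` by GLS with error covariance proportional to the
#' Brownian-motion matrix of the tree (Pagel's lambda fixed at 1):
#' `beta = (X' V^-1 X)^-1 X' V^-1 y`, standard errors from
#' `sigma2 (X' V^-1 X)^-1` with `sigma2 = RSS_V / (n - 2)`, a two-sided t
#' test on the slope with `n - 2` degrees of freedom, and a signed
#' phylogeny-adjusted correlation `R = sign(b1) sqrt(1 - RSS_V / TSS_V)`
#' where `TSS_V` comes from the V-weighted intercept-only fit.
#'
#' @param x,y named numeric vectors defined on the tree's tips.
#' @param tree an `ape::phylo` tree covering the names of `x` and `y`.
#' @return an object of class `pgls_fit`: list with `intercept`, `slope`,
#'   `se`, `t`, `p`, `R`, `n`, `rss`, `tss`.
#' @export
pgls <- function(x, y, tree) {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  sp <- intersect(intersect(names(x), names(y)), tree$tip.label)
  n <- length(sp)
  if (n < 3L) stopf("PGLS needs at least 3 species with data on the tree")
  tr <- prune(tree, sp)
  V <- bm_covariance(tr)
  sp <- rownames(V)
  xv <- x[sp]; yv <- y[sp]
  Vi <- tryCatch(solve(V), error = function(e)
    stopf("singular phylogenetic covariance; consider jittering zero-length branches"))
  Xd <- cbind(1, xv)
  XtVi <- crossprod(Xd, Vi)
  beta <- solve(XtVi %*% Xd, XtVi %*% yv)
  resid <- yv - Xd %*% beta
  rss <- drop(crossprod(resid, Vi %*% resid))
  sigma2 <- rss / (n - 2)
  covb <- sigma2 * solve(XtVi %*% Xd)
  se <- sqrt(covb[2, 2])
  tstat <- beta[2] / se
  p <- 2 * pt(-abs(tstat), df = n - 2)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% yv) / crossprod(one, Vi %*% one))
  r0 <- yv - mu
  tss <- drop(crossprod(r0, Vi %*% r0))
  R <- if (tss > 0) sign(beta[2]) * sqrt(max(0, 1 - rss / tss)) else NA_real_
  structure(
    list(intercept = unname(beta[1]), slope = unname(beta[2]), se = se,
         t = unname(tstat), p = unname(p), R = unname(R), n = n,
         rss = rss, tss = tss),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "<pgls_fit> slope %.4g (SE %.3g), t = %.3f, p = %.3g, R = %.3f, n = %d\n",
    x$slope, x$se, x$t, x$p, x$R, x$n))
  cat("  (Brownian covariance, lambda = 1; R = signed sqrt of GLS R^2)\n")
  invisible(x)
}

#' Export iTOL annotation datasets
#'
#' Writes a valid iTOL `DATASET_SIMPLEBAR` (single value per tip) or
#' `DATASET_HEATMAP` (one column per field) annotation text file.
#'
#' @param values for `kind = "bar"`, a named numeric vector (names = tips);
#'   for `kind = "heatmap"`, a numeric matrix with species rownames and
#'   field colnames.
#' @param kind `"bar"` or `"heatmap"`.
#' @param path destination text file.
#' @param label dataset label shown in iTOL.
#' @param color dataset color.
#' @return `path`, invisibly.
#' @export
export_itol_annotations <- function(values, kind = c("bar", "heatmap"), path,
                                    label = "famtrait", color = "#1f78b4") {
  kind <- match.arg(kind)
  if (kind == "bar") {
    if (!length(values)) stopf("empty annotation table")
    stopifnot(!is.null(names(values)))
    lines <- c("DATASET_SIMPLEBAR", "SEPARATOR COMMA",
               paste0("DATASET_LABEL,", label), paste0("COLOR,", color),
               "DATA",
               paste(names(values), format(unname(values), trim = TRUE),
                     sep = ","))
  } else {
    if (!nrow(values) || !ncol(values)) stopf("empty annotation table")
    stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
    lines <- c("DATASET_HEATMAP", "SEPARATOR COMMA",
               paste0("DATASET_LABEL,", label), paste0("COLOR,", color),
               paste0("FIELD_LABELS,", paste(colnames(values), collapse = ",")),
               "DATA",
               vapply(seq_len(nrow(values)), function(i)
                 paste(c(rownames(values)[i],
                         format(values[i, ], trim = TRUE)), collapse = ","),
                 ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Two-sided Welch t-test between phenotype groups
#'
#' Convenience wrapper for pairwise comparisons (e.g. gene counts in the
#' resistant versus sensitive class).
#'
#' @param a,b numeric vectors.
#' @return list with `estimate` (mean difference a - b), `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  fit <- t.test(a, b)
  list(estimate = unname(diff(rev(fit$estimate))), t = unname(fit$statistic),
       df = unname(fit$parameter), p = fit$p.value)
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `t`, `df`, `p`.
#' @export
pearson_cor <- function(x, y) {
  fit <- cor.test(x, y)
  list(r = unname(fit$estimate), t = unname(fit$statistic),
       df = unname(fit$parameter), p = fit$p.value)
}

#' One-way ANOVA of a phenotype across groups
#'
#' E.g. mean resistance across taxonomic orders.
#'
#' @param value numeric response.
#' @param group grouping factor.
#' @return list with `F`, `df` (between, within), `p`.
#' @export
oneway_anova <- function(value, group) {
  fit <- summary(aov(value ~ factor(group)))[[1]]
  list(F = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}
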