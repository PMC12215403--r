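#' Collect the member genes of selected gene families for one species
#'
#' @param features character vector of orthogroup identifiers.
#' @param membership a [read_membership()] table.
#' @param species the species whose orthologs to retrieve.
#' @return the de-duplicated union of gene identifiers.
#' @export
genes_for_features <- function(features, membership, species) {
  unknown <- setdiff(features, names(membership))
  if (length(unknown))
    stopf("unknown orthogroup(s): %s", paste(unknown, collapse = ", "))
  if (!species %in% names(membership[[1]]))
    stopf("species '%s' not in membership table", species)
  sort(unique(unlist(lapply(membership[features], `[[`, species))))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure with monotonicity enforcement; invariant to the order
#' of the input.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return the adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Over-representation test with a custom background
#'
#' For every annotation term: `k` study genes with the term out of `n` study
#' genes, against `K` of `N` background genes. The one-sided
#' over-representation p value is the upper-tail hypergeometric probability
#' `P(X >= k)`; fold enrichment is `(k/n) / (K/N)`. P values are BH-adjusted
#' across all tested terms, then results are filtered to `k >= min_genes`
#' and `fdr < fdr_threshold` and sorted by decreasing fold.
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param annotations a data frame with columns `term_id`, `term_name`,
#'   `gene` (flat, pre-propagated term -> gene table), or a path to such a
#'   TSV. Genes outside the background are ignored; terms with no background
#'   gene are skipped.
#' @param min_genes minimum study hits for reporting (default 5).
#' @param fdr_threshold FDR cutoff for reporting (default 0.001).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"` (Fisher's exact test).
#' @return a list with `results` (the filtered, fold-sorted data frame) and
#'   `all` (every tested term, unfiltered). Columns: `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `p`, `fdr`.
#' @export
fisher_enrich <- function(study, background, annotations, min_genes = 5L,
                          fdr_threshold = 0.001,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- as.data.frame(data.table::fread(annotations,
                                                   colClasses = "character"))
  need <- c("term_id", "term_name", "gene")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stopf("annotations lack column(s): %s", paste(miss, collapse = ", "))
  study <- unique(study); background <- unique(background)
  outsiders <- setdiff(study, background)
  if (length(outsiders))
    stopf("study genes not in background: %s",
          paste(head(outsiders, 5), collapse = ", "))
  terms <- unique(annotations[, c("term_id", "term_name")])
  annotations <- annotations[annotations$gene %in% background, ]
  n <- length(study); N <- length(background)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(annotations$gene[annotations$term_id == terms$term_id[i]])
    K <- length(genes)
    if (K == 0L) {
      msgf("term %s has no background genes; skipped", terms$term_id[i])
      return(NULL)
    }
    k <- length(intersect(study, genes))
    p <- if (alternative == "greater") {
      phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                         alternative = "two.sided")$p.value
    }
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p = p)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(list(results = NULL, all = NULL))
  all <- do.call(rbind, rows)
  all$fdr <- bh_fdr(all$p)
  res <- all[all$k >= min_genes & all$fdr < fdr_threshold, , drop = FALSE]
  res <- res[order(-res$fold_enrichment, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  rownames(all) <- NULL
  list(results = res, all = all)
}
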