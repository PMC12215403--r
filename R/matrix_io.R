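#' Read an orthogroup gene-count matrix
#'
#' Reads an OrthoFinder `Orthogroups.GeneCount.tsv`-style TSV. The file may
#' be oriented either way; by default the orientation is inferred from the
#' first header cell (`Orthogroup`/`OG` means families in rows). A trailing
#' OrthoFinder `Total` row/column is dropped with a message. The returned
#' matrix is always species x families.
#'
#' @param path the TSV file.
#' @param orientation `"auto"`, `"families_rows"` or `"species_rows"`.
#' @return an integer matrix, species as rownames, orthogroups as colnames.
#' @export
read_orthogroup_counts <- function(path,
                                   orientation = c("auto", "families_rows",
                                                   "species_rows")) {
  orientation <- match.arg(orientation)
  df <- as.data.frame(data.table::fread(path))
  first <- names(df)[1]
  if (orientation == "auto") {
    orientation <- if (grepl("^(orthogroup|og|family)", tolower(first)))
      "families_rows" else "species_rows"
  }
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  if ("Total" %in% names(body)) {
    body <- body[, names(body) != "Total", drop = FALSE]
    msgf("dropped OrthoFinder 'Total' column")
  }
  if ("Total" %in% ids) {
    keep <- ids != "Total"
    body <- body[keep, , drop = FALSE]
    ids <- ids[keep]
    msgf("dropped OrthoFinder 'Total' row")
  }
  m <- as.matrix(body)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-negative-integer cell at row '%s', column '%s' (value %s)",
          ids[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (orientation == "families_rows") m <- t(m)
  if (anyDuplicated(rownames(m))) stopf("duplicate species identifiers")
  if (anyDuplicated(colnames(m))) stopf("duplicate orthogroup identifiers")
  m
}

#' Write a species x family count matrix as TSV
#'
#' @param counts integer matrix, species x families.
#' @param path destination TSV.
#' @param orientation write species in rows (default) or the OrthoFinder
#'   families-in-rows dialect.
#' @return `path`, invisibly.
#' @export
write_orthogroup_counts <- function(counts, path,
                                    orientation = c("species_rows",
                                                    "families_rows")) {
  orientation <- match.arg(orientation)
  if (orientation == "families_rows") {
    df <- data.frame(Orthogroup = colnames(counts), t(counts),
                     check.names = FALSE)
  } else {
    df <- data.frame(species = rownames(counts), counts, check.names = FALSE)
  }
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: one row per orthogroup,
#' one column per species, cells holding comma-separated gene lists (empty
#' cell = no members in that species).
#'
#' @param path the TSV file.
#' @return a named list: orthogroup -> named list species -> character vector
#'   of gene identifiers.
#' @export
read_membership <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = "character"))
  ogs <- df[[1]]
  species <- names(df)[-1]
  out <- lapply(seq_along(ogs), function(i) {
    row <- lapply(setNames(species, species), function(sp) {
      cell <- df[i, sp]
      if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
      genes <- trimws(strsplit(cell, ",")[[1]])
      genes <- genes[nzchar(genes)]
      if (anyDuplicated(genes))
        stopf("duplicate gene identifier '%s' in orthogroup %s, species %s",
              genes[duplicated(genes)][1], ogs[i], sp)
      genes
    })
    row
  })
  names(out) <- ogs
  out
}

#' Derive a count matrix from a membership table
#'
#' Used to cross-check that a membership table and a GeneCount matrix agree.
#'
#' @param membership output of [read_membership()].
#' @return an integer species x family matrix.
#' @export
membership_counts <- function(membership) {
  species <- names(membership[[1]])
  m <- vapply(membership, function(row) lengths(row)[species],
              integer(length(species)))
  rownames(m) <- species
  m
}

#' Balanced holdout split and stratified cross-validation folds
#'
#' Holds out `round(holdout_frac * N / 2)` species *per class* for testing
#' (so the test set is exactly class-balanced) and partitions the remaining
#' training species into `k` approximately class-balanced folds by a seeded
#' per-class shuffle followed by round-robin assignment.
#'
#' @param y named integer vector of 0/1 class labels (names = species).
#' @param holdout_frac fraction of all instances to hold out (default 0.1).
#' @param k number of cross-validation folds (default 10).
#' @param seed integer seed; the same seed always yields the same plan.
#' @return an object of class `split_plan`: list with `test_species`,
#'   `folds` (list of `k` disjoint species vectors covering the training
#'   set), and `seed`.
#' @export
make_split <- function(y, holdout_frac = 0.1, k = 10L, seed = 1L) {
  stopifnot(!is.null(names(y)), all(y %in% c(0L, 1L)))
  sp0 <- sort(names(y)[y == 0L]); sp1 <- sort(names(y)[y == 1L])
  if (!length(sp0) || !length(sp1)) stopf("both classes must be non-empty")
  n <- length(y)
  n_hold <- round(holdout_frac * n / 2)
  withr::with_seed(seed, {
    sh0 <- sample(sp0); sh1 <- sample(sp1)
    test <- sort(c(sh0[seq_len(n_hold)], sh1[seq_len(n_hold)]))
    tr0 <- sample(setdiff(sp0, test)); tr1 <- sample(setdiff(sp1, test))
    if (k > min(length(tr0), length(tr1)))
      stopf("k = %d exceeds the smallest training class (%d)",
            k, min(length(tr0), length(tr1)))
    # class 1 fills folds in reverse so the per-fold totals stay even
    folds <- lapply(seq_len(k), function(i) {
      sort(c(tr0[seq(i, length(tr0), by = k)],
             tr1[seq(k + 1L - i, length(tr1), by = k)]))
    })
  })
  structure(list(test_species = test, folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d test species, %d folds of %s (seed %d)\n",
              length(x$test_species), length(x$folds),
              paste(range(lengths(x$folds)), collapse = "-"), x$seed))
  invisible(x)
}

#' Serialize a split plan to JSON
#'
#' @param plan a [make_split()] result.
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
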