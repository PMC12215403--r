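#' Dual-concentration tail classification into binary trait classes
#'
#' Implements the two-tail rule that defines the binary resistance trait: the
#' `floor(f * N)` species with the *smallest* relative growth at the low dose
#' become class 0 (sensitive), and the `floor(f * N)` species with the
#' *largest* relative growth at the high dose become class 1 (resistant).
#' All other species are left unclassified and excluded from the instance
#' table (they are kept in the `middle` component for downstream
#' count-vs-growth correlations). Ties at a cutoff are broken by a stable
#' (value, species) sort and logged.
#'
#' @param phenotypes a data frame as returned by [phenotype_table()]
#'   (columns `species`, `dose_mM`, `relative_growth`).
#' @param low_dose,high_dose the two concentrations (mM) defining the tails.
#' @param f tail fraction per class, in (0, 0.5).
#' @return an object of class `trait_classes`: a list with `table` (data
#'   frame `species`, `class_label`), `rule`, `cutoffs` (realized phenotype
#'   thresholds), and `middle` (unclassified species).
#' @export
classify_tails <- function(phenotypes, low_dose = 1, high_dose = 2, f = 0.2) {
  if (!(f > 0 && f < 0.5)) stopf("f must be in (0, 0.5), got %g", f)
  lo <- phenotypes[phenotypes$dose_mM == low_dose, ]
  hi <- phenotypes[phenotypes$dose_mM == high_dose, ]
  if (!nrow(lo)) stopf("no phenotypes at low dose %g mM", low_dose)
  if (!nrow(hi)) stopf("no phenotypes at high dose %g mM", high_dose)
  both <- intersect(lo$species, hi$species)
  missing_any <- union(setdiff(lo$species, both), setdiff(hi$species, both))
  if (length(missing_any))
    stopf("species lacking a phenotype at both doses: %s",
          paste(sort(missing_any), collapse = ", "))
  lo <- lo[match(both, lo$species), ]
  hi <- hi[match(both, hi$species), ]

  n <- length(both)
  k <- floor(f * n)
  if (k < 1L) stopf("floor(f * N) = 0: too few species (N = %d)", n)

  ord_lo <- order(lo$relative_growth, lo$species)          # poorest first
  ord_hi <- order(-hi$relative_growth, hi$species)         # best first
  sensitive <- lo$species[ord_lo][seq_len(k)]
  resistant <- hi$species[ord_hi][seq_len(k)]
  cut_lo <- lo$relative_growth[ord_lo][k]
  cut_hi <- hi$relative_growth[ord_hi][k]
  if (any(lo$relative_growth[ord_lo][-seq_len(k)] == cut_lo) ||
      any(hi$relative_growth[ord_hi][-seq_len(k)] == cut_hi))
    msgf("boundary tie at a tail cutoff resolved by stable species-id order")

  overlap <- intersect(sensitive, resistant)
  if (length(overlap))
    stopf("tail rule degenerate: species in both classes: %s",
          paste(sort(overlap), collapse = ", "))

  tab <- data.frame(
    species = c(sensitive, resistant),
    class_label = rep(c(0L, 1L), each = k))
  tab <- tab[order(tab$species), ]
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         rule = list(low_dose = low_dose, high_dose = high_dose, f = f),
         cutoffs = c(low = cut_lo, high = cut_hi),
         middle = sort(setdiff(both, tab$species))),
    class = "trait_classes")
}

#' @export
print.trait_classes <- function(x, ...) {
  cat(sprintf(
    "<trait_classes> %d sensitive + %d resistant of %d species (f = %g, %g/%g mM)\n",
    sum(x$table$class_label == 0L), sum(x$table$class_label == 1L),
    nrow(x$table) + length(x$middle), x$rule$f, x$rule$low_dose,
    x$rule$high_dose))
  invisible(x)
}

#' Assemble the machine-learning instance table
#'
#' Restricts the orthogroup count matrix to the classified species and
#' appends the class column.
#'
#' @param classes a [classify_tails()] result.
#' @param counts a species x family count matrix (integer, species as
#'   rownames), e.g. from [read_orthogroup_counts()].
#' @return a list with `X` (numeric matrix, classified species x families,
#'   rows in species order) and `y` (integer 0/1 class labels, named by
#'   species).
#' @export
build_instance_table <- function(classes, counts) {
  stopifnot(inherits(classes, "trait_classes"))
  sp <- classes$table$species
  miss <- setdiff(sp, rownames(counts))
  if (length(miss))
    stopf("classified species missing from counts: %s",
          paste(miss, collapse = ", "))
  X <- counts[sp, , drop = FALSE]
  y <- setNames(classes$table$class_label, sp)
  list(X = X, y = y)
}

#' Write the instance table and its rule sidecar
#'
#' Emits a TSV (`species`, one column per orthogroup, `class`) and a JSON
#' sidecar recording the rule, realized cutoffs and unclassified species.
#'
#' @param instances output of [build_instance_table()].
#' @param classes the [classify_tails()] result used to build it.
#' @param path destination TSV; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_instance_table <- function(instances, classes, path) {
  df <- data.frame(species = rownames(instances$X),
                   instances$X, check.names = FALSE)
  df$class <- instances$y
  data.table::fwrite(df, path, sep = "\t")
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(rule = classes$rule, cutoffs = as.list(classes$cutoffs),
         unclassified = classes$middle),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an instance table written by [write_instance_table()]
#'
#' @param path the instance TSV.
#' @return a list with `X` and `y` as in [build_instance_table()].
#' @export
read_instance_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("species", "class") %in% names(df)))
    stopf("instance table must have 'species' and 'class' columns")
  X <- as.matrix(df[, setdiff(names(df), c("species", "class")), drop = FALSE])
  rownames(X) <- df$species
  list(X = X, y = setNames(as.integer(df$class), df$species))
}
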