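#' Construct a growth curve
#'
#' A single optical-density time series for one well: one species, one
#' condition, one dose, one replicate.
#'
#' @param species species identifier.
#' @param condition condition label (e.g. the stressor name).
#' @param dose concentration in mM; 0 denotes the untreated control.
#' @param replicate replicate index.
#' @param times time points in hours, strictly increasing.
#' @param od optical-density readings (OD600), same length as `times`.
#' @return an object of class `growth_curve`.
#' @export
growth_curve <- function(species, condition, dose, replicate, times, od) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od))
    stopf("times and od differ in length (%d vs %d)", length(times), length(od))
  if (length(times) < 2L)
    stopf("a growth curve needs at least 2 readings, got %d", length(times))
  if (any(!is.finite(times)) || any(!is.finite(od)))
    stopf("non-finite values in growth curve for species '%s'", species)
  if (any(diff(times) <= 0))
    stopf("times must be strictly increasing (species '%s', replicate %s)",
          species, replicate)
  if (dose < 0) stopf("dose must be >= 0, got %s", dose)
  structure(
    list(species = as.character(species), condition = as.character(condition),
         dose = as.numeric(dose), replicate = as.integer(replicate),
         times = times, od = od),
    class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s | %s %g mM | rep %d | %d readings over %g h\n",
              x$species, x$condition, x$dose, x$replicate,
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' Read plate-reader growth curves from CSV
#'
#' Accepts either a wide table (first column time, one column per well) or a
#' long table with columns `time`, `well`, `od`. Well metadata maps each well
#' to its species, condition, dose and replicate.
#'
#' @param path path to the readings CSV.
#' @param metadata a data frame with columns `well`, `species`, `condition`,
#'   `dose_mM`, `replicate`, or a path to such a CSV.
#' @return a list of [growth_curve()] objects, one per well.
#' @export
read_plate_table <- function(path, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- as.data.frame(data.table::fread(metadata))
  need <- c("well", "species", "condition", "dose_mM", "replicate")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))

  tab <- as.data.frame(data.table::fread(path))
  lower <- tolower(names(tab))
  if (all(c("time", "well", "od") %in% lower)) {
    names(tab) <- lower
    long <- tab[, c("time", "well", "od")]
  } else {
    long <- data.frame(
      time = rep(tab[[1]], ncol(tab) - 1L),
      well = rep(names(tab)[-1], each = nrow(tab)),
      od   = unlist(tab[-1], use.names = FALSE))
  }
  wells <- unique(long$well)
  unknown <- setdiff(wells, metadata$well)
  if (length(unknown))
    stopf("well(s) missing from metadata: %s", paste(unknown, collapse = ", "))

  lapply(setNames(wells, wells), function(w) {
    rows <- long[long$well == w, ]
    rows <- rows[order(rows$time), ]
    if (anyDuplicated(rows$time))
      stopf("duplicate timestamps for well %s", w)
    md <- metadata[match(w, metadata$well), ]
    growth_curve(md$species, md$condition, md$dose_mM, md$replicate,
                 rows$time, rows$od)
  })
}

#' Empirical area under a growth curve
#'
#' Trapezoidal integral of OD over time (OD.h), optionally after subtracting
#' the initial reading (negative values clipped at zero so the area stays
#' non-negative).
#'
#' @param curve a [growth_curve()].
#' @param baseline `"none"` (default) or `"subtract_initial"`.
#' @return the area in OD.h, a non-negative scalar.
#' @export
eauc <- function(curve, baseline = c("none", "subtract_initial")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(curve, "growth_curve"))
  od <- curve$od
  if (baseline == "subtract_initial") od <- pmax(od - od[1], 0)
  sum(diff(curve$times) * (head(od, -1) + tail(od, -1)) / 2)
}

#' Relative growth of a treated curve versus its untreated control
#'
#' The ratio of empirical areas under the curve; each curve is integrated on
#' its own time grid.
#'
#' @param treated,control [growth_curve()] objects for the same species and
#'   replicate; `control` must have dose 0.
#' @inheritParams eauc
#' @return the unitless EAUC ratio, or `NA_real_` with a warning when the
#'   control area is zero (invalid replicate, to be excluded upstream).
#' @export
relative_growth <- function(treated, control,
                            baseline = c("none", "subtract_initial")) {
  baseline <- match.arg(baseline)
  if (!identical(treated$species, control$species))
    stopf("treated (%s) and control (%s) species differ",
          treated$species, control$species)
  if (!identical(treated$replicate, control$replicate))
    stopf("treated and control replicates differ for species %s",
          treated$species)
  if (control$dose != 0)
    stopf("control curve for %s has dose %g, expected 0",
          control$species, control$dose)
  denom <- eauc(control, baseline)
  if (denom == 0) {
    warnf("control EAUC is 0 for species %s replicate %d; replicate invalid",
          control$species, control$replicate)
    return(NA_real_)
  }
  eauc(treated, baseline) / denom
}

#' Per-species relative-growth phenotypes
#'
#' Pairs every treated curve with the dose-0 control of the same species and
#' replicate, computes per-replicate EAUC ratios, and averages them into one
#' record per (species, dose). Replicates with a zero-area control, and
#' treated replicates without a matching control, are dropped with a warning.
#'
#' @param curves a list of [growth_curve()] objects (treated and controls).
#' @inheritParams eauc
#' @return a data frame with columns `species`, `dose_mM`, `relative_growth`,
#'   `n_replicates`, plus a `per_replicate` list column of the per-replicate
#'   ratios.
#' @export
phenotype_table <- function(curves, baseline = c("none", "subtract_initial")) {
  baseline <- match.arg(baseline)
  meta <- data.frame(
    species = vapply(curves, `[[`, "", "species"),
    dose = vapply(curves, `[[`, 0, "dose"),
    replicate = vapply(curves, `[[`, 0L, "replicate"))
  treated <- which(meta$dose > 0)
  if (!length(treated)) stopf("no treated (dose > 0) curves supplied")

  keys <- unique(meta[treated, c("species", "dose")])
  keys <- keys[order(keys$species, keys$dose), ]
  per_rep <- lapply(seq_len(nrow(keys)), function(i) {
    sp <- keys$species[i]; d <- keys$dose[i]
    idx <- which(meta$species == sp & meta$dose == d)
    ratios <- numeric(0)
    for (j in idx) {
      ctl <- which(meta$species == sp & meta$dose == 0 &
                     meta$replicate == meta$replicate[j])
      if (!length(ctl)) {
        warnf("no dose-0 control for species %s replicate %d; dropped",
              sp, meta$replicate[j])
        next
      }
      r <- relative_growth(curves[[j]], curves[[ctl[1]]], baseline)
      if (!is.na(r)) ratios <- c(ratios, r)
    }
    if (!length(ratios))
      warnf("species %s has no valid replicate at dose %g; excluded", sp, d)
    ratios
  })
  keep <- lengths(per_rep) > 0L
  out <- data.frame(
    species = keys$species[keep], dose_mM = keys$dose[keep],
    relative_growth = vapply(per_rep[keep], mean, 0),
    n_replicates = lengths(per_rep[keep]))
  rownames(out) <- NULL
  out$per_replicate <- per_rep[keep]
  out
}

#' Write a phenotype table to TSV
#'
#' @param phenotypes output of [phenotype_table()].
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  cols <- c("species", "dose_mM", "relative_growth", "n_replicates")
  data.table::fwrite(phenotypes[, cols], path, sep = "\t")
  invisible(path)
}
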