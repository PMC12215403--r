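run_config_defaults <- function() {
  list(
    paths = list(curves = NULL, metadata = NULL, counts = NULL,
                 membership = NULL, tree = NULL, annotations = NULL,
                 outdir = "famtrait_run"),
    rule = list(low_dose = 1, high_dose = 2, f = 0.2),
    ml = list(n_select = 50L, replicates = 10L, holdout_frac = 0.1,
              k_folds = 10L, seed = 1L,
              select_n_estimators = 500L, select_max_depth = 10,
              grid = list(n_estimators = 500L, max_features = "sqrt",
                          max_depth = 10)),
    shap = list(enabled = TRUE),
    pgls = list(families = character(0)),
    enrichment = list(species = NULL, min_genes = 5L, fdr_threshold = 0.001))
}

check_known_keys <- function(given, reference, prefix = "") {
  unknown <- setdiff(names(given), names(reference))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste0(prefix, unknown, collapse = ", "))
  for (key in names(given)) {
    if (is.list(reference[[key]]) && !is.null(names(reference[[key]])) &&
        is.list(given[[key]]))
      check_known_keys(given[[key]], reference[[key]],
                       prefix = paste0(prefix, key, "."))
  }
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML or JSON file, rejects unknown keys, and fills defaults.
#' Sections: `paths` (curves, metadata, counts, membership, tree,
#' annotations, outdir), `rule` (low_dose, high_dose, f), `ml` (n_select,
#' replicates, holdout_frac, k_folds, seed, selection-forest size, grid),
#' `shap`, `pgls` (families), `enrichment` (species, min_genes,
#' fdr_threshold).
#'
#' @param path a `.yaml`/`.yml` or `.json` config file.
#' @return a validated `run_config` list.
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- run_config_defaults()
  check_known_keys(cfg, defaults)
  merged <- modifyList(defaults, cfg)
  if (!is.null(merged$ml$grid) && is.list(merged$ml$grid))
    merged$ml$grid <- as.data.frame(merged$ml$grid,
                                    stringsAsFactors = FALSE)
  for (field in c("curves", "metadata", "counts")) {
    p <- merged$paths[[field]]
    if (is.null(p)) stopf("config paths.%s is required", field)
    if (!file.exists(p)) stopf("paths.%s: file not found: %s", field, p)
  }
  for (field in c("membership", "tree", "annotations")) {
    p <- merged$paths[[field]]
    if (!is.null(p) && !file.exists(p))
      stopf("paths.%s: file not found: %s", field, p)
  }
  if (length(merged$pgls$families) && is.null(merged$paths$tree))
    stopf("config paths.tree is required when pgls.families is set")
  if (!is.null(merged$enrichment$species) &&
      (is.null(merged$paths$membership) || is.null(merged$paths$annotations)))
    stopf("enrichment needs paths.membership and paths.annotations")
  class(merged) <- "run_config"
  merged
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full pipeline from a configuration
#'
#' Stages: phenotype (growth curves to relative-growth table), classify
#' (dual-tail rule, instance table), train (replicated evaluation protocol),
#' explain (TreeSHAP on a final model over all instances), pgls (for the
#' configured families), enrich (term over-representation of the selected
#' features' genes). Every stage writes its outputs under
#' `paths.outdir`; a `manifest.json` records the configuration, seeds and
#' per-output MD5 checksums. Two runs from the same config and inputs are
#' byte-identical apart from the log.
#'
#' @param config a [load_run_config()] result (or an equivalent list).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.list(config$ml$grid) && !is.data.frame(config$ml$grid))
    config$ml$grid <- as.data.frame(config$ml$grid, stringsAsFactors = FALSE)
  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  put <- function(name) {
    outputs[[length(outputs) + 1L]] <<- file.path(outdir, name)
    file.path(outdir, name)
  }

  log_stage("phenotype", "reading curves from %s", config$paths$curves)
  curves <- read_plate_table(config$paths$curves, config$paths$metadata)
  phenotypes <- phenotype_table(curves)
  write_phenotypes(phenotypes, put("phenotypes.tsv"))

  log_stage("classify", "dual-tail rule f = %g at %g/%g mM",
            config$rule$f, config$rule$low_dose, config$rule$high_dose)
  classes <- classify_tails(phenotypes, config$rule$low_dose,
                            config$rule$high_dose, config$rule$f)
  counts <- read_orthogroup_counts(config$paths$counts)
  instances <- build_instance_table(classes, counts)
  write_instance_table(instances, classes, put("instances.tsv"))
  outputs[[length(outputs) + 1L]] <- file.path(outdir, "instances.json")

  log_stage("train", "%d replicate(s), base seed %d",
            config$ml$replicates, config$ml$seed)
  report <- evaluate_replicates(
    instances, n_replicates = config$ml$replicates,
    holdout_frac = config$ml$holdout_frac, k = config$ml$k_folds,
    n_select = config$ml$n_select,
    select_n_estimators = config$ml$select_n_estimators,
    select_max_depth = config$ml$select_max_depth,
    grid = config$ml$grid, base_seed = config$ml$seed)
  data.table::fwrite(report$metrics, put("metrics.tsv"), sep = "\t")
  jsonlite::write_json(
    list(mean_confusion = report$mean_confusion,
         mean_roc = report$mean_roc,
         settings = report$settings,
         mean_metrics = as.list(colMeans(
           report$metrics[, !names(report$metrics) %in% "max_features"]))),
    put("evaluation.json"), auto_unbox = TRUE, digits = NA, na = "null")
  feats <- report$selected_features[[1L]]
  writeLines(feats, put("selected_features.txt"))

  final <- fit_forest(
    instances$X[, feats, drop = FALSE], instances$y,
    n_estimators = config$ml$grid$n_estimators[1],
    max_depth = config$ml$grid$max_depth[1],
    max_features = parse_max_features(config$ml$grid$max_features[1]),
    seed = config$ml$seed)
  write_forest(final, put("model.json"))
  imp <- gini_importance(final)
  data.table::fwrite(imp, put("importance.tsv"), sep = "\t")

  if (isTRUE(config$shap$enabled)) {
    log_stage("explain", "TreeSHAP over %d instances", nrow(instances$X))
    shap <- shap_tree(final, instances$X)
    write_shap(shap, put("shap.tsv"))
    if (!is.null(config$paths$tree)) {
      tree <- read_newick(config$paths$tree)
      keep <- intersect(tree$tip.label, rownames(shap$phi))
      top <- head(imp$family, min(10L, nrow(imp)))
      export_itol_annotations(shap$phi[keep, top, drop = FALSE],
                              "heatmap", put("shap_itol_heatmap.txt"),
                              label = "shap")
    }
  }

  if (length(config$pgls$families)) {
    log_stage("pgls", "%d famil(ies)", length(config$pgls$families))
    tree <- read_newick(config$paths$tree)
    rows <- lapply(config$pgls$families, function(fam) {
      res <- lapply(unique(phenotypes$dose_mM), function(d) {
        ph <- phenotypes[phenotypes$dose_mM == d, ]
        fit <- pgls(setNames(counts[ph$species, fam], ph$species),
                    setNames(ph$relative_growth, ph$species), tree)
        data.frame(family = fam, dose_mM = d, slope = fit$slope,
                   se = fit$se, t = fit$t, p = fit$p, R = fit$R, n = fit$n)
      })
      do.call(rbind, res)
    })
    data.table::fwrite(do.call(rbind, rows), put("pgls.tsv"), sep = "\t")
  }

  if (!is.null(config$enrichment$species)) {
    log_stage("enrich", "species %s", config$enrichment$species)
    membership <- read_membership(config$paths$membership)
    study <- genes_for_features(feats, membership,
                                config$enrichment$species)
    background <- genes_for_features(names(membership), membership,
                                     config$enrichment$species)
    enr <- fisher_enrich(study, background, config$paths$annotations,
                         min_genes = config$enrichment$min_genes,
                         fdr_threshold = config$enrichment$fdr_threshold)
    if (!is.null(enr$all))
      data.table::fwrite(enr$all, put("enrichment.tsv"), sep = "\t")
  }

  manifest <- list(
    config = unclass(config),
    seed = config$ml$seed,
    package_version = as.character(utils::packageVersion("famtrait")),
    outputs = lapply(setNames(outputs, basename(unlist(outputs))),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done", "outputs in %s", outdir)
  invisible(manifest)
}
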