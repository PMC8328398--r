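## Pipeline orchestration: validated run configuration, staged commands
## (simulate, extract, evaluate, cluster, gate, full) and reproducible run
## metadata.  A thin command-line wrapper over these functions ships in
## inst/scripts/octrad.R.

defaultConfig <- function() {
  list(
    output_dir = "octrad_run",
    seed = 1L,
    cohort = specToList(cohortSpec()),
    feature_set = "oct",             # f, rtc1, rtc2, rtc, oct
    slice_window = NULL,             # NULL = proportional mid-macular window
    protocol = list(trainFraction = 0.8, nIterations = 1000L, nFolds = 3L,
                    classifiers = c("LDA", "QDA", "RF", "SVM")),
    clustering = list(nComponents = 10L, kMax = 6L),
    gate = list(targetGroup = "nonrebounder", targetPct = 90),
    log_level = "info")
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (or accepts a list), fills defaults, and rejects
#' unknown keys with an error naming the offending key.
#'
#' @param config path to a YAML/JSON file, a list, or NULL for defaults.
#' @param seed optional seed overriding the config's.
#' @return validated config list.
#' @export
loadConfig <- function(config = NULL, seed = NULL) {
  base <- defaultConfig()
  user <- if (is.null(config)) list()
    else if (is.character(config)) {
      if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
    } else if (is.list(config)) config
    else stop("config must be a path, a list, or NULL")
  mergeValidate <- function(base, user, path = "") {
    bad <- setdiff(names(user), names(base))
    if (length(bad) > 0)
      stop("unknown config key: ", paste0(path, bad[1]))
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
          is.list(user[[nm]]))
        base[[nm]] <- mergeValidate(base[[nm]], user[[nm]],
                                    paste0(path, nm, "."))
      else base[nm] <- user[nm]
    }
    base
  }
  cfg <- mergeValidate(base, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$cohort$seed <- cfg$seed
  if (!cfg$feature_set %in% c("f", "rtc1", "rtc2", "rtc", "oct"))
    stop("feature_set must be one of f, rtc1, rtc2, rtc, oct")
  cfg
}

writeRunMetadata <- function(cfg, dir, stage) {
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  digest <- unname(tools::md5sum(tmp)); unlink(tmp)
  meta <- list(stage = stage, timestamp = format(Sys.time(), usetz = TRUE),
               config = cfg, config_digest = digest,
               manifest_version = featureBankManifest()@version,
               package_version = as.character(utils::packageVersion("octrad")))
  jsonlite::write_json(meta, file.path(dir, paste0("run_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(meta)
}

logStage <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Pipeline stage commands
#'
#' `runSimulate` writes a synthetic cohort (volumes, masks, surfaces,
#' labels, manifest) to `<output_dir>/cohort`.  `runExtract` computes the
#' per-compartment feature tables and the fused F_f / F_RTC / F_OCT CSVs.
#' `runEvaluate` runs the repeated-CV protocol on the configured feature
#' set and writes the metric summary, per-eye scores and selection audit.
#' `runCluster` writes hierarchical and K-means cluster reports on the
#' fused fluid features.  `runGate` writes the threshold table and the
#' target-confidence threshold.  `runFull` chains all five.  Every stage
#' drops a `run_<stage>.json` metadata file sufficient to reproduce it.
#'
#' @param config see [loadConfig()].
#' @param seed optional seed override.
#' @param force overwrite a non-empty output directory (simulate only).
#' @return the stage's principal artifact, invisibly (see details above).
#' @export
runSimulate <- function(config = NULL, seed = NULL, force = FALSE) {
  cfg <- loadConfig(config, seed)
  dir <- file.path(cfg$output_dir, "cohort")
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output dir not empty (use force = TRUE): ", dir)
  if (force && dir.exists(dir)) logStage(cfg, "simulate", "overwriting")
  spec <- specFromList(cfg$cohort)
  eyes <- generateCohort(spec)
  writeCohort(eyes, dir, spec)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeRunMetadata(cfg, cfg$output_dir, "simulate")
  logStage(cfg, "simulate", sprintf(
    "%d eyes (%d rebounder / %d non-rebounder) -> %s", length(eyes),
    spec@nRebounder, spec@nNonrebounder, dir))
  invisible(eyes)
}

#' @rdname runSimulate
#' @export
runExtract <- function(config = NULL, seed = NULL) {
  cfg <- loadConfig(config, seed)
  dir <- cfg$output_dir
  manifestPath <- file.path(dir, "cohort", "manifest.json")
  if (!file.exists(manifestPath))
    stop("missing cohort manifest (run simulate first): ", manifestPath)
  records <- readCohort(manifestPath)
  eyes <- lapply(records, loadEye)
  for (i in seq_along(eyes)) if (!is.na(records[[i]]@label))
    eyes[[i]]@label <- records[[i]]@label
  manifest <- featureBankManifest()
  tabs <- extractCohortFeatures(eyes, manifest,
                                sliceWindow = cfg$slice_window)
  for (nm in names(tabs))
    writeFeatureTable(tabs[[nm]], file.path(dir, paste0("features_", nm, ".csv")))
  writeFeatureTable(fuseTables(tabs, "f"), file.path(dir, "features_Ff.csv"))
  writeFeatureTable(fuseTables(tabs, "rtc"), file.path(dir, "features_FRTC.csv"))
  writeFeatureTable(fuseTables(tabs, "oct"), file.path(dir, "features_FOCT.csv"))
  writeManifest(manifest, file.path(dir, "feature_manifest.json"))
  writeRunMetadata(cfg, dir, "extract")
  logStage(cfg, "extract", sprintf("%d eyes x %d features per compartment",
                                   length(eyes), nrow(manifest@descriptors)))
  invisible(tabs)
}

featureSetTable <- function(cfg) {
  dir <- cfg$output_dir
  fname <- switch(cfg$feature_set,
    f = "features_Ff.csv", rtc = "features_FRTC.csv",
    oct = "features_FOCT.csv", rtc1 = "features_RTC1.csv",
    rtc2 = "features_RTC2.csv")
  path <- file.path(dir, fname)
  if (!file.exists(path))
    stop("missing feature table (run extract first): ", path)
  readFeatureTable(path)
}

cohortLabels <- function(cfg, ids) {
  lab <- data.table::fread(file.path(cfg$output_dir, "cohort", "labels.csv"))
  stats::setNames(lab$label, lab$eye_id)[ids]
}

#' @rdname runSimulate
#' @export
runEvaluate <- function(config = NULL, seed = NULL) {
  cfg <- loadConfig(config, seed)
  tab <- featureSetTable(cfg)
  labels <- cohortLabels(cfg, eyeIds(tab))
  protocol <- evalProtocol(
    trainFraction = cfg$protocol$trainFraction,
    nIterations = cfg$protocol$nIterations, nFolds = cfg$protocol$nFolds,
    classifiers = cfg$protocol$classifiers, seed = cfg$seed)
  results <- runProtocol(tab, labels, protocol)
  dir <- cfg$output_dir
  data.table::fwrite(cvSummary(results), file.path(dir, "cv_results.csv"))
  scores <- do.call(cbind, lapply(results, function(r) r@scores))
  data.table::fwrite(data.frame(eye_id = rownames(scores), scores),
                     file.path(dir, "cv_scores.csv"))
  data.table::fwrite(attr(results, "selectionAudit"),
                     file.path(dir, "selection_audit.csv"))
  writeRunMetadata(cfg, dir, "evaluate")
  logStage(cfg, "evaluate", sprintf("best classifier %s (AUC %.3f)",
    attr(results, "best"),
    results[[attr(results, "best")]]@metrics["AUC", "mean"]))
  invisible(results)
}

#' @rdname runSimulate
#' @export
runCluster <- function(config = NULL, seed = NULL) {
  cfg <- loadConfig(config, seed)
  tab <- featureSetTable(cfg)
  labels <- cohortLabels(cfg, eyeIds(tab))
  zn <- znormalize(tab)
  red <- pcaReduce(zn, cfg$clustering$nComponents)
  hier <- hierarchicalCut(red, 2L, labels)
  red2 <- pcaReduce(zn, 2L)
  kOpt <- elbowK(red2, cfg$clustering$kMax, seed = cfg$seed)
  km <- kmeansComposition(red2, as.integer(kOpt), labels, seed = cfg$seed)
  dir <- cfg$output_dir
  rep <- rbind(
    data.frame(method = "hierarchical", cluster = rownames(hier$composition),
               hier$composition, check.names = FALSE),
    data.frame(method = "kmeans", cluster = rownames(km$composition),
               km$composition, check.names = FALSE))
  data.table::fwrite(rep, file.path(dir, "cluster_report.csv"))
  writeRunMetadata(cfg, dir, "cluster")
  logStage(cfg, "cluster", sprintf("elbow k = %d%s", as.integer(kOpt),
    if (isTRUE(attr(kOpt, "weakElbow"))) " (weak elbow)" else ""))
  invisible(list(hierarchical = hier, kmeans = km, elbowK = kOpt))
}

#' @rdname runSimulate
#' @export
runGate <- function(config = NULL, seed = NULL) {
  cfg <- loadConfig(config, seed)
  dir <- cfg$output_dir
  scorePath <- file.path(dir, "cv_scores.csv")
  if (!file.exists(scorePath))
    stop("missing cv_scores.csv (run evaluate first): ", scorePath)
  sc <- data.table::fread(scorePath)
  labels <- cohortLabels(cfg, sc$eye_id)
  best <- setdiff(names(sc), "eye_id")[1]
  resPath <- file.path(dir, "cv_results.csv")
  if (file.exists(resPath)) {
    cvr <- data.table::fread(resPath)
    aucs <- cvr[cvr$metric == "AUC", ]
    best <- aucs$classifier[which.max(aucs$mean)]
  }
  scores <- sc[[best]]
  tab <- thresholdTable(scores, labels)
  found <- findThreshold(scores, labels, cfg$gate$targetGroup,
                         cfg$gate$targetPct)
  data.table::fwrite(tab, file.path(dir, "threshold_table.csv"))
  jsonlite::write_json(c(found, list(classifier = best)),
                       file.path(dir, "gate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeRunMetadata(cfg, dir, "gate")
  logStage(cfg, "gate", if (found$reachable)
    sprintf("threshold %.3f for %.0f%% %s (classifier %s)", found$threshold,
            cfg$gate$targetPct, cfg$gate$targetGroup, best)
    else "target unreachable")
  invisible(list(table = tab, found = found, classifier = best))
}

#' @rdname runSimulate
#' @export
runFull <- function(config = NULL, seed = NULL, force = FALSE) {
  cfg <- loadConfig(config, seed)
  runSimulate(cfg, force = force)
  runExtract(cfg)
  results <- runEvaluate(cfg)
  clusters <- runCluster(cfg)
  gate <- runGate(cfg)
  invisible(list(results = results, clusters = clusters, gate = gate))
}
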