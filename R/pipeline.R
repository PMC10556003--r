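#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages. Every stochastic step derives
#' its stream from the single top-level `seed`, so a config fully determines
#' every output. Defaults: normative cohort of 1200 subjects (ages 18-100),
#' longitudinal cohort of 400 (strong-effect preset), annual binning at
#' +/- 5 months, 10/40/50 stratified split, spectral reducer with
#' n_neighbors 20 (normative space) / 16 (longitudinal space), clusters
#' C in 3..6, trajectories up to length 3, 10-fold CV repeated 10 times.
#'
#' @param seed master seed.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    generator = list(
      normative = list(n_subjects = 1200L),
      longitudinal = list(n_subjects = 400L, effect = "strong")
    ),
    data = list(normative_path = NULL, longitudinal_path = NULL),
    preprocessing = list(tolerance = 5 / 12, min_visits = 2L),
    embedding = list(
      n_neighbors = list(normative = 20L, longitudinal = 16L),
      min_dist = 0, dim = 2L, reducer = "spectral"
    ),
    clustering = list(grid = c(3L, 4L, 5L, 6L), max_iter = 100L, tol = 1e-6),
    atlas = list(max_length = 3L),
    evaluation = list(test_fraction = 0.10, space_fraction = 0.40,
                      k = 10L, repeats = 10L)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML pipeline configuration
#'
#' Keys absent from the file fall back to [defaultPipelineConfig()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  .mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

## Deterministic 32-bit FNV-1a hash of the canonicalised config, for the
## run manifest.
.configHash <- function(config) {
  s <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 2166136261
  for (b in s) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.loadOrGenerateCohorts <- function(config) {
  seed <- config$seed
  normative <- if (!is.null(config$data$normative_path)) {
    readCohort(config$data$normative_path, "cross_sectional")
  } else {
    generateNormativeCohort(normativePreset(
      nSubjects = config$generator$normative$n_subjects,
      seed = deriveSeed(seed, 1)))
  }
  longitudinal <- if (!is.null(config$data$longitudinal_path)) {
    readCohort(config$data$longitudinal_path, "longitudinal")
  } else {
    preset <- switch(config$generator$longitudinal$effect,
                     strong = strongEffectPreset, null = nullEffectPreset,
                     stop("unknown effect preset: ",
                          config$generator$longitudinal$effect))
    generateLongitudinalCohort(preset(
      nSubjects = config$generator$longitudinal$n_subjects,
      seed = deriveSeed(seed, 2)))
  }
  list(normative = normative, longitudinal = longitudinal)
}

.runExperiment <- function(config, experiment, outputDir = NULL,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  cohorts <- .loadOrGenerateCohorts(config)
  say("cohorts: %d normative scans, %d longitudinal scans (%d subjects)",
      ncol(cohorts$normative), ncol(cohorts$longitudinal),
      nSubjects(cohorts$longitudinal))

  long <- binVisitsAnnual(cohorts$longitudinal,
                          tolerance = config$preprocessing$tolerance)
  say("binning: %d -> %d scans", ncol(cohorts$longitudinal), ncol(long))
  long <- filterMinVisits(long, config$preprocessing$min_visits)
  say("min-visit filter: %d subjects retained", nSubjects(long))
  long <- normativeZscore(long, cohorts$normative)
  norm <- normativeZscore(cohorts$normative, cohorts$normative)

  split <- splitSubjects(long,
                         testFraction = config$evaluation$test_fraction,
                         spaceFraction = config$evaluation$space_fraction,
                         seed = deriveSeed(config$seed, 3))
  say("split: %d test / %d space / %d cv subjects",
      length(split$test), length(split$space), length(split$cv))

  kNbr <- config$embedding$n_neighbors
  if (is.list(kNbr) || length(kNbr) > 1) kNbr <- kNbr[[experiment]]
  rcfg <- ReductionConfig(nNeighbors = kNbr,
                          minDist = config$embedding$min_dist,
                          dim = config$embedding$dim,
                          seed = deriveSeed(config$seed, 4),
                          reducer = config$embedding$reducer)
  embedSource <- if (experiment == "normative") norm else
    long[, subjectIds(long) %in% split$space]
  model <- fitEmbedding(embedSource, config = rcfg)
  say("embedding (%s source): axis-age r = %s", experiment,
      paste(sprintf("%.3f", model@axisAgeR), collapse = " / "))

  cvTable <- crossValidate(long, model, split$cv,
                           clusterGrid = config$clustering$grid,
                           maxLength = config$atlas$max_length,
                           k = config$evaluation$k,
                           repeats = config$evaluation$repeats,
                           seed = deriveSeed(config$seed, 5))
  best <- selectBestConfig(cvTable)
  say("best CV config: C = %d, l = %d, mean AUC = %.3f",
      best$C, best$l, best$mean_auc)
  test <- finalTest(long, model, split$cv, split$test, best$C, best$l,
                    maxLength = config$atlas$max_length,
                    seed = deriveSeed(config$seed, 6))
  say("held-out test AUC = %.3f (%d scored, %d excluded)",
      test$auc, test$nScored, test$nExcluded)

  result <- list(experiment = experiment, config = config, split = split,
                 embeddingModel = model, cvTable = cvTable, best = best,
                 test = test)
  if (!is.null(outputDir)) result$files <- .writeResultsBundle(result, outputDir)
  result
}

.writeResultsBundle <- function(result, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outputDir, x)
  data.table::fwrite(result$cvTable, fp("cv_grid.csv"))
  writeAtlas(result$test$atlas, fp("atlas.csv"))
  roc <- result$test$roc
  data.table::fwrite(data.frame(threshold = roc@thresholds, tpr = roc@tpr,
                                fpr = roc@fpr), fp("roc_test.csv"))
  manifest <- list(
    experiment = result$experiment,
    package_version = as.character(utils::packageVersion("mciTrajectory")),
    seed = result$config$seed,
    config_hash = .configHash(result$config),
    config = result$config,
    split = result$split,
    best = list(C = result$best$C, l = result$best$l,
                mean_auc = result$best$mean_auc),
    test_auc = result$test$auc,
    n_test_scored = result$test$nScored,
    n_test_excluded = result$test$nExcluded
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  vapply(c("cv_grid.csv", "atlas.csv", "roc_test.csv", "manifest.json"),
         fp, "")
}

#' Run the normative-embedding experiment end to end
#'
#' Generates (or loads) the cohorts, preprocesses the longitudinal data,
#' fits the embedding on the normative cohort, projects the
#' longitudinal scans, cross-validates the trajectory classifier over the
#' (C, l) grid and evaluates the selected model on the held-out test
#' subjects. With `outputDir` set, writes `cv_grid.csv`, `atlas.csv`,
#' `roc_test.csv` and `manifest.json`.
#'
#' @param config configuration list (see [defaultPipelineConfig()]).
#' @param outputDir optional results directory.
#' @param quiet suppress stage-boundary messages.
#' @return Results list (split, embedding model, CV table, best config,
#'   final test).
#' @export
runExperimentNormative <- function(config = defaultPipelineConfig(),
                                   outputDir = NULL, quiet = FALSE) {
  .runExperiment(config, "normative", outputDir, quiet)
}

#' Run the longitudinal-embedding experiment end to end
#'
#' Identical orchestration to [runExperimentNormative()] except the
#' embedding is fitted on the 40% space split of the longitudinal cohort
#' itself; at equal seed both experiments share the exact same test, space
#' and CV subject memberships.
#'
#' @inheritParams runExperimentNormative
#' @return Results list.
#' @export
runExperimentLongitudinal <- function(config = defaultPipelineConfig(),
                                      outputDir = NULL, quiet = FALSE) {
  .runExperiment(config, "longitudinal", outputDir, quiet)
}
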