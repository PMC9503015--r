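# End-to-end orchestration: config (YAML round-trip), presets, pipeline.

#' Experiment configuration
#'
#' Bundles everything one run needs: cohort spec, preprocessing arm,
#' architecture, training and augmentation specs, number of folds, output
#' directory and the master seed from which all stage seeds derive.
#'
#' @param cohort a \code{\link{CohortSpec}}.
#' @param preprocess a \code{\link{PreprocessSpec}}.
#' @param architecture architecture name.
#' @param train a \code{\link{TrainSpec}}.
#' @param augment an \code{\link{AugmentSpec}}.
#' @param k folds.
#' @param outDir output directory.
#' @param seed master seed.
#' @return An \code{ExperimentConfig}.
#' @export
ExperimentConfig <- function(cohort, preprocess = PreprocessSpec(),
                             architecture = "cnn_a", train = deskTrainSpec(),
                             augment = AugmentSpec(), k = 3L,
                             outDir = "dbtmc-out", seed = 1L) {
  new("ExperimentConfig", cohort = cohort, preprocess = preprocess,
      architecture = architecture, train = train, augment = augment,
      k = as.integer(k), outDir = outDir, seed = as.integer(seed))
}

#' Named configuration presets
#'
#' \code{"desk"}: 128-pixel grids, ~60 cases, 10 epochs -- a single-CPU
#' scale at which the full protocol runs in minutes. \code{"paper"}:
#' 512-pixel grids, full slice counts and the full 200-epoch protocol
#' (compute-heavy; provided for completeness).
#'
#' @param name \code{"desk"} or \code{"paper"}.
#' @param seed master seed.
#' @param outDir output directory.
#' @return An \code{\link{ExperimentConfig}}.
#' @export
configPreset <- function(name = c("desk", "paper"), seed = 1L,
                         outDir = "dbtmc-out") {
  name <- match.arg(name)
  if (name == "desk") {
    ExperimentConfig(
      cohort = CohortSpec(nCases = 60L, seed = seed, gridSize = 128L,
                          clusterSpec = highContrastClusterSpec()),
      preprocess = PreprocessSpec("original", targetSize = 128L),
      train = deskTrainSpec(seed = seed), k = 3L, outDir = outDir, seed = seed)
  } else {
    ExperimentConfig(
      cohort = CohortSpec(nCases = 400L, seed = seed, gridSize = 512L,
                          sliceScale = 1),
      preprocess = PreprocessSpec("p3", targetSize = 512L),
      train = TrainSpec(seed = seed), k = 3L, outDir = outDir, seed = seed)
  }
}

specToList <- function(x) {
  slots <- methods::slotNames(class(x))
  out <- lapply(slots, function(s) {
    v <- methods::slot(x, s)
    if (isVirtualClass(class(v)) || is(v, "MCClusterSpec")) specToList(v) else v
  })
  names(out) <- slots
  out
}

#' Save / load an experiment configuration as YAML
#'
#' The YAML round-trip is faithful: \code{loadConfig(saveConfig(cfg))}
#' reproduces the configuration.
#'
#' @param config an \code{ExperimentConfig}.
#' @param path YAML file path.
#' @return \code{loadConfig} returns the restored \code{ExperimentConfig}.
#' @export
saveConfig <- function(config, path) {
  x <- list(
    cohort = specToList(config@cohort),
    preprocess = specToList(config@preprocess),
    architecture = config@architecture,
    train = specToList(config@train),
    augment = specToList(config@augment),
    k = config@k, outDir = config@outDir, seed = config@seed)
  x$cohort$clusterSpec <- specToList(config@cohort@clusterSpec)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  x <- yaml::read_yaml(path)
  cl <- x$cohort$clusterSpec
  ExperimentConfig(
    cohort = CohortSpec(nCases = x$cohort$nCases,
                        densityProportions = unlist(x$cohort$densityProportions),
                        positiveFraction = x$cohort$positiveFraction,
                        seed = x$cohort$seed, gridSize = x$cohort$gridSize,
                        sliceScale = x$cohort$sliceScale,
                        clusterSpec = MCClusterSpec(cl$nCalcifications,
                                                    unlist(cl$diametersPx),
                                                    cl$contrast, cl$spreadPx)),
    preprocess = PreprocessSpec(x$preprocess$method, x$preprocess$tvLambda,
                                x$preprocess$claheClip, x$preprocess$claheDist,
                                x$preprocess$claheAlpha,
                                unlist(x$preprocess$claheTiles),
                                x$preprocess$targetSize),
    architecture = x$architecture,
    train = TrainSpec(x$train$learningRate, x$train$batchSize,
                      x$train$maxEpochs, x$train$momentum, x$train$l2Weight,
                      x$train$seed),
    augment = AugmentSpec(x$augment$reflectLR, x$augment$rotationRangeDeg,
                          x$augment$seed),
    k = x$k, outDir = x$outDir, seed = x$seed)
}

#' Run the full pipeline
#'
#' Simulate the cohort, write it to disk (8-bit TIFFs + manifest), run the
#' cross-validated experiment for the configured arm and architecture
#' (preprocessed TIFFs and per-fold checkpoints are written), and store
#' per-fold score tables, the fold-averaged ROC, a one-row results
#' summary and a reproducibility record (config, seeds, package version).
#' Deterministic for a fixed configuration.
#'
#' @param config an \code{\link{ExperimentConfig}}.
#' @param verbose print stage progress.
#' @return Invisibly, the \code{\link{runExperiment}} result.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  outDir <- config@outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    if (verbose) message("[", name, "] ...")
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    if (verbose)
      message(sprintf("[%s] done in %.1fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  cohort <- stage("simulate", generateCohort(config@cohort))
  stage("write-cohort", writeCohort(cohort, file.path(outDir, "cohort")))
  res <- stage("experiment", runExperiment(
    cohort, config@preprocess, config@architecture, config@k,
    config@train, config@augment,
    inputSize = min(config@preprocess@targetSize, config@cohort@gridSize),
    seed = config@seed, outDir = file.path(outDir, "processed"),
    verbose = verbose))
  stage("report", {
    for (f in seq_along(res$evals)) {
      ev <- res$evals[[f]]
      utils::write.csv(data.frame(score = ev@scores, label = ev@labels),
                       file.path(outDir, sprintf("fold%d_scores.csv", f)),
                       row.names = FALSE)
    }
    utils::write.csv(res$rocAvg, file.path(outDir, "roc_average.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$byDensity, file.path(outDir, "auc_by_density.csv"),
                     row.names = FALSE)
    saveConfig(methods::new("ExperimentConfig", cohort = config@cohort,
                            preprocess = config@preprocess,
                            architecture = config@architecture,
                            train = config@train, augment = config@augment,
                            k = config@k, outDir = config@outDir,
                            seed = config@seed),
               file.path(outDir, "config.yml"))
    writeLines(c(sprintf("package: DBTmc %s",
                         as.character(utils::packageVersion("DBTmc"))),
                 sprintf("master_seed: %d", config@seed),
                 sprintf("fold_seeds: %s",
                         paste(vapply(seq_len(config@k), function(f)
                           deriveSeed(config@seed, "train", f), integer(1)),
                           collapse = " "))),
               file.path(outDir, "reproducibility.txt"))
  })
  invisible(res)
}
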