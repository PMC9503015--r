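# Central S4 classes. Slices are stored as plain numeric matrices in the
# unit intensity range [0,1] (row = image y, column = image x) with the
# chest wall at column 1; binary masks are 0/1 matrices on the same grid.

DENSITY_LEVELS <- c("fatty", "scattered", "heterogeneous", "dense")

# Per-density geometry and texture parameters. Slice counts are the
# full-scale per-volume counts; spectralExponent steers the power-law
# anatomical texture and glandularFraction the mean glandular intensity,
# both increasing from fatty to dense.
DENSITY_TABLE <- data.frame(
  density           = DENSITY_LEVELS,
  nSlices           = c(62L, 57L, 47L, 38L),
  prevalence        = c(0.10, 0.40, 0.40, 0.10),
  spectralExponent  = c(2.0, 2.4, 2.8, 3.2),
  glandularFraction = c(0.15, 0.35, 0.55, 0.75),
  # semi-axis of the compressed breast outline as a fraction of the grid
  outlineFraction   = c(0.46, 0.40, 0.34, 0.28),
  stringsAsFactors  = FALSE
)

#' Breast-density classes and their parameters
#'
#' Returns the four breast-density classes used throughout the package with
#' their full-scale slice counts, population prevalence and the texture
#' parameters of the synthetic generator.
#'
#' @return A data.frame with one row per density class.
#' @export
#' @examples
#' densityClasses()
densityClasses <- function() DENSITY_TABLE

checkDensity <- function(density) {
  if (!is.character(density) || length(density) != 1L ||
      !(density %in% DENSITY_LEVELS))
    stop("'density' must be one of: ", paste(DENSITY_LEVELS, collapse = ", "))
  density
}

#' @rdname MCClusterSpec
#' @export
setClass("MCClusterSpec", representation(
  nCalcifications = "integer",
  diametersPx     = "integer",
  contrast        = "numeric",
  spreadPx        = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@nCalcifications < 1L) msg <- c(msg, "nCalcifications must be >= 1")
  if (object@contrast < 0) msg <- c(msg, "contrast must be >= 0")
  if (object@spreadPx <= 0) msg <- c(msg, "spreadPx must be > 0")
  if (any(object@diametersPx < 1L)) msg <- c(msg, "diametersPx must be >= 1 px")
  if (length(msg)) msg else TRUE
})

#' Specification of a microcalcification cluster
#'
#' A cluster is a group of small bright calcified lesions added to a slice:
#' by default five calcifications per cluster, with diameters of a few
#' pixels emulating the 195/179/171 um lesions of the emulated cohort at
#' the working pixel scale, an additive contrast above the local anatomical
#' background, and a cluster radius \code{spreadPx} within which all lesion
#' centers fall.
#'
#' @param nCalcifications number of calcified lesions per cluster.
#' @param diametersPx lesion diameters in pixels, recycled over lesions.
#' @param contrast additive intensity of a lesion above local background.
#' @param spreadPx cluster radius in pixels.
#' @return An object of class \code{MCClusterSpec}.
#' @export
#' @examples
#' MCClusterSpec(contrast = 0.4)
MCClusterSpec <- function(nCalcifications = 5L, diametersPx = c(3L, 2L, 2L),
                          contrast = 0.25, spreadPx = 6) {
  new("MCClusterSpec", nCalcifications = as.integer(nCalcifications),
      diametersPx = as.integer(diametersPx), contrast = as.numeric(contrast),
      spreadPx = as.numeric(spreadPx))
}

#' High-contrast desk-scale cluster preset
#'
#' The cluster setting used by the package's scaled-down end-to-end
#' checks: additive contrast 0.7 (the generator default is 0.25) and
#' lesion diameters of 4-5 px, at least the stride of the first
#' convolution so no lesion can fall between samples. At the 128-px desk
#' grid one pixel spans roughly four full-scale pixels; this preset
#' represents maximally conspicuous clusters, the easy end of the task,
#' while the generator default remains the nontrivial condition.
#'
#' @param contrast additive lesion contrast.
#' @return An \code{\link{MCClusterSpec}}.
#' @export
highContrastClusterSpec <- function(contrast = 0.7) {
  MCClusterSpec(contrast = contrast, diametersPx = c(5L, 4L, 4L))
}

#' @rdname CohortSpec
#' @export
setClass("CohortSpec", representation(
  nCases             = "integer",
  densityProportions = "numeric",
  positiveFraction   = "numeric",
  seed               = "integer",
  gridSize           = "integer",
  sliceScale         = "numeric",
  clusterSpec        = "MCClusterSpec"
), validity = function(object) {
  msg <- character()
  if (object@nCases < 4L) msg <- c(msg, "nCases must be >= 4 to honor all four densities")
  if (length(object@densityProportions) != 4L)
    msg <- c(msg, "densityProportions must have 4 entries")
  if (abs(sum(object@densityProportions) - 1) > 1e-9)
    msg <- c(msg, "densityProportions must sum to 1")
  if (any(object@densityProportions < 0))
    msg <- c(msg, "densityProportions must be nonnegative")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    msg <- c(msg, "positiveFraction must be in [0, 1]")
  if (object@gridSize < 32L) msg <- c(msg, "gridSize must be >= 32")
  if (object@sliceScale <= 0 || object@sliceScale > 1)
    msg <- c(msg, "sliceScale must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic cohort
#'
#' Describes a cohort of virtual patients: the number of cases, the density
#' mix (default 10/40/40/10 percent for fatty/scattered/heterogeneous/dense,
#' the usual population distribution), the fraction of positive
#' (cluster-bearing) cases, the in-plane grid size and the factor by which
#' full-scale per-density slice counts (62/57/47/38) are scaled down.
#'
#' @param nCases number of cases (virtual patients).
#' @param densityProportions four nonnegative fractions summing to 1.
#' @param positiveFraction fraction of cases carrying clusters.
#' @param seed master seed; all cohort randomness derives from it.
#' @param gridSize in-plane grid side in pixels (desk default 128, full 512).
#' @param sliceScale factor applied to the full-scale slice counts; the
#'   scaled count is never allowed below 5 (slice selection needs 5).
#'   Default \code{gridSize/512} so depth shrinks with the grid.
#' @param clusterSpec an \code{\link{MCClusterSpec}}.
#' @return An object of class \code{CohortSpec}.
#' @export
#' @examples
#' CohortSpec(nCases = 20, seed = 1)
CohortSpec <- function(nCases, densityProportions = c(0.10, 0.40, 0.40, 0.10),
                       positiveFraction = 0.5, seed = 1L,
                       gridSize = 128L, sliceScale = gridSize / 512,
                       clusterSpec = MCClusterSpec()) {
  new("CohortSpec", nCases = as.integer(nCases),
      densityProportions = as.numeric(densityProportions),
      positiveFraction = as.numeric(positiveFraction),
      seed = as.integer(seed), gridSize = as.integer(gridSize),
      sliceScale = as.numeric(sliceScale), clusterSpec = clusterSpec)
}

#' @rdname DBTCase
#' @export
setClass("DBTCase", representation(
  patientId   = "character",
  density     = "character",
  label       = "character",
  slices      = "list",
  clusters    = "data.frame",
  breastMask  = "matrix",
  pixelSizeMM = "numeric"
), validity = function(object) {
  msg <- character()
  if (!(object@density %in% DENSITY_LEVELS)) msg <- c(msg, "unknown density")
  if (!(object@label %in% c("absent", "presentMCs"))) msg <- c(msg, "unknown label")
  if (object@label == "absent" && nrow(object@clusters) != 0L)
    msg <- c(msg, "absent cases must have no clusters")
  if (object@label == "presentMCs" && nrow(object@clusters) != 4L)
    msg <- c(msg, "presentMCs cases must record exactly 4 cluster centers")
  if (length(object@slices)) {
    d <- dim(object@slices[[1L]])
    if (!all(vapply(object@slices, function(s) identical(dim(s), d), logical(1L))))
      msg <- c(msg, "all slices must share one grid shape")
  }
  if (length(msg)) msg else TRUE
})

#' A synthetic DBT case (virtual patient volume)
#'
#' Holds the ordered slice stack of one reconstructed volume together with
#' its density class, class label, ground-truth cluster centers (slice,
#' row, col; empty for absent cases) and the true breast mask used during
#' generation.
#'
#' @name DBTCase-class
#' @aliases DBTCase
NULL

#' @rdname DBTCohort
#' @export
setClass("DBTCohort", representation(
  cases = "list",
  spec  = "CohortSpec"
))

#' A cohort of synthetic DBT cases
#'
#' A list of \code{\linkS4class{DBTCase}} objects plus the
#' \code{\link{CohortSpec}} that generated them.
#'
#' @name DBTCohort-class
#' @aliases DBTCohort
NULL

PREPROCESS_ARMS <- c("original", "p1", "p2", "p3", "p4", "p5", "p6")

#' @rdname PreprocessSpec
#' @export
setClass("PreprocessSpec", representation(
  method     = "character",
  tvLambda   = "numeric",
  claheClip  = "numeric",
  claheDist  = "character",
  claheAlpha = "numeric",
  claheTiles = "integer",
  targetSize = "integer"
), validity = function(object) {
  msg <- character()
  if (!(object@method %in% PREPROCESS_ARMS))
    msg <- c(msg, paste("method must be one of:", paste(PREPROCESS_ARMS, collapse = ", ")))
  if (object@tvLambda <= 0) msg <- c(msg, "tvLambda must be > 0")
  if (object@claheClip <= 0 || object@claheClip > 1)
    msg <- c(msg, "claheClip must be in (0, 1]")
  if (!(object@claheDist %in% c("uniform", "rayleigh", "exponential")))
    msg <- c(msg, "claheDist must be uniform, rayleigh or exponential")
  if (length(object@claheTiles) != 2L || any(object@claheTiles < 1L))
    msg <- c(msg, "claheTiles must be two positive integers")
  if (object@targetSize < 8L) msg <- c(msg, "targetSize too small")
  if (length(msg)) msg else TRUE
})

#' Preprocessing arm specification
#'
#' Selects one of the seven input arms (\code{original} and \code{p1}
#' through \code{p6}) and carries the parameters of the underlying
#' operations: the ROF fidelity weight (\code{tvLambda}, default 14), the
#' CLAHE clip limit (0.01), histogram distribution (uniform) and
#' distribution parameter (0.4, inert under the uniform distribution but
#' stored for fidelity), the CLAHE tile grid (8 x 8) and the common resize
#' target (512).
#'
#' @param method one of \code{"original"}, \code{"p1"} ... \code{"p6"}.
#' @param tvLambda positive fidelity weight of the ROF objective.
#' @param claheClip normalized CLAHE contrast-enhancement limit in (0, 1].
#' @param claheDist target histogram shape for CLAHE.
#' @param claheAlpha distribution parameter (used by the non-uniform shapes).
#' @param claheTiles tile grid (rows, cols).
#' @param targetSize common in-plane resize target in pixels.
#' @return A \code{PreprocessSpec} object.
#' @export
#' @examples
#' PreprocessSpec("p3")
PreprocessSpec <- function(method = "original", tvLambda = 14,
                           claheClip = 0.01, claheDist = "uniform",
                           claheAlpha = 0.4, claheTiles = c(8L, 8L),
                           targetSize = 512L) {
  new("PreprocessSpec", method = method, tvLambda = as.numeric(tvLambda),
      claheClip = as.numeric(claheClip), claheDist = claheDist,
      claheAlpha = as.numeric(claheAlpha), claheTiles = as.integer(claheTiles),
      targetSize = as.integer(targetSize))
}

#' @rdname FoldAssignment
#' @export
setClass("FoldAssignment", representation(
  k       = "integer",
  mapping = "integer"   # named: patientId -> fold in 1..k
), validity = function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@mapping))) msg <- c(msg, "mapping must be named by patient id")
  if (anyDuplicated(names(object@mapping))) msg <- c(msg, "every patient must appear exactly once")
  if (length(object@mapping) &&
      (min(object@mapping) < 1L || max(object@mapping) > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Patient-level fold assignment
#'
#' Maps each patient id to one of \code{k} cross-validation folds. The
#' split is at the patient level: all slices of a patient share its fold.
#'
#' @name FoldAssignment-class
#' @aliases FoldAssignment
NULL

#' @rdname AugmentSpec
#' @export
setClass("AugmentSpec", representation(
  reflectLR        = "logical",
  rotationRangeDeg = "numeric",
  seed             = "integer"
), validity = function(object) {
  if (object@rotationRangeDeg < 0) "rotationRangeDeg must be >= 0" else TRUE
})

#' Training-time augmentation specification
#'
#' Random left-right reflection (probability 0.5, emulating right breasts)
#' followed by rotation by a uniform draw in +/- \code{rotationRangeDeg}
#' degrees (default 20), bilinear interpolation, background fill 0.
#' Augmentation is applied to training data only, never at evaluation.
#'
#' @param reflectLR enable random left-right reflection.
#' @param rotationRangeDeg symmetric rotation bound in degrees.
#' @param seed base seed for augmentation draws.
#' @return An \code{AugmentSpec} object.
#' @export
AugmentSpec <- function(reflectLR = TRUE, rotationRangeDeg = 20, seed = 1L) {
  new("AugmentSpec", reflectLR = reflectLR,
      rotationRangeDeg = as.numeric(rotationRangeDeg), seed = as.integer(seed))
}

#' @rdname TrainSpec
#' @export
setClass("TrainSpec", representation(
  learningRate = "numeric",
  batchSize    = "integer",
  maxEpochs    = "integer",
  momentum     = "numeric",
  l2Weight     = "numeric",
  seed         = "integer"
), validity = function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@momentum < 0 || object@momentum >= 1) msg <- c(msg, "momentum must be in [0, 1)")
  if (object@l2Weight < 0) msg <- c(msg, "l2Weight must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Training protocol specification
#'
#' Stochastic gradient descent with momentum 0.9, learning rate 1e-3,
#' mini-batch size 32, at most 200 epochs and an L2 penalty of 5e-3 on the
#' weights added to the cross-entropy loss -- the full-scale protocol.
#' Desk-scale presets (see \code{\link{deskTrainSpec}}) shrink the epoch
#' budget.
#'
#' @param learningRate SGD learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum number of epochs.
#' @param momentum SGD momentum coefficient.
#' @param l2Weight weight of the L2 penalty term added to the loss.
#' @param seed training seed (shuffling, dropout, augmentation draws).
#' @return A \code{TrainSpec} object.
#' @export
TrainSpec <- function(learningRate = 1e-3, batchSize = 32L, maxEpochs = 200L,
                      momentum = 0.9, l2Weight = 5e-3, seed = 1L) {
  new("TrainSpec", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      momentum = as.numeric(momentum), l2Weight = as.numeric(l2Weight),
      seed = as.integer(seed))
}

#' Desk-scale training preset
#'
#' A reduced protocol for single-CPU experimentation on 128-pixel grids:
#' the optimizer, momentum and L2 penalty are unchanged, but the epoch
#' budget is capped at 10, the mini-batch is shrunk to 8 (doubling the
#' update count on tiny cohorts) and the learning rate is raised to 2e-2:
#' with only a few dozen updates available, the full-scale rate of 1e-3
#' cannot move the loss off its plateau.
#'
#' @param maxEpochs epoch cap (default 10).
#' @param seed training seed.
#' @return A \code{\link{TrainSpec}}.
#' @export
deskTrainSpec <- function(maxEpochs = 10L, seed = 1L) {
  TrainSpec(learningRate = 2e-2, batchSize = 8L, maxEpochs = maxEpochs,
            momentum = 0.9, l2Weight = 5e-3, seed = seed)
}

#' @rdname EvalResult
#' @export
setClass("EvalResult", representation(
  scores      = "numeric",
  labels      = "character",
  roc         = "data.frame",
  auc         = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  accuracy    = "numeric",
  threshold   = "numeric"
), validity = function(object) {
  msg <- character()
  if (length(object@scores) != length(object@labels))
    msg <- c(msg, "scores and labels must have equal length")
  if (length(object@auc) == 1L && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must lie in [0, 1]")
  if (nrow(object@roc)) {
    if (any(diff(object@roc$fpr) < -1e-12) || any(diff(object@roc$tpr) < -1e-12))
      msg <- c(msg, "roc must be monotone nondecreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Evaluation result for one scored test set
#'
#' Per-slice positive-class scores and labels, the ROC polygon from (0,0)
#' to (1,1), the trapezoidal AUC, and sensitivity/specificity/accuracy at
#' the stated threshold (positive class: \code{presentMCs}).
#'
#' @name EvalResult-class
#' @aliases EvalResult
NULL

#' @rdname CNNModel
#' @export
setClass("CNNModel", representation(
  arch      = "character",
  inputSize = "integer",
  nClasses  = "integer",
  nodes     = "list",
  weights   = "list",
  state     = "environment"
))

#' A convolutional network on the built-in engine
#'
#' A directed acyclic layer graph (\code{nodes}) plus its parameter tensors
#' (\code{weights}) and mutable engine state (layer caches, batch-norm
#' running statistics). Build with \code{\link{buildCNNa}} or
#' \code{\link{buildReference}}; inspect with \code{\link{layerTable}}.
#'
#' @name CNNModel-class
#' @aliases CNNModel
NULL

#' @rdname ExperimentConfig
#' @export
setClass("ExperimentConfig", representation(
  cohort       = "CohortSpec",
  preprocess   = "PreprocessSpec",
  architecture = "character",
  train        = "TrainSpec",
  augment      = "AugmentSpec",
  k            = "integer",
  outDir       = "character",
  seed         = "integer"
))

showHeader <- function(cls, ...) cat(sprintf("%s object\n", cls), ...)

setMethod("show", "DBTCase", function(object) {
  cat(sprintf("DBTCase %s | %s | %s | %d slices of %dx%d | %d clusters\n",
              object@patientId, object@density, object@label,
              length(object@slices), nrow(object@slices[[1L]]),
              ncol(object@slices[[1L]]), nrow(object@clusters)))
})

setMethod("show", "DBTCohort", function(object) {
  lab <- vapply(object@cases, function(x) x@label, character(1L))
  den <- vapply(object@cases, function(x) x@density, character(1L))
  cat(sprintf("DBTCohort: %d cases (%d presentMCs / %d absent), grid %dx%d\n",
              length(object@cases), sum(lab == "presentMCs"),
              sum(lab == "absent"), object@spec@gridSize, object@spec@gridSize))
  print(table(factor(den, levels = DENSITY_LEVELS)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: n = %d, AUC = %.4f | sens %.3f spec %.3f acc %.3f @ thr %.2f\n",
    length(object@scores), object@auc, object@sensitivity,
    object@specificity, object@accuracy, object@threshold))
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel '%s': input %dx%dx1, %d classes, %d layers, %s parameters\n",
              object@arch, object@inputSize, object@inputSize, object@nClasses,
              length(object@nodes), format(parameterCount(object), big.mark = ",")))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d patients in %d folds (%s)\n",
              length(object@mapping), object@k,
              paste(tabulate(object@mapping, object@k), collapse = "/")))
})
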