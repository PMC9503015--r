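# Training protocol and the evaluation stack: ROC/AUC, threshold metrics,
# fold averaging, t-test comparison, density-stratified testing.

POSITIVE_CLASS <- "presentMCs"

labelIndex <- function(labels) ifelse(labels == POSITIVE_CLASS, 2L, 1L)

# recursive in-place update over the nested weight structure; w and v must
# be training-local copies (see trainClassifier), g may omit entries
updateWeights <- function(w, g, v, lr, mom, l2, isW = FALSE) {
  if (is.list(w)) {
    for (nm in names(w))
      updateWeights(w[[nm]], g[[nm]], v[[nm]], lr, mom, l2,
                    isW = identical(nm, "W"))
    return(invisible(NULL))
  }
  if (is.null(g)) return(invisible(NULL))
  sgdStepCpp(w, v, g, lr, mom, if (isW) l2 else 0)
  invisible(NULL)
}

# deep copy so in-place updates never touch the caller's object
deepCopy <- function(w) {
  if (is.list(w)) return(lapply(w, deepCopy))
  w + 0
}

zeroLike <- function(w) {
  if (is.list(w)) return(lapply(w, zeroLike))
  w * 0
}

l2Norm2 <- function(w) {
  if (is.list(w)) {
    tot <- 0
    for (nm in names(w)) if (identical(nm, "W") || is.list(w[[nm]]))
      tot <- tot + l2Norm2(w[[nm]])
    return(tot)
  }
  sumSquaresCpp(w)
}

asInputColumn <- function(img) {
  as.vector(zeroCenter(img))
}

#' Train a classifier with SGD + momentum
#'
#' Minimizes cross-entropy plus an L2 penalty (\code{l2Weight * ||W||^2},
#' applied to weight matrices, not biases or normalization parameters)
#' with stochastic gradient descent (momentum 0.9 by default). Data order
#' is reshuffled every epoch under the training seed; each training image
#' is optionally augmented (reflection/rotation) and zero-centered before
#' entering the network. Deterministic given the seed.
#'
#' @param model a \code{CNNModel}.
#' @param images list of slice matrices (unit-range or 8-bit integer) with
#'   dimension matching the model input.
#' @param labels character vector, \code{"absent"} / \code{"presentMCs"}.
#' @param spec a \code{\link{TrainSpec}}.
#' @param augment an \code{\link{AugmentSpec}} or NULL to disable.
#' @param verbose print per-epoch loss.
#' @return list with \code{model} (trained) and \code{lossHistory}
#'   (numeric, one mean total loss per epoch).
#' @export
trainClassifier <- function(model, images, labels, spec = deskTrainSpec(),
                            augment = NULL, verbose = FALSE) {
  n <- length(images)
  stopifnot(n == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  y <- labelIndex(labels)
  model@weights <- deepCopy(model@weights)   # updates happen in place
  vel <- zeroLike(model@weights)
  lossHistory <- numeric(0)
  counter <- 0L
  withSeed(spec@seed, {
    for (epoch in seq_len(spec@maxEpochs)) {
      perm <- sample.int(n)
      ceLosses <- numeric(0)
      for (start in seq(1L, n, by = spec@batchSize)) {
        idx <- perm[start:min(start + spec@batchSize - 1L, n)]
        cols <- lapply(idx, function(i) {
          img <- images[[i]]
          if (is.integer(img)) img <- img / 255
          if (!is.null(augment)) {
            counter <<- counter + 1L
            img <- augmentSlice(img, augment,
                                drawSeed = deriveSeed(spec@seed, "augment", counter))
          }
          asInputColumn(img)
        })
        Xb <- do.call(cbind, cols)
        fwd <- forwardModel(model, Xb, training = TRUE)
        ce <- softmaxCE(fwd$logits, y[idx])
        grads <- backwardModel(model, fwd, ce$dLogits)
        updateWeights(model@weights, grads, vel,
                      spec@learningRate, spec@momentum, spec@l2Weight)
        ceLosses <- c(ceLosses, ce$loss)
      }
      # total loss: mean cross-entropy plus the penalty at epoch end
      lossHistory <- c(lossHistory,
                       mean(ceLosses) + spec@l2Weight * l2Norm2(model@weights))
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f", epoch, spec@maxEpochs,
                        lossHistory[epoch]))
    }
  })
  list(model = model, lossHistory = lossHistory)
}

#' Score slices with a trained model
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' dropout, no augmentation); returns the softmax probability of the
#' positive class (\code{presentMCs}).
#'
#' @param model a trained \code{CNNModel}.
#' @param images list of slice matrices.
#' @param batchSize evaluation batch size.
#' @return Numeric vector of positive-class probabilities.
#' @export
predictScores <- function(model, images, batchSize = 16L) {
  n <- length(images)
  out <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    Xb <- do.call(cbind, lapply(images[idx], function(img) {
      if (is.integer(img)) img <- img / 255
      asInputColumn(img)
    }))
    fwd <- forwardModel(model, Xb, training = FALSE)
    out[idx] <- softmaxProbs(fwd$logits)[2L, ]
  }
  out
}

#' ROC curve of a score set
#'
#' Thresholds at every distinct score; returns the ROC polygon from (0,0)
#' to (1,1), monotone nondecreasing in both coordinates (ties grouped).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels character labels (\code{"presentMCs"} positive).
#' @return data.frame with columns \code{fpr}, \code{tpr}.
#' @export
rocCurve <- function(scores, labels) {
  pos <- labels == POSITIVE_CLASS
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("ROC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(diff(s) != 0, TRUE)   # group tied scores
  data.frame(fpr = c(0, fp[last] / nN), tpr = c(0, tp[last] / nP))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under \code{\link{rocCurve}}; equals the probability
#' that a random positive outscores a random negative, ties counted one
#' half.
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1].
#' @export
#' @examples
#' aucScore(c(0.9, 0.8, 0.7, 0.85), c("presentMCs", "presentMCs", "absent", "absent"))
aucScore <- function(scores, labels) {
  roc <- rocCurve(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Scores at or above the threshold are called positive.
#'
#' @inheritParams rocCurve
#' @param threshold decision threshold on the positive-class score.
#' @return Named numeric vector (sensitivity, specificity, accuracy).
#' @export
metricsAtThreshold <- function(scores, labels, threshold = 0.5) {
  pos <- labels == POSITIVE_CLASS
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(scores))
}

#' Bundle scores into an evaluation result
#'
#' @inheritParams metricsAtThreshold
#' @return An \code{\linkS4class{EvalResult}}.
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  roc <- rocCurve(scores, labels)
  m <- metricsAtThreshold(scores, labels, threshold)
  new("EvalResult", scores = scores, labels = labels, roc = roc,
      auc = aucScore(scores, labels), sensitivity = m[["sensitivity"]],
      specificity = m[["specificity"]], accuracy = m[["accuracy"]],
      threshold = threshold)
}

#' Vertically average ROC curves
#'
#' Interpolates every curve's TPR on a common FPR grid (101 points by
#' default) and averages pointwise -- the fold-averaged ROC.
#'
#' @param curves list of ROC data.frames (fpr, tpr).
#' @param nGrid number of FPR grid points.
#' @return data.frame with columns fpr, tpr.
#' @export
averageROC <- function(curves, nGrid = 101L) {
  stopifnot(length(curves) >= 1L)
  grid <- seq(0, 1, length.out = nGrid)
  tprs <- vapply(curves, function(cv)
    stats::approx(cv$fpr, cv$tpr, xout = grid, rule = 2,
                  ties = list("ordered", max))$y,
    numeric(nGrid))
  data.frame(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Compare per-fold AUCs with a two-sample t-test
#'
#' Unpaired two-tailed t-test with pooled variance on the per-fold AUC
#' values of two models. When both groups are constant with equal means
#' the difference is exactly zero and p = 1 by convention.
#'
#' @param aucA,aucB numeric vectors of per-fold AUCs (length >= 2).
#' @return Two-tailed p-value.
#' @export
compareAUCTTest <- function(aucA, aucB) {
  stopifnot(length(aucA) >= 2L, length(aucB) >= 2L)
  if (stats::var(aucA) + stats::var(aucB) == 0) {
    return(if (isTRUE(all.equal(mean(aucA), mean(aucB)))) 1 else 0)
  }
  stats::t.test(aucA, aucB, var.equal = TRUE)$p.value
}

#' Density-stratified evaluation
#'
#' AUC of the same scored test set restricted to each breast-density
#' class (the model is trained on all densities mixed; only testing is
#' stratified). Subsets holding a single class have no defined AUC and
#' are reported as NA.
#'
#' @inheritParams rocCurve
#' @param densities character vector of per-slice density classes.
#' @return data.frame with columns density, n, auc.
#' @export
densityStratifiedEval <- function(scores, labels, densities) {
  out <- lapply(DENSITY_LEVELS, function(d) {
    sel <- densities == d
    auc <- if (sum(sel) && length(unique(labels[sel])) == 2L)
      aucScore(scores[sel], labels[sel]) else NA_real_
    data.frame(density = d, n = sum(sel), auc = auc)
  })
  do.call(rbind, out)
}

preprocessCohortSlices <- function(cohort, arm, inputSize, st = NULL,
                                   outDir = NULL) {
  if (is.null(st)) st <- sliceTable(cohort)
  images <- vector("list", nrow(st))
  maskCache <- list()
  for (r in seq_len(nrow(st))) {
    cs <- cohort@cases[[st$case_index[r]]]
    raw <- cs@slices[[st$slice_index[r]]]
    pid <- cs@patientId
    pp <- applyPreprocessing(raw, arm, mask = maskCache[[pid]])
    if (is.null(maskCache[[pid]])) maskCache[[pid]] <- pp$mask
    img <- resizeSlice(pp$image, inputSize)
    img8 <- to8bit(img)
    if (!is.null(outDir)) {
      fn <- file.path(outDir, sprintf("%s_s%03d_%s.tif", pid,
                                      st$slice_index[r], arm@method))
      tiff::writeTIFF(img8 / 255, fn, bits.per.sample = 8L)
    }
    images[[r]] <- img8
  }
  images
}

#' Run one cross-validated experiment
#'
#' The full protocol for one (preprocessing arm, architecture) cell:
#' preprocess the selected slices of every case, split patients into
#' \code{k} stratified folds, train on each training fold (augmented),
#' score the held-out fold, and report per-fold evaluation results plus
#' the mean and sample standard deviation of the fold AUCs.
#'
#' @param cohort a \code{DBTCohort}.
#' @param arm a \code{\link{PreprocessSpec}}.
#' @param architecture architecture name (see \code{\link{buildReference}}).
#' @param k number of folds (default 3).
#' @param trainSpec a \code{\link{TrainSpec}}.
#' @param augment an \code{\link{AugmentSpec}} or NULL.
#' @param inputSize network input side (defaults to the cohort grid).
#' @param seed master experiment seed (folds, initialization, training).
#' @param threshold decision threshold for the threshold metrics.
#' @param permuteLabels permute case labels at the patient level and run
#'   the whole experiment (training and evaluation) under the permuted
#'   assignment -- the permutation-null control. Permuted labels carry no
#'   association with image content, so test AUC sits at chance.
#' @param outDir optional directory for preprocessed TIFFs and checkpoints.
#' @param verbose print progress.
#' @return list with \code{evals} (per-fold \code{EvalResult}),
#'   \code{aucs}, \code{aucMean}, \code{aucSD}, \code{rocAvg} (fold-averaged
#'   ROC), \code{byDensity} (pooled density-stratified table),
#'   \code{folds} (the \code{FoldAssignment}) and \code{summary} (one-row
#'   data.frame mirroring a results-table cell, "mean +/- sd").
#' @export
runExperiment <- function(cohort, arm = PreprocessSpec(), architecture = "cnn_a",
                          k = 3L, trainSpec = deskTrainSpec(),
                          augment = AugmentSpec(), inputSize = NULL,
                          seed = 1L, threshold = 0.5, permuteLabels = FALSE,
                          outDir = NULL, verbose = FALSE) {
  if (is.null(inputSize)) inputSize <- cohort@spec@gridSize
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- sliceTable(cohort)
  images <- preprocessCohortSlices(cohort, arm, inputSize, st, outDir)
  pids <- patientId(cohort)
  dens <- caseDensity(cohort)
  labs <- caseLabel(cohort)
  caseLab <- stats::setNames(labs, pids)
  if (permuteLabels) {
    caseLab[] <- withSeed(deriveSeed(seed, "permute"),
                          sample(unname(caseLab)))
  }
  sliceLab <- unname(caseLab[st$patient_id])
  folds <- assignFolds(pids, k, deriveSeed(seed, "folds"), dens, labs)
  fmap <- foldMap(folds)
  evals <- list()
  scoresAll <- numeric(0); labelsAll <- character(0); densAll <- character(0)
  for (f in seq_len(k)) {
    testPat <- names(fmap)[fmap == f]
    trainSel <- !(st$patient_id %in% testPat)
    spec <- trainSpec
    spec@seed <- deriveSeed(seed, "train", f)
    model <- buildReference(architecture, inputSize, 2L,
                            seed = deriveSeed(seed, "init", f))
    if (verbose) message(sprintf("fold %d: %d train / %d test slices",
                                 f, sum(trainSel), sum(!trainSel)))
    fit <- trainClassifier(model, images[trainSel], sliceLab[trainSel],
                           spec, augment, verbose = verbose)
    if (!is.null(outDir))
      saveModel(fit$model, file.path(outDir, sprintf("fold%d_checkpoint.rds", f)))
    sc <- predictScores(fit$model, images[!trainSel])
    testLabs <- sliceLab[!trainSel]   # permuted run: the null labels apply
    evals[[f]] <- evaluateScores(sc, testLabs, threshold)
    scoresAll <- c(scoresAll, sc)
    labelsAll <- c(labelsAll, testLabs)
    densAll <- c(densAll, st$density[!trainSel])
  }
  aucs <- vapply(evals, aucValue, numeric(1))
  list(evals = evals, aucs = aucs, aucMean = mean(aucs),
       aucSD = stats::sd(aucs),
       rocAvg = averageROC(lapply(evals, function(e) e@roc)),
       byDensity = densityStratifiedEval(scoresAll, labelsAll, densAll),
       folds = folds,
       summary = data.frame(arm = arm@method, architecture = architecture,
                            k = k, aucMean = mean(aucs), aucSD = stats::sd(aucs),
                            cell = sprintf("%.2f +/- %.2f", 100 * mean(aucs),
                                           100 * stats::sd(aucs)),
                            stringsAsFactors = FALSE))
}

#' Sweep preprocessing arms
#'
#' Runs \code{\link{runExperiment}} for each requested arm and stacks the
#' one-row summaries into a results table (rows = arms).
#'
#' @inheritParams runExperiment
#' @param arms character vector of arm names.
#' @return data.frame with one row per arm.
#' @export
armSweep <- function(cohort, arms = PREPROCESS_ARMS, architecture = "cnn_a",
                     k = 3L, trainSpec = deskTrainSpec(),
                     augment = AugmentSpec(), seed = 1L, verbose = FALSE) {
  rows <- lapply(arms, function(a) {
    res <- runExperiment(cohort, PreprocessSpec(a), architecture, k,
                         trainSpec, augment, seed = seed, verbose = verbose)
    res$summary
  })
  do.call(rbind, rows)
}

#' Pairwise t-tests between models' fold AUCs
#'
#' @param aucList named list of per-fold AUC vectors.
#' @return Symmetric matrix of two-tailed p-values (diagonal NA).
#' @export
pairwiseAUCTests <- function(aucList) {
  n <- length(aucList)
  out <- matrix(NA_real_, n, n, dimnames = list(names(aucList), names(aucList)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- compareAUCTTest(aucList[[i]], aucList[[j]])
  out
}
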