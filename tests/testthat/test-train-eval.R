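# Evaluation stack oracles and the training loop.

test_that("AUC reproduces hand-worked and degenerate examples", {
  labs4 <- c("presentMCs", "presentMCs", "absent", "absent")
  # pos {0.9, 0.8}, neg {0.7, 0.85}: 3 of 4 pairs concordant
  expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.85), labs4), 0.75)
  expect_equal(aucScore(c(0.9, 0.8, 0.1, 0.2), labs4), 1)
  expect_equal(aucScore(rep(0.5, 4), labs4), 0.5)   # all ties
  expect_error(aucScore(1:3 / 3, rep("absent", 3)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random score sets", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    labs <- c("presentMCs", "absent",
              sample(c("absent", "presentMCs"), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))   # provoke ties
    expect_lt(abs(aucScore(scores, labs) - bruteForceAUC(scores, labs)), 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  labs <- sample(c("absent", "presentMCs"), 30, replace = TRUE)
  labs[1:2] <- c("absent", "presentMCs")
  s <- runif(30)
  expect_equal(aucScore(s, labs), aucScore(exp(3 * s) - 1, labs))
  expect_equal(aucScore(s, labs), aucScore(rank(s), labs))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  labs <- c("absent", "presentMCs",
            sample(c("absent", "presentMCs"), 48, replace = TRUE))
  s <- round(runif(50), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labs, predictor = s, levels = c("absent", "presentMCs"),
    direction = "<", quiet = TRUE)))
  expect_equal(aucScore(s, labs), ref, tolerance = 1e-12)
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(10)
  labs <- c("absent", "presentMCs",
            sample(c("absent", "presentMCs"), 18, replace = TRUE))
  roc <- rocCurve(runif(20), labs)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("threshold metrics count confusion cells by definition", {
  # 2 TP, 1 FN, 3 TN, 1 FP
  scores <- c(0.9, 0.8, 0.2, 0.1, 0.3, 0.4, 0.7)
  labels <- c("presentMCs", "presentMCs", "presentMCs",
              "absent", "absent", "absent", "absent")
  m <- metricsAtThreshold(scores, labels, 0.5)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 3 / 4)
  expect_equal(unname(m["accuracy"]), 5 / 7)
  all_pos <- metricsAtThreshold(scores, labels, 0)
  expect_equal(unname(all_pos["sensitivity"]), 1)
  expect_equal(unname(all_pos["specificity"]), 0)
  perfect <- metricsAtThreshold(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1), labels, 0.5)
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("vertical ROC averaging matches hand-computed cases", {
  perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  chance <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  one <- averageROC(list(chance))
  expect_equal(one$tpr, one$fpr)                    # single curve = itself
  two <- averageROC(list(chance, chance))
  expect_equal(two$tpr, two$fpr)
  avg <- averageROC(list(perfect, chance))
  expect_equal(avg$tpr[avg$fpr == 0.5], 0.75)       # (1.0 + 0.5) / 2
})

test_that("the AUC t-test matches the closed form and its conventions", {
  a <- c(0.90, 0.91, 0.92)
  b <- c(0.80, 0.81, 0.82)
  expect_lt(abs(compareAUCTTest(a, b) - pooledTTestP(a, b)), 1e-9)
  expect_lt(compareAUCTTest(a, b), 0.05)
  expect_equal(compareAUCTTest(a, b), compareAUCTTest(b, a))  # symmetric
  expect_equal(compareAUCTTest(c(0.9, 0.9), c(0.9, 0.9)), 1)  # identical groups
  set.seed(3)
  x <- 0.8 + runif(3) / 100
  y <- 0.8 + runif(3) / 100
  expect_lt(abs(compareAUCTTest(x, y) - pooledTTestP(x, y)), 1e-9)
})

test_that("density-stratified AUC brackets the pooled AUC when balanced", {
  set.seed(12)
  dens <- rep(densityClasses()$density, each = 20)
  labs <- rep(rep(c("absent", "presentMCs"), each = 10), 4)
  scores <- ifelse(labs == "presentMCs", runif(80, 0.4, 1), runif(80, 0, 0.6))
  tab <- densityStratifiedEval(scores, labs, dens)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$auc)))
  pooled <- aucScore(scores, labs)
  expect_gte(pooled, min(tab$auc) - 1e-9)
  expect_lte(pooled, max(tab$auc) + 1e-9)
  # a single-class subset yields NA
  tab2 <- densityStratifiedEval(scores[1:30], labs[1:30],
                                rep(c("fatty", "scattered"), c(10, 20)))
  expect_true(is.na(tab2$auc[tab2$density == "fatty"]))
})

test_that("training learns a separable toy problem and applies the L2 penalty", {
  set.seed(21)
  nodes <- list(
    nd("input", "input", character()),
    nd("c1", "conv", "input", kernel = 3L, stride = 2L, pad = 1L,
       outChannels = 4L, groups = 1L),
    nd("r1", "relu", "c1"),
    nd("g", "gap", "r1"),
    nd("fc", "fc", "g", outFeatures = 2L))
  mkimg <- function(cls) {
    x <- matrix(runif(256, 0, 0.2), 16)
    if (cls == 2) x[6:10, 6:10] <- x[6:10, 6:10] + 0.7  # localized bright patch
    x
  }
  images <- lapply(rep(1:2, each = 12), mkimg)
  labels <- rep(c("absent", "presentMCs"), each = 12)
  m <- DBTmc:::buildModel("toy", nodes, 16L, 2L, seed = 2)
  spec <- TrainSpec(learningRate = 0.05, batchSize = 8L, maxEpochs = 30L,
                    momentum = 0.9, l2Weight = 0, seed = 5)
  fit <- trainClassifier(m, images, labels, spec, augment = NULL)
  expect_lte(length(fit$lossHistory), 30)
  sc <- predictScores(fit$model, images)
  acc <- mean((sc >= 0.5) == (labels == "presentMCs"))
  expect_equal(acc, 1)                               # fully separable
  expect_lt(tail(fit$lossHistory, 1), fit$lossHistory[1])

  # identical protocol with L2 penalty shrinks the weight norm
  spec2 <- spec; spec2@l2Weight <- 0.05
  fit2 <- trainClassifier(DBTmc:::buildModel("toy", nodes, 16L, 2L, seed = 2),
                          images, labels, spec2, augment = NULL)
  expect_lt(DBTmc:::l2Norm2(fit2$model@weights), DBTmc:::l2Norm2(fit$model@weights))
  expect_error(trainClassifier(m, images, rep("absent", 24), spec),
               "both classes")
})

test_that("training is deterministic given the seed", {
  set.seed(77)
  images <- lapply(1:10, function(i) matrix(runif(256), 16))
  labels <- rep(c("absent", "presentMCs"), 5)
  nodes <- list(
    nd("input", "input", character()),
    nd("c1", "conv", "input", kernel = 3L, stride = 2L, pad = 1L,
       outChannels = 2L, groups = 1L),
    nd("r1", "relu", "c1"),
    nd("g", "gap", "r1"),
    nd("fc", "fc", "g", outFeatures = 2L))
  run <- function() {
    m <- DBTmc:::buildModel("toy", nodes, 16L, 2L, seed = 3)
    trainClassifier(m, images, labels,
                    TrainSpec(maxEpochs = 3L, batchSize = 4L, seed = 11),
                    augment = AugmentSpec(seed = 1L))$model@weights
  }
  expect_identical(run(), run())
})

test_that("pairwise AUC test tables are symmetric with NA diagonal", {
  aucs <- list(a = c(0.9, 0.91, 0.92), b = c(0.8, 0.81, 0.82),
               c = c(0.85, 0.86, 0.87))
  p <- pairwiseAUCTests(aucs)
  expect_true(all(is.na(diag(p))))
  expect_equal(p["a", "b"], p["b", "a"])
  expect_lt(p["a", "b"], 0.05)
})
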