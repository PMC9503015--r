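# Architecture construction, layer audits and engine correctness.

test_that("CNN-a differs from stock AlexNet exactly as designed", {
  ma <- buildCNNa(128, seed = 1)
  ref <- buildReference("alexnet", 128, seed = 1)
  ta <- layerTable(ma)
  tr <- layerTable(ref)
  # one extra max-pool
  expect_equal(sum(ta$kind == "maxpool"), sum(tr$kind == "maxpool") + 1L)
  # no LRN left, batch norm instead (at least the two replaced layers)
  expect_equal(sum(ta$kind == "lrn"), 0L)
  expect_gte(sum(ta$kind == "bn"), 2L)
  expect_equal(sum(tr$kind == "lrn"), 2L)
  expect_equal(sum(tr$kind == "bn"), 0L)
  # the inserted pool sits between the grouped convolutions conv4 and conv5
  expect_equal(ta$inputs[ta$name == "pool_new"], "relu4")
  expect_equal(ta$inputs[ta$name == "conv5"], "pool_new")
  expect_equal(ta$groups[ta$name %in% c("conv2", "conv4", "conv5")],
               c(2L, 2L, 2L))
  # it halves (floor) the map between the grouped convolutions
  h4 <- ta$outH[ta$name == "conv4"]
  expect_equal(ta$outH[ta$name == "pool_new"], floor((h4 - 3) / 2) + 1)
})

test_that("model builds are deterministic and input-shape audited", {
  m1 <- buildCNNa(128, seed = 7)
  m2 <- buildCNNa(128, seed = 7)
  expect_identical(m1@weights, m2@weights)
  expect_equal(parameterCount(m1), parameterCount(m2))
  m3 <- buildCNNa(128, seed = 8)
  expect_false(identical(m1@weights, m3@weights))
  # spatial audit at full scale: every intermediate map keeps positive extent
  t512 <- layerTable(buildCNNa(512, seed = 1))
  expect_true(all(t512$outH[!is.na(t512$outH)] >= 1))
  # too-small inputs fail with the offending layer named
  expect_error(buildCNNa(64), "pool")
})

test_that("reference architectures build, score batches and stay seeded", {
  set.seed(33)
  X <- matrix(rnorm(128 * 128 * 3, 0, 0.1), 128 * 128, 3)
  for (a in c("alexnet", "googlenet", "resnet18", "squeezenet")) {
    m <- buildReference(a, 128, seed = 2)
    f <- forwardModel(m, X, training = FALSE)
    expect_equal(dim(f$logits), c(2L, 3L), info = a)
    expect_true(all(is.finite(f$logits)), info = a)
    m2 <- buildReference(a, 128, seed = 2)
    expect_identical(m@weights, m2@weights, info = a)
  }
  expect_error(buildReference("vgg16", 128), "unknown architecture")
})

test_that("evaluation-mode forward passes are deterministic", {
  m <- buildCNNa(128, seed = 3)
  set.seed(1); X <- matrix(rnorm(128 * 128 * 2, 0, 0.1), 128 * 128, 2)
  f1 <- forwardModel(m, X, training = FALSE)
  f2 <- forwardModel(m, X, training = FALSE)
  expect_identical(f1$logits, f2$logits)
})

test_that("backpropagation matches numerical gradients on a mixed DAG", {
  nodes <- list(
    nd("input", "input", character()),
    nd("c1", "conv", "input", kernel = 3L, stride = 1L, pad = 1L,
       outChannels = 4L, groups = 1L),
    nd("b1", "bn", "c1"),
    nd("r1", "relu", "b1"),
    nd("c2", "conv", "r1", kernel = 3L, stride = 1L, pad = 1L,
       outChannels = 4L, groups = 2L),
    nd("n2", "lrn", "c2", nwin = 5L, alpha = 1e-4, beta = 0.75, k = 2),
    nd("a1", "add", c("n2", "r1")),
    nd("p1", "maxpool", "a1", kernel = 3L, stride = 2L, pad = 1L),
    nd("c3", "conv", "p1", kernel = 1L, stride = 1L, pad = 0L,
       outChannels = 2L, groups = 1L),
    nd("cc", "concat", c("p1", "c3")),
    nd("g", "gap", "cc"),
    nd("fc", "fc", "g", outFeatures = 2L))
  m <- DBTmc:::buildModel("toy", nodes, 8L, 2L, seed = 3)
  set.seed(4)
  X <- matrix(rnorm(64 * 3), 64, 3)
  y <- c(1L, 2L, 1L)
  lossOf <- function(mm) {
    f <- forwardModel(mm, X, training = TRUE)
    DBTmc:::softmaxCE(f$logits, y)$loss
  }
  f <- forwardModel(m, X, training = TRUE)
  ce <- DBTmc:::softmaxCE(f$logits, y)
  gr <- backwardModel(m, f, ce$dLogits)
  eps <- 1e-5
  checkOne <- function(node, pname, gidx = NULL) {
    target <- if (is.null(gidx)) m@weights[[node]][[pname]]
      else m@weights[[node]][[pname]][[gidx]]
    ganl <- if (is.null(gidx)) gr[[node]][[pname]] else gr[[node]][[pname]][[gidx]]
    for (i in sample(length(target), min(4, length(target)))) {
      mp <- m
      wm <- mp@weights
      if (is.null(gidx)) wm[[node]][[pname]][i] <- wm[[node]][[pname]][i] + eps
      else wm[[node]][[pname]][[gidx]][i] <- wm[[node]][[pname]][[gidx]][i] + eps
      mp@weights <- wm
      lp <- lossOf(mp)
      if (is.null(gidx)) wm[[node]][[pname]][i] <- wm[[node]][[pname]][i] - 2 * eps
      else wm[[node]][[pname]][[gidx]][i] <- wm[[node]][[pname]][[gidx]][i] - 2 * eps
      mp@weights <- wm
      lm <- lossOf(mp)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - ganl[i]) / max(1e-6, abs(num) + abs(ganl[i])), 1e-4,
                label = paste("grad", node, pname, i))
    }
  }
  checkOne("c1", "W", 1)
  checkOne("c2", "W", 1); checkOne("c2", "W", 2)
  checkOne("b1", "gamma"); checkOne("b1", "beta")
  checkOne("c3", "W", 1)
  checkOne("fc", "W"); checkOne("fc", "b")
})

test_that("layer tables serialize and checkpoints round-trip", {
  m <- buildCNNa(128, seed = 4)
  dir <- withr::local_tempdir()
  p <- writeLayerTable(m, file.path(dir, "layers.csv"))
  tab <- read.csv(p)
  expect_equal(nrow(tab), length(m@nodes))
  saveModel(m, file.path(dir, "ckpt.rds"))
  m2 <- loadModel(file.path(dir, "ckpt.rds"))
  expect_identical(m@weights, m2@weights)
  set.seed(5); X <- matrix(rnorm(128 * 128, 0, 0.1), 128 * 128, 1)
  expect_identical(forwardModel(m, X)$logits, forwardModel(m2, X)$logits)
})
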