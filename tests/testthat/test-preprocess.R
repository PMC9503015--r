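# Background suppression chain, TV denoising, CLAHE, square normalization,
# arm composition, resizing and 8-bit conversion.

test_that("binarization separates bright foreground and flags constants", {
  img <- matrix(0, 32, 32)
  img[10:20, 12:22] <- 0.8
  m <- binarizeSlice(img)
  expect_equal(m, (img > 0) * 1, ignore_attr = TRUE)

  flat <- matrix(0.3, 16, 16)
  mf <- binarizeSlice(flat)
  expect_true(all(mf == 0))
  expect_true(attr(mf, "degenerate"))

  cb <- matrix(c(0.2, 0.7), 8, 8)                   # checkerboard-ish columns
  mfix <- binarizeSlice(cb, threshold = 0.5)
  expect_equal(mfix, (cb >= 0.5) * 1, ignore_attr = TRUE)
})

test_that("hole filling obeys the border rule and is idempotent", {
  ring <- matrix(0, 15, 15)
  ring[5:11, 5:11] <- 1
  ring[7:9, 7:9] <- 0                               # interior hole
  f <- fillHoles(ring)
  expect_true(all(f[5:11, 5:11] == 1))
  open <- matrix(0, 15, 15)
  open[1:5, 5:11] <- 1
  open[1:2, 7:9] <- 0                               # notch touching border
  fo <- fillHoles(open)
  expect_equal(sum(fo), sum(open))                  # border hole survives
  expect_equal(fillHoles(f), f)                     # fixed point
})

test_that("largest component keeps the biggest blob, ties by scan order", {
  m <- matrix(0, 20, 20)
  m[2:8, 2:8] <- 1                                  # area 49
  m[15:17, 15:17] <- 1                              # area 9
  big <- largestComponent(m)
  expect_equal(sum(big), 49)
  expect_true(all(big[15:17, 15:17] == 0))

  single <- largestComponent((m > 0 & row(m) < 10) * 1)
  expect_equal(single, (m > 0 & row(m) < 10) * 1, ignore_attr = TRUE)

  # equal areas: scan order is column-major, the left blob is seen first
  tie <- matrix(0, 20, 20)
  tie[5:7, 2:4] <- 1
  tie[5:7, 10:12] <- 1
  kept <- largestComponent(tie)
  expect_equal(sum(kept), 9)
  expect_true(all(kept[5:7, 2:4] == 1))
  expect_equal(sum(largestComponent(matrix(0, 5, 5))), 0)
})

test_that("region growing is monotone and improves mask recovery", {
  m <- generateBreastMask(96, "scattered", 8)
  img <- generateBackground(m, "scattered", 8)
  b <- largestComponent(fillHoles(binarizeSlice(img)))
  grown <- regionGrow(b, img)
  expect_true(all(grown[b > 0] == 1))               # monotone growth
  expect_identical(regionGrow(b, img, admitFraction = Inf), b)
  expect_gte(jaccardIndex(grown, m), jaccardIndex(b, m))
})

test_that("background suppression zeroes outside and preserves inside", {
  m <- generateBreastMask(96, "heterogeneous", 4)
  img <- generateBackground(m, "heterogeneous", 4)
  sb <- suppressBackground(img)
  expect_true(all(sb$image[sb$mask == 0] == 0))
  expect_equal(sb$image[sb$mask > 0], img[sb$mask > 0])
  # idempotent on already clean input
  again <- suppressBackground(sb$image)
  expect_equal(again$image[again$mask > 0], sb$image[again$mask > 0])
  # degenerate flag propagates
  expect_true(suppressBackground(matrix(0.5, 32, 32))$degenerate)
})

test_that("TV denoising matches an independent primal-dual solver", {
  set.seed(101)
  for (lambda in c(5, 14, 30)) {
    f <- matrix(runif(32 * 32), 32)
    mine <- tvDenoise(f, lambda, tol = 1e-8, maxIter = 8000L)
    ref <- rofPrimalDual(f, lambda, iter = 8000L)
    expect_lt(max(abs(mine - ref)) / max(abs(ref)), 1e-3)
  }
})

test_that("TV denoising contracts total variation and handles edge cases", {
  const <- matrix(0.7, 24, 24)
  expect_equal(tvDenoise(const), const)             # TV already zero
  f <- matrix(0.2, 33, 33)
  f[17, 17] <- 0.9
  g <- tvDenoise(f, 14)
  expect_lt(g[17, 17], 0.9)                         # impulse shrinks
  expect_gt(g[17, 17], 0.2)
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(runif(28 * 28), 28)
    expect_lte(totalVariation(tvDenoise(x, 14)), totalVariation(x))
  }
  expect_error(tvDenoise(f, -1), "positive")
})

test_that("CLAHE keeps constants constant, stays in range, adds contrast", {
  const <- matrix(0.5, 64, 64)
  out <- claheSlice(const)
  expect_lt(diff(range(out)), 1e-6)
  set.seed(3)
  x <- matrix(runif(96 * 96), 96)
  y <- claheSlice(x)
  expect_gte(min(y), 0); expect_lte(max(y), 1)
  # spatially mixed uniform-histogram image is approximately unchanged
  set.seed(9)
  u <- matrix(sample(seq_len(64 * 64) - 0.5) / (64 * 64), 64)
  expect_lt(mean(abs(claheSlice(u, clip = 1) - u)), 0.05)
  # low-contrast ramp gains spread
  r <- matrix(rep(seq(0.4, 0.6, length.out = 128), each = 128), 128)
  expect_gt(sd(claheSlice(r)), sd(r))
  expect_error(claheSlice(x, tiles = c(200L, 200L)), "tile")
  expect_error(claheSlice(x, dist = "rayleigh"), "uniform")
})

test_that("square normalization maps endpoints and preserves order", {
  x <- matrix(c(0.1, 0.3, 0.5, 0.9), 2)
  y <- squareNormalize(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_equal(squareNormalize(matrix(c(0, 0.5, 1, 0.2), 2))[2, 1], 0.25)
  expect_equal(order(as.vector(x)), order(as.vector(y)))   # monotone
  flat <- squareNormalize(matrix(1, 4, 4))
  expect_true(all(flat == 0))
  expect_true(attr(flat, "degenerate"))
})

test_that("every arm composes with background suppression correctly", {
  m <- generateBreastMask(96, "scattered", 21)
  img <- generateBackground(m, "scattered", 21)
  base <- suppressBackground(img)
  for (arm in c("original", "p1", "p2", "p3", "p4", "p5", "p6")) {
    pp <- applyPreprocessing(img, PreprocessSpec(arm))
    expect_gte(min(pp$image), 0)
    expect_lte(max(pp$image), 1)
    expect_true(all(pp$image[pp$mask == 0] == 0),
                info = paste("arm", arm, "leaks background"))
    expect_identical(pp$mask, base$mask)            # mask from original image
  }
  # original arm on a clean-background slice is the identity
  clean <- base$image
  ppc <- applyPreprocessing(clean, PreprocessSpec("original"), mask = base$mask)
  expect_equal(ppc$image, clean)
  # order of TV and CLAHE matters
  p3 <- applyPreprocessing(img, PreprocessSpec("p3"), mask = base$mask)
  p4 <- applyPreprocessing(img, PreprocessSpec("p4"), mask = base$mask)
  expect_gt(max(abs(p3$image - p4$image)), 1e-6)
  expect_error(PreprocessSpec("p9"), "method")
})

test_that("contrast arms do not dim calcifications relative to background", {
  cohort <- .testCohort(nCases = 8L, seed = 42L, gridSize = 64L)
  cs <- Filter(function(x) caseLabel(x) == "presentMCs", cohortCases(cohort))[[1]]
  cl <- caseClusters(cs)[1, ]
  sl <- caseSlices(cs)[[cl$slice]]
  msk <- trueBreastMask(cs)
  cbr <- function(x) {
    rr <- pmax(1, round(cl$row - 6)):pmin(nrow(x), round(cl$row + 6))
    cc <- pmax(1, round(cl$col - 6)):pmin(ncol(x), round(cl$col + 6))
    max(x[rr, cc]) / mean(x[msk > 0])
  }
  for (arm in c("p5", "p6")) {
    pp <- applyPreprocessing(sl, PreprocessSpec(arm), mask = (msk > 0) * 1)
    expect_gte(cbr(pp$image), cbr(sl) - 1e-9)
  }
})

test_that("resizing honors identity, constants and mask binarity", {
  x <- matrix(runif(64 * 64), 64)
  expect_identical(resizeSlice(x, 64), x)
  cst <- resizeSlice(matrix(0.42, 40, 40), 64)
  expect_lt(diff(range(cst)), 1e-6)
  m <- (matrix(runif(40 * 40), 40) > 0.6) * 1
  mr <- resizeSlice(m, 64, isMask = TRUE)
  expect_true(all(mr %in% c(0, 1)))
  expect_equal(dim(resizeSlice(x, 48)), c(48L, 48L))
})

test_that("8-bit conversion and zero-centering meet their contracts", {
  x <- matrix(seq(0, 1, length.out = 64), 8)
  x8 <- to8bit(x)
  expect_equal(max(x8), 255L)
  expect_equal(min(x8), 0L)
  expect_lte(max(abs(x8 / 255 - x)), 1 / 255 / 2 + 1e-12)
  z <- zeroCenter(x8)
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(attr(z, "offset"), mean(x8 / 255))
})
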