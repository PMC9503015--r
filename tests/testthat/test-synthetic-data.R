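# Synthetic cohort generator: determinism, geometry, texture and labels.

test_that("breast masks are deterministic, connected and plausibly sized", {
  m1 <- generateBreastMask(128, "fatty", 7)
  m2 <- generateBreastMask(128, "fatty", 7)
  expect_identical(m1, m2)

  for (d in densityClasses()$density) {
    m <- generateBreastMask(128, d, 3)
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(m > 0)))
    expect_equal(max(lab), 1)                       # one component
    filled <- as.matrix(EBImage::fillHull(EBImage::Image(m > 0)))
    expect_equal(sum(filled > 0), sum(m > 0))       # no holes
    expect_gt(mean(m), 0.2)
    expect_lt(mean(m), 0.9)
    expect_gt(sum(m[, 1]), 0)                       # touches chest wall
  }
  expect_error(generateBreastMask(16, "fatty", 1), "too small")
})

test_that("anatomical background is seeded, contaminated and density-ordered", {
  m <- generateBreastMask(96, "scattered", 5)
  b1 <- generateBackground(m, "scattered", 9)
  b2 <- generateBackground(m, "scattered", 9)
  expect_identical(b1, b2)
  expect_gte(min(b1), 0)
  expect_lte(max(b1), 1)
  expect_gt(mean(b1[m == 0]), 0)                    # contaminated background

  bf <- generateBackground(m, "fatty", 9)
  bd <- generateBackground(m, "dense", 9)
  expect_gt(var(bd[m > 0]), var(bf[m > 0]))         # denser = more texture
  expect_gt(mean(bd[m > 0]), mean(bf[m > 0]))       # denser = brighter
})

test_that("cluster insertion adds the requested lesions inside the mask", {
  m <- generateBreastMask(96, "fatty", 2)
  bg <- generateBackground(m, "fatty", 2)
  spec <- MCClusterSpec(contrast = 0.4, spreadPx = 5)
  ctr <- c(48, 30)
  ins <- insertMCCluster(bg, m, spec, ctr, 11)
  expect_equal(nrow(ins$lesions), 5)
  d <- sqrt((ins$lesions$row - ctr[1])^2 + (ins$lesions$col - ctr[2])^2)
  expect_true(all(d <= spec@spreadPx + 1e-9))
  expect_true(all(m[cbind(round(ins$lesions$row), round(ins$lesions$col))] > 0))
  expect_gt(sum(ins$image - bg), 0)

  zero <- insertMCCluster(bg, m, MCClusterSpec(contrast = 0), ctr, 11)
  expect_equal(zero$image, bg)                      # zero contrast = identity
  expect_error(insertMCCluster(bg, m, spec, c(2, 95), 1), "placement")
})

test_that("generated cases respect label contracts and slice counts", {
  pos <- generateCase("P1", "fatty", "presentMCs", gridSize = 64, seed = 3,
                      sliceScale = 1)
  expect_equal(length(caseSlices(pos)), 62)         # full-scale fatty depth
  expect_equal(nrow(caseClusters(pos)), 4)
  neg <- generateCase("P2", "dense", "absent", gridSize = 64, seed = 3,
                      sliceScale = 1)
  expect_equal(length(caseSlices(neg)), 38)
  expect_equal(nrow(caseClusters(neg)), 0)
  # cluster centers are inside the true mask
  msk <- trueBreastMask(pos)
  cl <- caseClusters(pos)
  expect_true(all(msk[cbind(round(cl$row), round(cl$col))] > 0))
})

test_that("positive slices are visibly brighter near recorded cluster centers", {
  cohort <- .testCohort(nCases = 8L, seed = 42L, gridSize = 64L)
  spec <- cohort@spec@clusterSpec
  for (cs in cohortCases(cohort)) {
    if (caseLabel(cs) != "presentMCs") next
    msk <- trueBreastMask(cs)
    for (q in seq_len(nrow(caseClusters(cs)))) {
      cl <- caseClusters(cs)[q, ]
      sl <- caseSlices(cs)[[cl$slice]]
      bgMean <- mean(sl[msk > 0])
      rr <- pmax(1, round(cl$row - spec@spreadPx)):pmin(nrow(sl), round(cl$row + spec@spreadPx))
      cc <- pmax(1, round(cl$col - spec@spreadPx)):pmin(ncol(sl), round(cl$col + spec@spreadPx))
      expect_gte(max(sl[rr, cc]) - bgMean, spec@contrast / 2)
    }
  }
})

test_that("cohorts honor largest-remainder density counts and label balance", {
  counts <- DBTmc:::largestRemainder(20, c(0.10, 0.40, 0.40, 0.10))
  expect_equal(counts, c(2L, 8L, 8L, 2L))
  expect_equal(DBTmc:::largestRemainder(7, c(0.10, 0.40, 0.40, 0.10)),
               c(1L, 3L, 3L, 0L))                   # remainder ties: first wins
  cohort <- .testCohort(nCases = 8L, seed = 42L, gridSize = 64L)
  dens <- caseDensity(cohort)
  expect_equal(as.integer(table(factor(dens, levels = densityClasses()$density))),
               DBTmc:::largestRemainder(8, c(0.10, 0.40, 0.40, 0.10)))
  labs <- caseLabel(cohort)
  expect_lte(abs(sum(labs == "presentMCs") - 0.5 * 8), 1)
  expect_error(generateCohort(CohortSpec(nCases = 3)), "nCases")
})

test_that("cohort generation is bit-identical for a fixed spec", {
  spec <- CohortSpec(nCases = 5, seed = 77, gridSize = 64)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(lapply(cohortCases(c1), caseSlices),
                   lapply(cohortCases(c2), caseSlices))
  expect_identical(lapply(cohortCases(c1), caseClusters),
                   lapply(cohortCases(c2), caseClusters))
})

test_that("cohorts round-trip through TIFF + manifest", {
  cohort <- .testCohort(nCases = 8L, seed = 42L, gridSize = 64L)
  dir <- withr::local_tempdir()
  man <- writeCohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), sum(vapply(cohortCases(cohort),
                                     function(cs) length(caseSlices(cs)), 1L)))
  back <- readManifest(dir)
  expect_equal(back$patient_id, man$patient_id)
  img <- readSliceTIFF(man$file[1])
  orig <- caseSlices(cohortCases(cohort)[[1]])[[1]]
  expect_equal(dim(img), dim(orig))
  expect_lte(max(abs(img - orig)), 1 / 255)         # 8-bit quantization bound
})
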