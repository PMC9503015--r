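# Synthetic VICTRE-like cohort generator.
#
# Slices emulate reconstructed craniocaudal DBT data: a compressed-breast
# outline touching the chest-wall edge (column 1), power-law anatomical
# texture whose spectral exponent and glandular level grow with breast
# density, low-amplitude signal contamination outside the breast, and
# additive calcification clusters with known ground truth. Volumes are
# generated slice by slice; the strongly anisotropic reconstruction depth
# is represented by slice independence (training is slice-by-slice).

densityRow <- function(density) {
  DENSITY_TABLE[DENSITY_TABLE$density == checkDensity(density), , drop = FALSE]
}

# Largest-remainder rounding of n * prop so the counts sum to n exactly.
largestRemainder <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a compressed-breast binary mask
#'
#' Builds a roughly semi-elliptical, seeded-random breast outline touching
#' the chest-wall edge of the grid (column 1). The outline is star-shaped
#' around the chest wall center, so the foreground is always a single
#' connected, hole-free component. Denser classes produce smaller
#' compressed outlines, mirroring the per-density grid extents of the
#' emulated archive.
#'
#' @param gridSize side of the square grid in pixels (>= 32).
#' @param density one of \code{"fatty"}, \code{"scattered"},
#'   \code{"heterogeneous"}, \code{"dense"}.
#' @param seed integer seed; the mask is deterministic given it.
#' @return A 0/1 matrix of dimension \code{gridSize x gridSize}.
#' @export
#' @examples
#' m <- generateBreastMask(64, "fatty", 7)
#' mean(m)
generateBreastMask <- function(gridSize, density, seed) {
  gridSize <- as.integer(gridSize)
  if (gridSize < 32L)
    stop("gridSize too small to contain a breast of the requested density (need >= 32)")
  row <- densityRow(density)
  aFrac <- c(fatty = 0.85, scattered = 0.78, heterogeneous = 0.70, dense = 0.62)[[density]]
  a <- aFrac * gridSize
  b <- row$outlineFraction * gridSize
  withSeed(seed, {
    amp <- runif(3L, 0.2, 1)
    phi <- runif(3L, 0, 2 * pi)
    cy <- (gridSize + 1) / 2 + runif(1L, -0.03, 0.03) * gridSize
    x <- matrix(rep(0:(gridSize - 1L), each = gridSize), gridSize)  # col - 1
    y <- matrix(rep(seq_len(gridSize), gridSize), gridSize) - cy
    theta <- atan2(y, x)
    s <- 1 + 0.06 * (amp[1] * cos(theta + phi[1]) +
                     amp[2] * cos(2 * theta + phi[2]) +
                     amp[3] * cos(3 * theta + phi[3]))
    mask <- ((x / (a * s))^2 + (y / (b * s))^2) <= 1
    storage.mode(mask) <- "double"
    mask
  })
}

# Power-law ("1/f^beta") random field with unit variance and zero mean.
powerLawField <- function(n, beta) {
  w <- matrix(stats::rnorm(n * n), n, n)
  fr <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) / n
  f <- sqrt(outer(fr^2, fr^2, "+"))
  amp <- (f + 1 / n)^(-beta / 2)
  amp[1, 1] <- 0
  t <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
  t <- t - mean(t)
  t / stats::sd(t)
}

#' Generate the anatomical background of one slice
#'
#' Fills the breast mask with power-law anatomical texture (spectral
#' exponent and glandular level increase from fatty to dense), tapers
#' intensity smoothly toward the breast edge, and adds low-amplitude
#' contamination outside the mask emulating the nonzero background signal
#' of reconstructed data.
#'
#' @param mask 0/1 breast mask from \code{\link{generateBreastMask}}.
#' @param density density class name.
#' @param seed integer seed.
#' @return A matrix in [0, 1]; pixels outside the mask are small but
#'   strictly positive.
#' @export
generateBackground <- function(mask, density, seed) {
  row <- densityRow(density)
  n <- nrow(mask)
  stopifnot(ncol(mask) == n)
  level <- 0.25 + 0.40 * row$glandularFraction
  sigma <- 0.030 + 0.070 * row$glandularFraction
  d <- as.matrix(EBImage::distmap(mask))
  ramp <- 0.2 + 0.8 * pmin(1, d / 5)
  withSeed(seed, {
    texture <- powerLawField(n, row$spectralExponent)
    inside <- ramp * (level + sigma * texture)
    phase <- runif(1L, 0, 2 * pi)
    colIdx <- matrix(rep(seq_len(n), each = n), n)
    contamination <- 0.012 + 0.008 * abs(stats::rnorm(n * n)) +
      0.004 * (1 + sin(2 * pi * colIdx / 24 + phase)) / 2
    dim(contamination) <- c(n, n)
    out <- ifelse(mask > 0, inside, contamination)
    clip01(out)
  })
}

# Antialiased additive disk of diameter d centered at (r0, c0), max height 1.
softDisk <- function(n, r0, c0, d) {
  rad <- d / 2
  rr <- floor(r0 - rad - 1):ceiling(r0 + rad + 1)
  cc <- floor(c0 - rad - 1):ceiling(c0 + rad + 1)
  rr <- rr[rr >= 1 & rr <= n]
  cc <- cc[cc >= 1 & cc <= n]
  out <- matrix(0, n, n)
  dist <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  out[rr, cc] <- pmin(1, pmax(0, rad + 0.5 - dist))
  out
}

#' Insert a microcalcification cluster into a slice
#'
#' Adds \code{nCalcifications} bright antialiased disks around
#' \code{center}; every lesion center is drawn uniformly within
#' \code{spreadPx} of the cluster center and constrained to the breast
#' mask. Intensities are additive and the result is clipped to [0, 1].
#'
#' @param image slice matrix in [0, 1].
#' @param mask 0/1 breast mask.
#' @param spec an \code{\link{MCClusterSpec}}.
#' @param center numeric (row, col) cluster center; must be inside the mask.
#' @param seed integer seed for lesion placement.
#' @return A list with elements \code{image} (modified slice) and
#'   \code{lesions} (data.frame of lesion centers: row, col, diameter).
#' @export
insertMCCluster <- function(image, mask, spec, center, seed) {
  r0 <- center[1]; c0 <- center[2]
  if (r0 < 1 || c0 < 1 || r0 > nrow(image) || c0 > ncol(image) ||
      mask[round(r0), round(c0)] <= 0)
    stop("cluster center must lie inside the breast mask (placement error)")
  n <- nrow(image)
  diam <- rep(spec@diametersPx, length.out = spec@nCalcifications)
  withSeed(seed, {
    les <- matrix(NA_real_, spec@nCalcifications, 2L)
    for (i in seq_len(spec@nCalcifications)) {
      for (try in 1:200) {
        rho <- spec@spreadPx * sqrt(runif(1L))
        ang <- runif(1L, 0, 2 * pi)
        rr <- r0 + rho * sin(ang); cc <- c0 + rho * cos(ang)
        if (rr >= 1 && cc >= 1 && rr <= n && cc <= n &&
            mask[round(rr), round(cc)] > 0) break
        if (try == 200) { rr <- r0; cc <- c0 }
      }
      les[i, ] <- c(rr, cc)
    }
    out <- image
    for (i in seq_len(spec@nCalcifications))
      out <- out + spec@contrast * softDisk(n, les[i, 1], les[i, 2], diam[i])
    list(image = clip01(out),
         lesions = data.frame(row = les[, 1], col = les[, 2], diameter = diam))
  })
}

#' Generate one synthetic DBT case
#'
#' Builds a full slice stack for one virtual patient: a per-case breast
#' mask, per-slice anatomical backgrounds, and -- for \code{presentMCs}
#' cases -- exactly four calcification clusters whose (slice, row, col)
#' centers are recorded as ground truth. Cluster centers are kept at least
#' \code{spreadPx + 2} pixels inside the breast boundary.
#'
#' @param patientId unique id string.
#' @param density density class name.
#' @param label \code{"absent"} or \code{"presentMCs"}.
#' @param clusterSpec an \code{\link{MCClusterSpec}}.
#' @param gridSize in-plane grid side in pixels.
#' @param seed integer seed; the case is deterministic given it.
#' @param sliceScale factor on the full-scale slice counts (62/57/47/38);
#'   the scaled count is floored at 5.
#' @return A \code{\linkS4class{DBTCase}}.
#' @export
generateCase <- function(patientId, density, label, clusterSpec = MCClusterSpec(),
                         gridSize = 128L, seed = 1L, sliceScale = gridSize / 512) {
  checkDensity(density)
  if (!(label %in% c("absent", "presentMCs"))) stop("unknown label: ", label)
  row <- densityRow(density)
  nSlices <- max(5L, as.integer(round(row$nSlices * sliceScale)))
  mask <- generateBreastMask(gridSize, density, deriveSeed(seed, "mask"))
  slices <- lapply(seq_len(nSlices), function(i)
    generateBackground(mask, density, deriveSeed(seed, "background", i)))
  clusters <- data.frame(slice = integer(), row = numeric(), col = numeric())
  if (label == "presentMCs") {
    d <- as.matrix(EBImage::distmap(mask))
    cand <- which(d >= clusterSpec@spreadPx + 2, arr.ind = TRUE)
    if (nrow(cand) < 4L)
      stop("breast region too small to host 4 clusters at this grid size")
    withSeed(deriveSeed(seed, "clusters"), {
      sliceIdx <- sort(sample(2:(nSlices - 1L), 4L, replace = TRUE))
      # draw well-separated centers when possible
      pick <- cand[sample(nrow(cand), min(nrow(cand), 500L)), , drop = FALSE]
      sel <- integer(0)
      for (j in seq_len(nrow(pick))) {
        if (length(sel) == 4L) break
        ok <- all(sqrt((pick[sel, 1] - pick[j, 1])^2 +
                       (pick[sel, 2] - pick[j, 2])^2) >= 2 * clusterSpec@spreadPx)
        if (!length(sel) || ok) sel <- c(sel, j)
      }
      while (length(sel) < 4L) sel <- c(sel, sample(nrow(pick), 1L))
      centers <- pick[sel[1:4], , drop = FALSE]
      for (q in 1:4) {
        ins <- insertMCCluster(slices[[sliceIdx[q]]], mask, clusterSpec,
                               c(centers[q, 1], centers[q, 2]),
                               deriveSeed(seed, "lesions", q))
        slices[[sliceIdx[q]]] <- ins$image
        clusters <- rbind(clusters, data.frame(
          slice = sliceIdx[q], row = centers[q, 1], col = centers[q, 2]))
      }
    })
  }
  new("DBTCase", patientId = as.character(patientId), density = density,
      label = label, slices = slices, clusters = clusters, breastMask = mask,
      pixelSizeMM = 0.085 * 1624 / 512 * (512 / gridSize))
}

#' Generate a labeled synthetic cohort
#'
#' Density counts follow largest-remainder rounding of the requested
#' proportions (so they always sum to \code{nCases}); positive cases are
#' distributed over densities the same way so every density carries both
#' classes whenever counts permit. All randomness derives from the single
#' cohort seed: regenerating with the same spec is bit-identical.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @return A \code{\linkS4class{DBTCohort}}.
#' @export
#' @examples
#' spec <- CohortSpec(nCases = 8, gridSize = 64, seed = 3)
#' cohort <- generateCohort(spec)
#' cohort
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  counts <- largestRemainder(spec@nCases, spec@densityProportions)
  nPos <- as.integer(round(spec@positiveFraction * spec@nCases))
  posPerDensity <- largestRemainder(nPos, counts / sum(counts))
  posPerDensity <- pmin(posPerDensity, counts)
  # if capping lost positives, give them to densities with room
  deficit <- nPos - sum(posPerDensity)
  while (deficit > 0) {
    room <- which(posPerDensity < counts)
    posPerDensity[room[1L]] <- posPerDensity[room[1L]] + 1L
    deficit <- deficit - 1L
  }
  cases <- list()
  idx <- 0L
  for (di in seq_along(DENSITY_LEVELS)) {
    for (j in seq_len(counts[di])) {
      idx <- idx + 1L
      label <- if (j <= posPerDensity[di]) "presentMCs" else "absent"
      pid <- sprintf("P%04d", idx)
      cases[[idx]] <- generateCase(
        pid, DENSITY_LEVELS[di], label, spec@clusterSpec,
        gridSize = spec@gridSize, seed = deriveSeed(spec@seed, "case", idx),
        sliceScale = spec@sliceScale)
    }
  }
  new("DBTCohort", cases = cases, spec = spec)
}

#' Write a cohort as 8-bit TIFF slices plus a manifest
#'
#' Every slice is quantized to 8 bits and written as a grayscale TIFF named
#' \code{<patient>_s<slice>.tif}; the manifest CSV records patient id,
#' density, label, slice index, file path and the ground-truth cluster
#' centers located on that slice (semicolon-separated \code{row:col} pairs).
#'
#' @param cohort a \code{DBTCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cs in cohort@cases) {
    for (si in seq_along(cs@slices)) {
      fn <- file.path(dir, sprintf("%s_s%03d.tif", cs@patientId, si))
      tiff::writeTIFF(to8bit(cs@slices[[si]]) / 255, fn, bits.per.sample = 8L)
      cl <- cs@clusters[cs@clusters$slice == si, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = cs@patientId, density = cs@density, label = cs@label,
        slice_index = si, file = fn,
        clusters = paste(sprintf("%.1f:%.1f", cl$row, cl$col), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path path to a \code{manifest.csv} written by
#'   \code{\link{writeCohort}} (or a directory containing one).
#' @return The manifest data.frame.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an 8-bit grayscale TIFF slice
#'
#' Generic ingestion for real reconstructed slices stored as 8-bit TIFF;
#' returns intensities rescaled to the unit range.
#'
#' @param path TIFF file path.
#' @return A matrix in [0, 1].
#' @export
readSliceTIFF <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  clip01(img)
}
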