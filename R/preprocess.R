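# Background suppression and the six preprocessing arms.
#
# Arm composition (background suppression with the original-image mask is
# applied to the result of every arm):
#   original : identity
#   p1 : TV (ROF) denoising
#   p2 : CLAHE
#   p3 : TV then CLAHE
#   p4 : CLAHE then TV
#   p5 : square normalization
#   p6 : square normalization then TV

#' Binarize a slice
#'
#' Thresholds a unit-range slice; the default strategy is Otsu's method on
#' the full slice, with an optional fixed threshold. A constant slice has
#' no meaningful threshold: an all-zeros mask is returned with attribute
#' \code{degenerate = TRUE}.
#'
#' @param image matrix in [0, 1].
#' @param threshold optional fixed threshold in (0, 1); overrides Otsu.
#' @return 0/1 matrix, foreground where intensity >= threshold.
#' @export
binarizeSlice <- function(image, threshold = NULL) {
  stopIfNot01(image)
  if (max(image) - min(image) < 1e-12) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(image))
  out <- (image >= threshold) * 1
  attr(out, "degenerate") <- FALSE
  out
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the grid border become
#' foreground; holes touching the border are kept (they are not holes).
#' Idempotent.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix.
#' @export
fillHoles <- function(mask) {
  out <- asPlainMatrix(EBImage::fillHull(EBImage::Image(mask > 0)))
  attr(out, "degenerate") <- attr(mask, "degenerate")
  out
}

#' Keep only the largest connected foreground component
#'
#' Components are 8-connected; ties in area are broken by label scan
#' order (first component encountered wins). An empty mask stays empty.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 matrix with at most one foreground component.
#' @export
largestComponent <- function(mask) {
  lab <- asPlainMatrix(EBImage::bwlabel(EBImage::Image(mask > 0)))
  if (max(lab) < 1) {
    out <- matrix(0, nrow(mask), ncol(mask))
  } else {
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)   # first maximum = scan-order tie break
    out <- matrix(as.numeric(lab == keep), nrow(mask), ncol(mask))
  }
  attr(out, "degenerate") <- attr(mask, "degenerate")
  out
}

#' Grow a breast mask into its faded rim
#'
#' Iterative region growing from the current mask boundary: at each pass,
#' 8-neighbors of the mask whose intensity exceeds
#' \code{admitFraction} of the in-mask mean intensity (computed on the
#' input mask) are admitted, until fixation. Growth is monotone and the
#' result remains a single connected component.
#'
#' @param mask 0/1 matrix with a single foreground component.
#' @param image intensity matrix in [0, 1] that guided binarization.
#' @param admitFraction admission threshold as a fraction of the in-mask
#'   mean intensity; \code{Inf} disables growth.
#' @param maxIter safety cap on growth passes.
#' @return 0/1 matrix containing the input mask.
#' @export
regionGrow <- function(mask, image, admitFraction = 0.10, maxIter = 256L) {
  if (sum(mask) == 0) return(mask)
  thr <- admitFraction * mean(image[mask > 0])
  if (!is.finite(thr)) return(mask)
  cur <- unclass(mask > 0)
  brush <- EBImage::makeBrush(3L, "box")
  for (i in seq_len(maxIter)) {
    dil <- asPlainMatrix(EBImage::dilate(EBImage::Image(cur), brush)) > 0
    newpx <- dil & !cur & (image >= thr)
    if (!any(newpx)) break
    cur <- cur | newpx
  }
  out <- matrix(as.numeric(cur), nrow(mask), ncol(mask))
  attr(out, "degenerate") <- attr(mask, "degenerate")
  out
}

#' Suppress background signal outside the breast
#'
#' Builds the breast mask in four steps -- binarize (Otsu), fill holes,
#' keep the largest component, region-grow into the faded rim -- and
#' multiplies the slice by it: pixels outside the mask become exactly 0,
#' pixels inside are untouched.
#'
#' @param image matrix in [0, 1].
#' @param admitFraction passed to \code{\link{regionGrow}}.
#' @return list with \code{image} (suppressed slice), \code{mask} (0/1
#'   matrix) and \code{degenerate} (TRUE when binarization failed and the
#'   mask is empty).
#' @export
suppressBackground <- function(image, admitFraction = 0.10) {
  b <- binarizeSlice(image)
  deg <- isTRUE(attr(b, "degenerate"))
  m <- regionGrow(largestComponent(fillHoles(b)), image, admitFraction)
  list(image = image * (m > 0), mask = (m > 0) * 1, degenerate = deg)
}

# forward-difference gradient (Neumann) and its negative adjoint
.grad <- function(u) {
  n <- nrow(u); m <- ncol(u)
  gx <- u[c(2:n, n), ] - u; gx[n, ] <- 0
  gy <- u[, c(2:m, m)] - u; gy[, m] <- 0
  list(x = gx, y = gy)
}
.divp <- function(px, py) {
  n <- nrow(px); m <- ncol(px)
  dx <- px - px[c(1, 1:(n - 1)), ]
  dx[1, ] <- px[1, ]; dx[n, ] <- -px[n - 1, ]
  dy <- py - py[, c(1, 1:(m - 1))]
  dy[, 1] <- py[, 1]; dy[, m] <- -py[, m - 1]
  dx + dy
}

#' Total-variation (ROF) denoising
#'
#' Minimizes \deqn{\lambda/2 \|u - f\|_2^2 + TV(u)} with isotropic total
#' variation by Chambolle's dual projection algorithm. Larger
#' \code{lambda} means stronger data fidelity (less smoothing); the
#' working default throughout the package is 14. The solver iterates
#' until the maximum pixel change falls below \code{tol} or
#' \code{maxIter} dual steps. By optimality, TV(output) <= TV(input).
#'
#' @param image matrix in [0, 1].
#' @param lambda positive fidelity weight.
#' @param tol convergence tolerance on the primal iterate.
#' @param maxIter maximum dual iterations.
#' @return Denoised matrix clipped to [0, 1].
#' @export
tvDenoise <- function(image, lambda = 14, tol = 1e-4, maxIter = 200L) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a positive number")
  stopIfNot01(image)
  theta <- 1 / lambda
  tau <- 0.25
  px <- py <- matrix(0, nrow(image), ncol(image))
  u <- image
  for (it in seq_len(maxIter)) {
    d <- .divp(px, py)
    g <- .grad(d - image / theta)
    den <- 1 + tau * sqrt(g$x^2 + g$y^2)
    px <- (px + tau * g$x) / den
    py <- (py + tau * g$y) / den
    uNew <- image - theta * .divp(px, py)
    if (max(abs(uNew - u)) < tol) { u <- uNew; break }
    u <- uNew
  }
  clip01(u)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based CLAHE with bilinear blending between neighboring tiles,
#' computed with \code{EBImage::clahe} (Zuiderveld's algorithm, the same
#' family as MATLAB's \code{adapthisteq}). The normalized clip limit in
#' (0, 1] is converted to the bin-height multiple the backend expects
#' (\code{clip * bins}). Only the uniform target histogram is
#' implemented; the distribution parameter \code{alpha} is inert under
#' it and retained for configuration fidelity.
#'
#' @param image matrix in [0, 1].
#' @param clip normalized contrast-enhancement limit (default 0.01).
#' @param tiles tile grid as (rows, cols), default 8 x 8.
#' @param dist target histogram shape; only \code{"uniform"} is available.
#' @param alpha distribution parameter (unused under uniform).
#' @param bins histogram bins per tile.
#' @return Matrix in [0, 1].
#' @export
claheSlice <- function(image, clip = 0.01, tiles = c(8L, 8L),
                       dist = "uniform", alpha = 0.4, bins = 256L) {
  stopIfNot01(image)
  if (dist != "uniform")
    stop("only the uniform target histogram is implemented")
  if (any(tiles > dim(image)))
    stop("tile grid larger than the image")
  n <- nrow(image); m <- ncol(image)
  # pad to tile multiples (replicate edges), run, crop back
  nPad <- ceiling(n / tiles[1]) * tiles[1]
  mPad <- ceiling(m / tiles[2]) * tiles[2]
  padded <- image[c(seq_len(n), rep(n, nPad - n)),
                  c(seq_len(m), rep(m, mPad - m)), drop = FALSE]
  out <- asPlainMatrix(EBImage::clahe(EBImage::Image(padded),
                                  nx = as.integer(tiles[1]),
                                  ny = as.integer(tiles[2]),
                                  bins = as.integer(bins),
                                  limit = clip * as.integer(bins)))
  clip01(out[seq_len(n), seq_len(m), drop = FALSE])
}

#' Square normalization
#'
#' Rescales intensities to [0, 1] and squares them, attenuating low
#' values and highlighting high-intensity structures such as
#' calcifications. Monotone in the input. A constant slice maps to all
#' zeros with attribute \code{degenerate = TRUE}.
#'
#' @param image numeric matrix.
#' @return Matrix in [0, 1].
#' @export
squareNormalize <- function(image) {
  rng <- range(image)
  if (diff(rng) < 1e-12) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ((image - rng[1]) / diff(rng))^2
}

#' Apply one preprocessing arm
#'
#' Runs the selected arm on a unit-range slice and applies background
#' suppression to the result. The breast mask is computed once from the
#' original slice and reused after the intensity transforms (CLAHE
#' amplifies background contamination, so a recomputed mask would be
#' corrupted).
#'
#' @param image matrix in [0, 1].
#' @param spec a \code{\link{PreprocessSpec}}.
#' @param mask optional precomputed 0/1 breast mask; computed from
#'   \code{image} when missing.
#' @return list with \code{image} (processed slice, zero outside the
#'   mask), \code{mask}, and \code{degenerate}.
#' @export
applyPreprocessing <- function(image, spec = PreprocessSpec(), mask = NULL) {
  stopifnot(is(spec, "PreprocessSpec"))
  deg <- FALSE
  if (is.null(mask)) {
    sb <- suppressBackground(image)
    mask <- sb$mask
    deg <- sb$degenerate
  }
  tv <- function(x) tvDenoise(x, spec@tvLambda)
  ce <- function(x) claheSlice(x, spec@claheClip, spec@claheTiles,
                               spec@claheDist, spec@claheAlpha)
  out <- switch(spec@method,
    original = image,
    p1 = tv(image),
    p2 = ce(image),
    p3 = ce(tv(image)),
    p4 = tv(ce(image)),
    p5 = squareNormalize(image),
    p6 = tv(squareNormalize(image)),
    stop("unknown preprocessing arm: ", spec@method))
  list(image = clip01(out) * (mask > 0), mask = mask, degenerate = deg)
}

#' Resize a slice (or mask) in-plane
#'
#' Antialiased bilinear resize to \code{targetSize} x \code{targetSize};
#' masks are resized with nearest-neighbor so they stay binary. Depth is
#' never resampled (training is slice-by-slice). An input already at the
#' target size is returned unchanged.
#'
#' @param image matrix.
#' @param targetSize output side in pixels.
#' @param isMask nearest-neighbor resize preserving binarity.
#' @return Matrix of dimension \code{targetSize x targetSize}.
#' @export
resizeSlice <- function(image, targetSize = 512L, isMask = FALSE) {
  targetSize <- as.integer(targetSize)
  if (nrow(image) == targetSize && ncol(image) == targetSize) return(image)
  if (isMask) {
    out <- asPlainMatrix(EBImage::resize(EBImage::Image(image), w = targetSize,
                                         h = targetSize, filter = "none"))
    return((out > 0.5) * 1)
  }
  out <- asPlainMatrix(EBImage::resize(EBImage::Image(image), w = targetSize,
                                       h = targetSize, filter = "bilinear"))
  clip01(out)
}

#' Quantize a unit-range slice to 8 bits
#'
#' @param image matrix in [0, 1].
#' @return Integer matrix with values 0..255.
#' @export
to8bit <- function(image) {
  stopIfNot01(image)
  out <- round(clip01(image) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Zero-center a slice for model input
#'
#' Subtracts the per-image mean (the "zero center" normalization applied
#' at model-input time) and records the offset.
#'
#' @param image numeric or integer matrix; 8-bit input is rescaled to
#'   [0, 1] first.
#' @return Matrix with mean 0 and attribute \code{offset} (the
#'   subtracted mean).
#' @export
zeroCenter <- function(image) {
  x <- if (is.integer(image)) image / 255 else image
  off <- mean(x)
  out <- x - off
  attr(out, "offset") <- off
  out
}
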