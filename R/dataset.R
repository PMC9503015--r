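# Slice selection, patient-level cross-validation and augmentation.

#' Proportional slice selection for absent cases
#'
#' Absent volumes contribute \code{nSelect} slices proportionally spaced
#' between the first and last slice: indices \code{1, 1+s, 1+2s, ...} with
#' spacing \code{s = ceiling((nSlices-1)/(nSelect-1))}, the final index
#' clamped to \code{nSlices} (62 slices give 1, 17, 33, 49, 62; 38 slices
#' give 1, 11, 21, 31, 38). Intermediate indices are clamped too, so very
#' shallow volumes can repeat the last slice.
#'
#' @param nSlices number of slices in the volume (>= \code{nSelect}).
#' @param nSelect number of slices to select (default 5).
#' @return Integer vector of 1-based slice indices, length \code{nSelect}.
#' @export
#' @examples
#' selectAbsentSlices(62)
#' selectAbsentSlices(38)
selectAbsentSlices <- function(nSlices, nSelect = 5L) {
  nSlices <- as.integer(nSlices); nSelect <- as.integer(nSelect)
  if (nSlices < nSelect)
    stop("cannot select ", nSelect, " slices from a ", nSlices, "-slice volume")
  s <- as.integer(ceiling((nSlices - 1) / (nSelect - 1)))
  idx <- 1L + s * (0:(nSelect - 1L))
  idx[nSelect] <- nSlices
  pmin(idx, nSlices)
}

#' Slice selection for cluster-bearing cases
#'
#' Positive cases contribute the slices holding cluster centers; when two
#' clusters share a slice the index appears once, so at most four indices
#' are returned.
#'
#' @param case a \code{DBTCase} with label \code{"presentMCs"}.
#' @return Sorted integer vector of unique slice indices.
#' @export
selectPresentSlices <- function(case) {
  stopifnot(is(case, "DBTCase"))
  if (case@label != "presentMCs")
    stop("slice selection by cluster center applies to presentMCs cases only")
  sort(unique(as.integer(case@clusters$slice)))
}

#' Assign patients to cross-validation folds
#'
#' Random partition of patients into \code{k} folds, stratified by
#' (density, label) so that small cohorts keep both classes in every
#' fold; within each stratum fold sizes differ by at most one, and a
#' global round-robin keeps overall fold sizes balanced. The split is at
#' the patient level: all slices of a patient inherit its fold.
#'
#' @param patientIds character vector of unique patient ids.
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @param densities,labels optional per-patient stratification factors
#'   (same length as \code{patientIds}).
#' @return A \code{\linkS4class{FoldAssignment}}.
#' @export
assignFolds <- function(patientIds, k = 3L, seed = 1L,
                        densities = NULL, labels = NULL) {
  k <- as.integer(k)
  n <- length(patientIds)
  if (anyDuplicated(patientIds)) stop("patient ids must be unique")
  if (n < k) stop("fewer patients (", n, ") than folds (", k, ")")
  strata <- if (is.null(densities) && is.null(labels)) rep("all", n) else
    paste(if (is.null(densities)) "" else densities,
          if (is.null(labels)) "" else labels, sep = "|")
  mapping <- integer(n)
  names(mapping) <- patientIds
  withSeed(seed, {
    counter <- sample.int(k, 1L) - 1L   # random fold offset
    for (s in sample(unique(strata))) {
      ids <- patientIds[strata == s]
      ids <- ids[sample.int(length(ids))]
      for (id in ids) {
        mapping[id] <- (counter %% k) + 1L
        counter <- counter + 1L
      }
    }
  })
  new("FoldAssignment", k = k, mapping = mapping)
}

#' Augment a training slice
#'
#' Optional left-right reflection (probability 0.5, emulating right
#' breasts) followed by rotation by a uniform draw in the symmetric range;
#' bilinear interpolation, out-of-canvas pixels filled with the background
#' value 0, grid shape preserved. Used on training data only.
#'
#' @param image slice matrix.
#' @param spec an \code{\link{AugmentSpec}}.
#' @param drawSeed seed for this draw (vary per image and epoch).
#' @return Matrix of the same dimension.
#' @export
augmentSlice <- function(image, spec = AugmentSpec(), drawSeed = 1L) {
  withSeed(drawSeed, {
    out <- image
    if (spec@reflectLR && stats::runif(1L) < 0.5)
      out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
    if (spec@rotationRangeDeg > 0) {
      ang <- stats::runif(1L, -spec@rotationRangeDeg, spec@rotationRangeDeg)
      out <- as.matrix(EBImage::rotate(EBImage::Image(out), ang,
                                       filter = "bilinear",
                                       output.dim = dim(out), bg.col = 0))
    }
    out
  })
}

#' Build the selected-slice table of a cohort
#'
#' Applies the per-class slice-selection rules to every case: absent cases
#' contribute \code{nSelect} proportionally spaced slices, positive cases
#' the (deduplicated) slices holding cluster centers.
#'
#' @param cohort a \code{DBTCohort}.
#' @param nSelect slices per absent case (default 5).
#' @return data.frame with columns patient_id, density, label, slice_index
#'   and case_index (position of the case in the cohort).
#' @export
sliceTable <- function(cohort, nSelect = 5L) {
  rows <- lapply(seq_along(cohort@cases), function(i) {
    cs <- cohort@cases[[i]]
    idx <- if (cs@label == "absent")
      selectAbsentSlices(length(cs@slices), nSelect)
    else selectPresentSlices(cs)
    data.frame(patient_id = cs@patientId, density = cs@density,
               label = cs@label, slice_index = idx, case_index = i,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Case counts of the emulated in-silico screening cohort
#'
#' The absent / presentMCs case counts per density class of the full-scale
#' reconstructed archive this package emulates. Useful for dataset
#' arithmetic (absent cases contribute 5 selected slices each).
#'
#' @return data.frame with columns density, absent, presentMCs.
#' @export
referenceCohortDesign <- function() {
  data.frame(density = DENSITY_LEVELS,
             absent = c(20L, 80L, 80L, 20L),
             presentMCs = c(25L, 100L, 100L, 25L))
}
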