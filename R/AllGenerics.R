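# Accessors (slots are implementation detail; use these in user code).

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' Accessors for cases and cohorts
#'
#' @param x a \code{DBTCase}, \code{DBTCohort}, \code{EvalResult} or
#'   \code{FoldAssignment} object.
#' @return \code{patientId}, \code{caseDensity}, \code{caseLabel}: character
#'   (vectors over cases for a cohort); \code{caseSlices}: list of slice
#'   matrices; \code{caseClusters}: data.frame of cluster centers
#'   (slice/row/col); \code{trueBreastMask}: 0/1 matrix;
#'   \code{cohortCases}: list of \code{DBTCase}; \code{aucValue}: numeric;
#'   \code{foldMap}: named integer vector.
#' @name accessors
#' @rdname accessors
#' @aliases patientId caseDensity caseLabel caseSlices caseClusters
#'   trueBreastMask cohortCases aucValue foldMap
#' @export
setMethod("patientId", "DBTCase", function(x) x@patientId)
#' @export
setMethod("patientId", "DBTCohort",
          function(x) vapply(x@cases, function(c) c@patientId, character(1L)))

#' @export
setGeneric("caseDensity", function(x) standardGeneric("caseDensity"))
#' @export
setMethod("caseDensity", "DBTCase", function(x) x@density)
#' @export
setMethod("caseDensity", "DBTCohort",
          function(x) vapply(x@cases, function(c) c@density, character(1L)))

#' @export
setGeneric("caseLabel", function(x) standardGeneric("caseLabel"))
#' @export
setMethod("caseLabel", "DBTCase", function(x) x@label)
#' @export
setMethod("caseLabel", "DBTCohort",
          function(x) vapply(x@cases, function(c) c@label, character(1L)))

#' @export
setGeneric("caseSlices", function(x) standardGeneric("caseSlices"))
#' @export
setMethod("caseSlices", "DBTCase", function(x) x@slices)

#' @export
setGeneric("caseClusters", function(x) standardGeneric("caseClusters"))
#' @export
setMethod("caseClusters", "DBTCase", function(x) x@clusters)

#' @export
setGeneric("trueBreastMask", function(x) standardGeneric("trueBreastMask"))
#' @export
setMethod("trueBreastMask", "DBTCase", function(x) x@breastMask)

#' @export
setGeneric("cohortCases", function(x) standardGeneric("cohortCases"))
#' @export
setMethod("cohortCases", "DBTCohort", function(x) x@cases)

#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @export
setMethod("aucValue", "EvalResult", function(x) x@auc)

#' @export
setGeneric("foldMap", function(x) standardGeneric("foldMap"))
#' @export
setMethod("foldMap", "FoldAssignment", function(x) x@mapping)
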