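#' Number of sites in a dataset or fit
#' @param object an [OccupancyData-class] object.
#' @return integer site count.
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' Per-site visit counts
#' @param object an [OccupancyData-class] object.
#' @return integer vector of visits per site.
#' @export
setGeneric("visitCounts", function(object) standardGeneric("visitCounts"))

#' Detection design matrix (one row per visit, site-major order)
#' @param object an [OccupancyData-class] object.
#' @export
setGeneric("detectionDesign", function(object) standardGeneric("detectionDesign"))

#' Occupancy design matrix (one row per site)
#' @param object an [OccupancyData-class] object.
#' @export
setGeneric("occupancyDesign", function(object) standardGeneric("occupancyDesign"))

#' Ragged detection histories
#' @param object an [OccupancyData-class] object.
#' @return list of per-site binary vectors.
#' @export
setGeneric("detectionHistory", function(object) standardGeneric("detectionHistory"))

#' Which sites have at least one detection?
#' @param object an [OccupancyData-class] object.
#' @return logical vector of length `n`.
#' @export
setGeneric("detectedSites", function(object) standardGeneric("detectedSites"))

#' Conditional occupancy probabilities of a fitted model
#'
#' Posterior probability that each site is occupied given its detection
#' history; exactly 1 for sites with at least one detection.
#'
#' @param object a fitted model ([OccuFitVB-class] or [OccuFitMCMC-class]).
#' @param ... further arguments for methods.
#' @return numeric vector of length `n`.
#' @export
setGeneric("conditionalOccupancy",
           function(object, ...) standardGeneric("conditionalOccupancy"))

#' Tidy parameter summary of a fitted occupancy model
#'
#' @param object a fitted model.
#' @param level interval level (default 0.95).
#' @return data.frame with columns `parameter`, `estimate`, `se`,
#'   `lower`, `upper`.
#' @export
setGeneric("parameterSummary",
           function(object, level = 0.95) standardGeneric("parameterSummary"))
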