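#' Construct an OccupancyData object
#'
#' Bundles ragged detection histories with their design matrices. Detection
#' histories are stored site-major: all visits to site 1, then site 2, and
#' so on; row block `i` of `W` holds the `K[i]` visit rows of site `i`.
#'
#' @param y binary detections: either a numeric vector of length `sum(K)` in
#'   site-major order, or a list of per-site vectors (lengths giving `K`).
#' @param K per-site visit counts; ignored (inferred) when `y` is a list.
#' @param W detection design matrix, `sum(K) x s`.
#' @param X occupancy design matrix, `n x r`.
#' @param siteIds optional site labels.
#' @return an [OccupancyData-class] object.
#' @examples
#' d <- occuData(y = list(c(0, 1), 0), W = cbind(1, c(-1, 0, 1)),
#'               X = cbind(1, c(0.5, -0.5)))
#' nSites(d)
#' @export
occuData <- function(y, K = NULL, W, X, siteIds = NULL) {
  if (is.list(y)) {
    K <- vapply(y, length, integer(1))
    y <- unlist(y, use.names = FALSE)
  }
  if (is.null(K)) stop("K required when y is not a list")
  K <- as.integer(K)
  W <- as.matrix(W)
  X <- as.matrix(X)
  storage.mode(W) <- "double"
  storage.mode(X) <- "double"
  if (is.null(siteIds)) siteIds <- as.character(seq_along(K))
  new("OccupancyData", y = as.numeric(y), K = K, W = W, X = X,
      siteIds = as.character(siteIds))
}

#' @describeIn occuData number of sites.
#' @param object an OccupancyData object.
#' @export
setMethod("nSites", "OccupancyData", function(object) length(object@K))

#' @rdname occuData
#' @export
setMethod("visitCounts", "OccupancyData", function(object) object@K)

#' @rdname occuData
#' @export
setMethod("detectionDesign", "OccupancyData", function(object) object@W)

#' @rdname occuData
#' @export
setMethod("occupancyDesign", "OccupancyData", function(object) object@X)

#' @rdname occuData
#' @export
setMethod("detectionHistory", "OccupancyData", function(object) {
  split(object@y, rep(seq_along(object@K), object@K))
})

#' @rdname occuData
#' @export
setMethod("detectedSites", "OccupancyData", function(object) {
  as.vector(rowsum(object@y, rep(seq_along(object@K), object@K)) > 0)
})

setMethod("show", "OccupancyData", function(object) {
  n <- length(object@K)
  cat("OccupancyData:", n, "sites,", sum(object@K), "visits",
      sprintf("(K in [%d, %d])\n", min(object@K), max(object@K)))
  cat("  detection design:", ncol(object@W), "column(s);",
      "occupancy design:", ncol(object@X), "column(s)\n")
  cat("  sites with >=1 detection:", sum(detectedSites(object)), "\n")
})

#' Expand a per-site vector to visit rows
#'
#' Repeats element `i` of `v` exactly `K[i]` times, preserving the
#' site-major ordering used by the visit-level arrays. Used to turn the
#' per-site occupancy probabilities `p` into their visit-level expansion.
#'
#' @param v numeric vector of length `n`.
#' @param K integer visit counts of length `n`.
#' @return numeric vector of length `sum(K)`.
#' @examples
#' expandSiteToVisits(c(0.2, 0.9), c(2, 1))
#' @export
expandSiteToVisits <- function(v, K) {
  if (length(v) != length(K)) stop("length(v) must equal length(K)")
  rep(v, times = K)
}

# site index of each visit row
.siteIndex <- function(data) rep(seq_along(data@K), data@K)
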