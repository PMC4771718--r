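#' Read occupancy data from long-format CSV files
#'
#' The visits file holds one row per site visit with columns `site`,
#' `visit`, `y`, followed by any detection covariates; the sites file holds
#' one row per site with column `site` followed by occupancy covariates.
#' Rows are assembled site-major (sites in the order of the sites file,
#' visits sorted by `visit` within site), ragged visit counts are inferred,
#' intercept columns are prepended, and covariates are standardized to mean
#' 0 / SD 1 by default.
#'
#' @param visitsPath path to the visit-level CSV.
#' @param sitesPath path to the site-level CSV.
#' @param standardize standardize covariate columns (default TRUE).
#' @param intercept prepend intercept columns (default TRUE).
#' @param maxVisits optional cap: keep only the first `maxVisits` visits
#'   per site (by `visit` order).
#' @return an [OccupancyData-class] object.
#' @export
readOccupancyCsv <- function(visitsPath, sitesPath, standardize = TRUE,
                             intercept = TRUE, maxVisits = NULL) {
  visits <- utils::read.csv(visitsPath, check.names = FALSE)
  sites <- utils::read.csv(sitesPath, check.names = FALSE)
  need <- c("site", "visit", "y")
  if (!all(need %in% names(visits)))
    stop("visits file must have columns site, visit, y")
  if (!"site" %in% names(sites)) stop("sites file must have a site column")
  if (anyNA(visits) || anyNA(sites)) stop("missing covariate values are not supported")
  if (!all(visits$y %in% c(0, 1))) stop("y must be binary")
  unknown <- setdiff(visits$site, sites$site)
  if (length(unknown))
    stop("visit rows reference unknown sites: ", paste(unknown, collapse = ", "))
  visits <- visits[order(match(visits$site, sites$site), visits$visit), ]
  if (!is.null(maxVisits)) {
    keep <- stats::ave(seq_len(nrow(visits)), visits$site,
                       FUN = seq_along) <= maxVisits
    visits <- visits[keep, ]
  }
  sites <- sites[sites$site %in% visits$site, , drop = FALSE]
  K <- as.integer(table(factor(visits$site, levels = sites$site)))
  detCov <- as.matrix(visits[setdiff(names(visits), need)])
  occCov <- as.matrix(sites[setdiff(names(sites), "site")])
  std <- function(M) if (standardize && ncol(M)) scale(M) else M
  addInt <- function(M) if (intercept) cbind(`(Intercept)` = 1, M) else M
  W <- addInt(std(detCov)); X <- addInt(std(occCov))
  if (ncol(W) == 0L || ncol(X) == 0L)
    stop("each design matrix needs at least one column")
  occuData(y = visits$y, K = K, W = W, X = X, siteIds = as.character(sites$site))
}

#' Write occupancy data back to the long-format CSV schema
#'
#' Inverse of [readOccupancyCsv()] with `standardize = FALSE`,
#' `intercept = FALSE`: covariate columns are written as stored (intercept
#' columns excluded), so a read round-trip reproduces `y`, `W`, `X`.
#'
#' @param data an [OccupancyData-class] object.
#' @param visitsPath,sitesPath output paths.
#' @param dropIntercept omit leading all-ones columns (default TRUE).
#' @return invisibly, the two paths.
#' @export
writeOccupancyCsv <- function(data, visitsPath, sitesPath,
                              dropIntercept = TRUE) {
  dropInt <- function(M, prefix) {
    if (dropIntercept && ncol(M) && all(M[, 1] == 1)) M <- M[, -1, drop = FALSE]
    if (ncol(M) && is.null(colnames(M)))
      colnames(M) <- paste0(prefix, seq_len(ncol(M)))
    colnames(M)[colnames(M) == ""] <- paste0(prefix, which(colnames(M) == ""))
    M
  }
  W <- dropInt(data@W, "w"); X <- dropInt(data@X, "x")
  idx <- .siteIndex(data)
  visit <- stats::ave(idx, idx, FUN = seq_along)
  visits <- data.frame(site = data@siteIds[idx], visit = visit, y = data@y)
  if (ncol(W)) visits <- cbind(visits, as.data.frame(W))
  sites <- data.frame(site = data@siteIds)
  if (ncol(X)) sites <- cbind(sites, as.data.frame(X))
  utils::write.csv(visits, visitsPath, row.names = FALSE)
  utils::write.csv(sites, sitesPath, row.names = FALSE)
  invisible(c(visitsPath, sitesPath))
}
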