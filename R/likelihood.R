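#' Softplus and its derivatives
#'
#' The logistic cumulant function `b(x) = log(1 + exp(x))` together with its
#' first two derivatives, evaluated stably for large `|x|`: `b'(x)` is the
#' logistic function and `b''(x)` its variance function.
#'
#' @param x numeric vector of finite values.
#' @return list with components `b`, `b1`, `b2`.
#' @examples
#' bFuncs(0)  # log(2), 0.5, 0.25
#' @export
bFuncs <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  list(b = softplus(x), b1 = stats::plogis(x),
       b2 = stats::plogis(x) * stats::plogis(-x))
}

#' @rdname bFuncs
#' @export
softplus <- function(x) {
  # log(1 + e^x) = max(x, 0) + log1p(exp(-|x|))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Occupancy and detection probabilities under the logistic links
#'
#' Computes `psi_i = logistic(x_i beta)` per site and
#' `d_ij = logistic(w_ij alpha)` per visit row.
#'
#' @param data an [OccupancyData-class] object.
#' @param alpha detection coefficients (length `ncol(W)`).
#' @param beta occupancy coefficients (length `ncol(X)`).
#' @return list with `psi` (length `n`) and `d` (length `N`, site-major).
#' @export
linkProbs <- function(data, alpha, beta) {
  if (length(alpha) != ncol(data@W) || length(beta) != ncol(data@X))
    stop("coefficient length does not match the design matrices")
  list(psi = stats::plogis(drop(data@X %*% beta)),
       d = stats::plogis(drop(data@W %*% alpha)))
}

#' Joint log-likelihood of data and latent occupancy states
#'
#' `log p(y, z | alpha, beta)` for the hierarchical model
#' `z_i ~ Bernoulli(psi_i)`, `y_ij | z_i ~ Bernoulli(z_i d_ij)`.
#' Returns `-Inf` for impossible configurations (a detection at a site with
#' `z_i = 0`), so optimizers and samplers can reject them.
#'
#' @param data an [OccupancyData-class] object.
#' @param z binary vector of length `n`.
#' @param alpha,beta coefficient vectors.
#' @return scalar log-likelihood (possibly `-Inf`).
#' @export
jointLogLik <- function(data, z, alpha, beta) {
  if (length(z) != length(data@K)) stop("z must have one entry per site")
  if (!all(z %in% c(0, 1))) stop("z must be binary")
  pr <- linkProbs(data, alpha, beta)
  zt <- expandSiteToVisits(z, data@K)
  if (any(zt == 0 & data@y == 1)) return(-Inf)
  etaW <- drop(data@W %*% alpha)
  etaX <- drop(data@X %*% beta)
  occ <- sum(z * etaX - softplus(etaX))
  det <- sum(zt * (data@y * etaW - softplus(etaW)))
  occ + det
}

#' Marginal log-likelihood of an occupancy model
#'
#' `log p(y | alpha, beta)` with the latent states summed out: site `i`
#' contributes `log[ psi_i prod_j d^y (1-d)^(1-y) + (1-psi_i) 1{y_i = 0} ]`,
#' evaluated in log space.
#'
#' @inheritParams jointLogLik
#' @return scalar log-likelihood.
#' @export
marginalLogLik <- function(data, alpha, beta) {
  etaW <- drop(data@W %*% alpha)
  etaX <- drop(data@X %*% beta)
  idx <- .siteIndex(data)
  # per-site detection log-likelihood given occupancy
  ldet <- as.vector(rowsum(data@y * etaW - softplus(etaW), idx))
  lpsi <- -softplus(-etaX)    # log psi
  lq <- -softplus(etaX)       # log(1 - psi)
  det <- detectedSites(data)
  a <- lpsi + ldet
  out <- numeric(length(a))
  out[det] <- a[det]
  if (any(!det)) {
    u <- a[!det]; v <- lq[!det]
    m <- pmax(u, v)
    out[!det] <- m + log(exp(u - m) + exp(v - m))
  }
  sum(out)
}

# analytic gradient of marginalLogLik wrt c(alpha, beta); used by the MLE
# fitter. For an undetected site the two z-completions are mixed with the
# posterior weight wA = P(z = 1 | y = 0).
.marginalGrad <- function(data, alpha, beta) {
  etaW <- drop(data@W %*% alpha)
  etaX <- drop(data@X %*% beta)
  d <- stats::plogis(etaW)
  psi <- stats::plogis(etaX)
  idx <- .siteIndex(data)
  det <- detectedSites(data)
  ldet <- as.vector(rowsum(data@y * etaW - softplus(etaW), idx))
  wA <- numeric(length(det))
  wA[det] <- 1
  wA[!det] <- stats::plogis(etaX[!det] + ldet[!det])
  wTilde <- expandSiteToVisits(wA, data@K)
  gAlpha <- drop(crossprod(data@W, wTilde * (data@y - d)))
  gBeta <- drop(crossprod(data@X, wA - psi))
  c(gAlpha, gBeta)
}
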