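#' @import methods
NULL

#' Detection-nondetection data for a single-season occupancy model
#'
#' Stores ragged detection histories in site-major order together with the
#' visit-level detection design matrix `W` (one row per visit) and the
#' site-level occupancy design matrix `X` (one row per site). Site `i` is
#' visited `K[i]` times; the total number of visit rows is `N = sum(K)`.
#'
#' @slot y numeric vector of length `N`; binary detections, site-major order.
#' @slot K integer vector of length `n`; visits per site, each at least 1.
#' @slot W numeric matrix, `N x s`; detection design (visit covariates).
#' @slot X numeric matrix, `n x r`; occupancy design (site covariates).
#' @slot siteIds character vector of length `n`; site labels.
#'
#' @seealso [occuData()] for the validating constructor,
#'   [readOccupancyCsv()] for building one from long-format files.
#' @export
setClass("OccupancyData",
  representation(
    y = "numeric",
    K = "integer",
    W = "matrix",
    X = "matrix",
    siteIds = "character"
  )
)

setValidity("OccupancyData", function(object) {
  n <- length(object@K)
  N <- sum(object@K)
  msg <- character()
  if (n < 1L) msg <- c(msg, "at least one site required")
  if (any(object@K < 1L)) msg <- c(msg, "every site needs at least one visit")
  if (length(object@y) != N) msg <- c(msg, "length(y) must equal sum(K)")
  if (anyNA(object@y) || !all(object@y %in% c(0, 1)))
    msg <- c(msg, "y must be binary with no missing values")
  if (nrow(object@W) != N) msg <- c(msg, "nrow(W) must equal sum(K)")
  if (nrow(object@X) != n) msg <- c(msg, "nrow(X) must equal length(K)")
  if (anyNA(object@W) || anyNA(object@X))
    msg <- c(msg, "covariates must not contain missing values")
  if (length(object@siteIds) != n) msg <- c(msg, "siteIds must have one label per site")
  if (length(msg)) msg else TRUE
})

#' Gaussian prior specification for the detection and occupancy effects
#'
#' Independent multivariate Gaussian priors for the detection coefficients
#' `alpha` (length `s`) and the occupancy coefficients `beta` (length `r`).
#'
#' @slot muAlpha,muBeta prior mean vectors.
#' @slot SigmaAlpha,SigmaBeta symmetric positive-definite prior covariances.
#'
#' @seealso [priorSpec()], [defaultPrior()]
#' @export
setClass("PriorSpec",
  representation(
    muAlpha = "numeric",
    SigmaAlpha = "matrix",
    muBeta = "numeric",
    SigmaBeta = "matrix"
  )
)

.checkCov <- function(S, what) {
  msg <- character()
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
    msg <- c(msg, paste(what, "must be symmetric"))
  else if (inherits(try(chol(S), silent = TRUE), "try-error"))
    msg <- c(msg, paste(what, "must be positive-definite"))
  msg
}

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (length(object@muAlpha) != nrow(object@SigmaAlpha))
    msg <- c(msg, "muAlpha and SigmaAlpha dimensions disagree")
  if (length(object@muBeta) != nrow(object@SigmaBeta))
    msg <- c(msg, "muBeta and SigmaBeta dimensions disagree")
  msg <- c(msg, .checkCov(object@SigmaAlpha, "SigmaAlpha"),
           .checkCov(object@SigmaBeta, "SigmaBeta"))
  if (length(msg)) msg else TRUE
})

#' Virtual parent class for fitted occupancy models
#'
#' @slot method fitter label: "laplace", "tangent", "mle" or "mcmc".
#' @slot converged whether the fitter met its convergence rule.
#' @export
setClass("OccuFit",
  representation("VIRTUAL",
    method = "character",
    converged = "logical"
  )
)

#' Gaussian variational posterior for an occupancy model
#'
#' Product-form variational approximation `q(alpha) q(beta) prod_i q(z_i)`:
#' Gaussian factors for the regression effects and independent Bernoulli
#' factors with success probabilities `sp` for the latent occupancy states.
#' Sites with at least one detection have `sp = 1` exactly.
#'
#' @slot muAlpha,SigmaAlpha Gaussian factor for the detection effects.
#' @slot muBeta,SigmaBeta Gaussian factor for the occupancy effects.
#' @slot sp per-site conditional occupancy probabilities, length `n`.
#' @slot elboTrace monitored variational lower bound, one value per outer cycle.
#' @slot iterations outer cycles used.
#'
#' @seealso [fitOccu()], [conditionalOccupancy()], [paoPredictive()]
#' @export
setClass("OccuFitVB",
  contains = "OccuFit",
  representation(
    muAlpha = "numeric",
    SigmaAlpha = "matrix",
    muBeta = "numeric",
    SigmaBeta = "matrix",
    sp = "numeric",
    elboTrace = "numeric",
    iterations = "integer"
  )
)

setValidity("OccuFitVB", function(object) {
  msg <- character()
  if (any(object@sp < -1e-12 | object@sp > 1 + 1e-12))
    msg <- c(msg, "sp must lie in [0, 1]")
  msg <- c(msg, .checkCov(object@SigmaAlpha, "SigmaAlpha"),
           .checkCov(object@SigmaBeta, "SigmaBeta"))
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood fit of an occupancy model
#'
#' @slot alpha,beta point estimates.
#' @slot vcov observed-information covariance of `c(alpha, beta)`, or a
#'   matrix of `NA` when the Hessian was not positive-definite.
#' @slot logLik maximized marginal log-likelihood.
#' @slot boundary flag for estimates on/near the parameter-space boundary
#'   (very large linear predictors; separation-type degeneracy).
#' @slot seAvailable whether Wald standard errors could be computed.
#' @export
setClass("OccuFitML",
  contains = "OccuFit",
  representation(
    alpha = "numeric",
    beta = "numeric",
    vcov = "matrix",
    logLik = "numeric",
    boundary = "logical",
    seAvailable = "logical"
  )
)

#' Posterior draws from the data-augmentation MCMC sampler
#'
#' @slot alphaDraws,betaDraws retained post-burn-in draws, one row each.
#' @slot zDraws optional retained latent-state draws (`iterations x n`),
#'   or a 0-row matrix when not stored.
#' @slot accept acceptance rates of the two Metropolis blocks.
#' @slot nBurnin,nIter chain settings actually used.
#' @export
setClass("OccuFitMCMC",
  contains = "OccuFit",
  representation(
    alphaDraws = "matrix",
    betaDraws = "matrix",
    zDraws = "matrix",
    accept = "numeric",
    nBurnin = "integer",
    nIter = "integer"
  )
)

#' Posterior-predictive sample of the number of occupied sites
#'
#' Draws of `sum_i z_i` (a site count in `[m, n]`, where `m` is the number of
#' sites with at least one detection). Divide by `n` for the PAO proportion.
#'
#' @slot draws integer-valued draws of the occupied-site count.
#' @slot n number of sites.
#' @slot nDetected number of sites with at least one detection (lower bound).
#' @export
setClass("PaoSample",
  representation(
    draws = "numeric",
    n = "integer",
    nDetected = "integer"
  )
)

setValidity("PaoSample", function(object) {
  if (length(object@draws) < 1L) return("at least one draw required")
  if (any(object@draws < object@nDetected - 1e-9) ||
      any(object@draws > object@n + 1e-9))
    return("draws must lie between the detected-site count and n")
  TRUE
})
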