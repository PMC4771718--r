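#' Construct a Gaussian prior specification
#'
#' @param muAlpha,muBeta prior mean vectors for the detection and occupancy
#'   coefficients.
#' @param SigmaAlpha,SigmaBeta prior covariance matrices (symmetric PD).
#' @return a [PriorSpec-class] object.
#' @export
priorSpec <- function(muAlpha, SigmaAlpha, muBeta, SigmaBeta) {
  new("PriorSpec",
      muAlpha = as.numeric(muAlpha), SigmaAlpha = as.matrix(SigmaAlpha),
      muBeta = as.numeric(muBeta), SigmaBeta = as.matrix(SigmaBeta))
}

#' Default vague prior for an occupancy dataset
#'
#' Independent N(0, `variance` I) priors on both coefficient vectors; the
#' default variance of 1000 gives an effectively flat prior on the logit
#' scale for standardized covariates.
#'
#' @param data an [OccupancyData-class] object (sets the dimensions).
#' @param variance common prior variance per coefficient.
#' @return a [PriorSpec-class] object.
#' @export
defaultPrior <- function(data, variance = 1000) {
  s <- ncol(data@W); r <- ncol(data@X)
  priorSpec(rep(0, s), diag(variance, s), rep(0, r), diag(variance, r))
}

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec: alpha ~ N(mu, Sigma), dim", length(object@muAlpha),
      "; beta ~ N(mu, Sigma), dim", length(object@muBeta), "\n")
})
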