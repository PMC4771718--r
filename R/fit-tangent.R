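#' Jaakkola-Jordan tangent-bound functions
#'
#' The quadratic tangent bound on the logistic log-likelihood,
#' `log sigma(x) >= log sigma(xi) + (x - xi)/2 - lambda(xi)(x^2 - xi^2)`,
#' uses the curvature weight `lambda(xi) = tanh(xi/2) / (4 xi)` (an even
#' function, `lambda(0) = 1/8` by continuity). `jjC(xi)` collects the
#' xi-only terms `log sigma(xi) - xi/2 + lambda(xi) xi^2` that appear in the
#' conditional-occupancy update and in the monitored bound.
#'
#' @param xi numeric vector of variational parameters.
#' @return numeric vector.
#' @examples
#' jjLambda(0)  # 1/8
#' @export
jjLambda <- function(xi) {
  out <- rep(0.125, length(xi))
  nz <- abs(xi) > 1e-6
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  out
}

#' @rdname jjLambda
#' @export
jjC <- function(xi) {
  # log sigma(xi) = -softplus(-xi)
  -softplus(-xi) - xi / 2 + jjLambda(xi) * xi^2
}

# E_q[(z' theta)^2] per row: second moment of the linear predictor
.rowSecondMoment <- function(Z, mu, Sigma) {
  m <- drop(Z %*% mu)
  pmax(rowSums((Z %*% Sigma) * Z), 0) + m^2
}

# Eq-6-style conditional occupancy update under the tangent bound
.spTangent <- function(data, muAlpha, SigmaAlpha, muBeta, xiDet) {
  det <- detectedSites(data)
  mW <- drop(data@W %*% muAlpha)
  qW <- .rowSecondMoment(data@W, muAlpha, SigmaAlpha)
  rowTerm <- jjC(xiDet) - 0.5 * mW - jjLambda(xiDet) * qW
  ci <- drop(data@X %*% muBeta) + as.vector(rowsum(rowTerm, .siteIndex(data)))
  sp <- stats::plogis(ci)
  sp[det] <- 1
  sp
}

# monitored tangent lower bound (exact lower bound on the log evidence)
.elboTangent <- function(data, prior, muAlpha, SigmaAlpha, muBeta, SigmaBeta,
                         sp, xiDet, xiOcc, cache) {
  spTilde <- expandSiteToVisits(sp, data@K)
  mW <- drop(data@W %*% muAlpha)
  qW <- .rowSecondMoment(data@W, muAlpha, SigmaAlpha)
  mX <- drop(data@X %*% muBeta)
  qX <- .rowSecondMoment(data@X, muBeta, SigmaBeta)
  Edet <- sum(spTilde * (data@y * mW + jjC(xiDet) - 0.5 * mW -
                           jjLambda(xiDet) * qW))
  Eocc <- sum(sp * mX + jjC(xiOcc) - 0.5 * mX - jjLambda(xiOcc) * qX)
  Edet + Eocc +
    .gaussPriorTerm(muAlpha, SigmaAlpha, prior@muAlpha, cache$SaInv, cache$ldSa) +
    .gaussPriorTerm(muBeta, SigmaBeta, prior@muBeta, cache$SbInv, cache$ldSb) +
    .gaussEntropy(SigmaAlpha) + .gaussEntropy(SigmaBeta) + .bernEntropy(sp)
}

.fitTangent <- function(data, prior, control) {
  cache <- .priorCache(prior)
  s <- ncol(data@W); r <- ncol(data@X)
  n <- length(data@K); N <- sum(data@K)
  muAlpha <- rep(0, s); muBeta <- rep(0, r)
  SigmaAlpha <- prior@SigmaAlpha; SigmaBeta <- prior@SigmaBeta
  sp <- .initSp(data)
  xiDet <- rep(1, N); xiOcc <- rep(1, n)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(control$maxOuter)) {
    sp <- .spTangent(data, muAlpha, SigmaAlpha, muBeta, xiDet)
    spTilde <- expandSiteToVisits(sp, data@K)
    # closed-form Gaussian updates: B1/B2 for alpha, D1/D2 for beta
    B1 <- cache$SaInv + 2 * crossprod(data@W * (jjLambda(xiDet) * spTilde), data@W)
    b2 <- drop(crossprod(data@W, spTilde * (data@y - 0.5))) +
      drop(cache$SaInv %*% prior@muAlpha)
    chB <- chol(B1)
    SigmaAlpha <- chol2inv(chB)
    muAlpha <- drop(SigmaAlpha %*% b2)
    D1 <- cache$SbInv + 2 * crossprod(data@X * jjLambda(xiOcc), data@X)
    d2 <- drop(crossprod(data@X, sp - 0.5)) + drop(cache$SbInv %*% prior@muBeta)
    chD <- chol(D1)
    SigmaBeta <- chol2inv(chD)
    muBeta <- drop(SigmaBeta %*% d2)
    # optimal variational parameters: xi^2 = E_q[(linear predictor)^2]
    xiDet <- sqrt(.rowSecondMoment(data@W, muAlpha, SigmaAlpha))
    xiOcc <- sqrt(.rowSecondMoment(data@X, muBeta, SigmaBeta))
    trace <- c(trace, .elboTangent(data, prior, muAlpha, SigmaAlpha,
                                   muBeta, SigmaBeta, sp, xiDet, xiOcc, cache))
    k <- length(trace)
    if (k >= 2 && abs(trace[k] - trace[k - 1]) <= control$tolerance) {
      converged <- TRUE
      break
    }
  }
  new("OccuFitVB", method = "tangent", converged = converged,
      muAlpha = muAlpha, SigmaAlpha = (SigmaAlpha + t(SigmaAlpha)) / 2,
      muBeta = muBeta, SigmaBeta = (SigmaBeta + t(SigmaBeta)) / 2,
      sp = sp, elboTrace = trace, iterations = length(trace))
}
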