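#' Control parameters for the variational fitters
#'
#' @param tolerance absolute change in the monitored lower bound below which
#'   the outer cycle stops (default `1e-6`).
#' @param maxOuter cap on outer cycles.
#' @param innerTol max-norm gradient tolerance for the inner Newton cycle
#'   (Laplace only).
#' @param maxInner cap on inner Newton iterations.
#' @param nodes Gauss-Hermite nodes for Gaussian softplus expectations.
#' @return list of control values.
#' @export
vbControl <- function(tolerance = 1e-6, maxOuter = 500L, innerTol = 1e-8,
                      maxInner = 100L, nodes = 150L) {
  list(tolerance = tolerance, maxOuter = as.integer(maxOuter),
       innerTol = innerTol, maxInner = as.integer(maxInner),
       nodes = as.integer(nodes))
}

# penalized-logistic Newton block with step-halving.
# Maximizes resp' eta - wt' b(eta) - (1/2)(mu - mu0)' S0inv (mu - mu0)
# over mu, eta = Z mu. Returns mode and curvature-based covariance.
.newtonBlock <- function(mu, Z, resp, wt, mu0, S0inv, tol, maxIter) {
  obj <- function(m) {
    eta <- drop(Z %*% m)
    sum(resp * eta - wt * softplus(eta)) -
      0.5 * drop(crossprod(m - mu0, S0inv %*% (m - mu0)))
  }
  f <- obj(mu)
  Sigma <- NULL
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% mu)
    b1 <- stats::plogis(eta)
    g <- drop(crossprod(Z, resp - wt * b1)) - drop(S0inv %*% (mu - mu0))
    H <- crossprod(Z * (wt * b1 * (1 - b1)), Z) + S0inv
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) stop("non-positive-definite curvature: degenerate design")
    Sigma <- chol2inv(ch)
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    step <- drop(Sigma %*% g)
    lam <- 1
    repeat {
      f1 <- obj(mu + lam * step)
      if (f1 >= f - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    mu <- mu + lam * step
    f <- f1
  }
  list(mu = mu, Sigma = Sigma, converged = converged)
}

# per-visit Gaussian moments of the detection linear predictor under q(alpha)
.visitMoments <- function(data, muAlpha, SigmaAlpha) {
  m <- drop(data@W %*% muAlpha)
  v <- rowSums((data@W %*% SigmaAlpha) * data@W)
  list(m = m, v = pmax(v, 0))
}

# Eq-5-style conditional occupancy update: c_i = x_i mu_beta - sum_j E_q b(w_ij alpha)
.spLaplace <- function(data, muAlpha, SigmaAlpha, muBeta, nodes) {
  det <- detectedSites(data)
  mom <- .visitMoments(data, muAlpha, SigmaAlpha)
  Eb <- expectedBGaussian(mom$m, mom$v, nodes)
  ci <- drop(data@X %*% muBeta) - as.vector(rowsum(Eb, .siteIndex(data)))
  sp <- stats::plogis(ci)
  sp[det] <- 1
  sp
}

.bernEntropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log1p(-p[ok]))
  sum(h)
}

.gaussPriorTerm <- function(mu, Sigma, mu0, S0inv, logdetS0) {
  d <- length(mu)
  dev <- mu - mu0
  -0.5 * (d * log(2 * pi) + logdetS0 +
          drop(crossprod(dev, S0inv %*% dev)) + sum(S0inv * Sigma))
}

.gaussEntropy <- function(Sigma) {
  d <- nrow(Sigma)
  0.5 * (d * (1 + log(2 * pi)) + 2 * sum(log(diag(chol(Sigma)))))
}

# variational lower-bound surrogate monitored by the Laplace scheme
.elboLaplace <- function(data, prior, muAlpha, SigmaAlpha, muBeta, SigmaBeta,
                         sp, nodes, cache) {
  spTilde <- expandSiteToVisits(sp, data@K)
  momW <- .visitMoments(data, muAlpha, SigmaAlpha)
  EbW <- expectedBGaussian(momW$m, momW$v, nodes)
  mX <- drop(data@X %*% muBeta)
  vX <- pmax(rowSums((data@X %*% SigmaBeta) * data@X), 0)
  EbX <- expectedBGaussian(mX, vX, nodes)
  Edet <- sum(spTilde * (data@y * momW$m - EbW))
  Eocc <- sum(sp * mX - EbX)
  Edet + Eocc +
    .gaussPriorTerm(muAlpha, SigmaAlpha, prior@muAlpha, cache$SaInv, cache$ldSa) +
    .gaussPriorTerm(muBeta, SigmaBeta, prior@muBeta, cache$SbInv, cache$ldSb) +
    .gaussEntropy(SigmaAlpha) + .gaussEntropy(SigmaBeta) + .bernEntropy(sp)
}

.priorCache <- function(prior) {
  cha <- chol(prior@SigmaAlpha); chb <- chol(prior@SigmaBeta)
  list(SaInv = chol2inv(cha), SbInv = chol2inv(chb),
       ldSa = 2 * sum(log(diag(cha))), ldSb = 2 * sum(log(diag(chb))))
}

.initSp <- function(data) {
  det <- detectedSites(data)
  sp <- rep(max(mean(det), 1e-3), length(det))
  sp[det] <- 1
  sp
}

.fitLaplace <- function(data, prior, control) {
  cache <- .priorCache(prior)
  s <- ncol(data@W); r <- ncol(data@X)
  muAlpha <- rep(0, s); muBeta <- rep(0, r)
  SigmaAlpha <- prior@SigmaAlpha; SigmaBeta <- prior@SigmaBeta
  sp <- .initSp(data)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(control$maxOuter)) {
    spTilde <- expandSiteToVisits(sp, data@K)
    na <- .newtonBlock(muAlpha, data@W, resp = spTilde * data@y, wt = spTilde,
                       mu0 = prior@muAlpha, S0inv = cache$SaInv,
                       tol = control$innerTol, maxIter = control$maxInner)
    muAlpha <- na$mu; SigmaAlpha <- na$Sigma
    nb <- .newtonBlock(muBeta, data@X, resp = sp, wt = rep(1, length(sp)),
                       mu0 = prior@muBeta, S0inv = cache$SbInv,
                       tol = control$innerTol, maxIter = control$maxInner)
    muBeta <- nb$mu; SigmaBeta <- nb$Sigma
    sp <- .spLaplace(data, muAlpha, SigmaAlpha, muBeta, control$nodes)
    trace <- c(trace, .elboLaplace(data, prior, muAlpha, SigmaAlpha,
                                   muBeta, SigmaBeta, sp, control$nodes, cache))
    k <- length(trace)
    if (k >= 2 && abs(trace[k] - trace[k - 1]) <= control$tolerance) {
      converged <- TRUE
      break
    }
  }
  new("OccuFitVB", method = "laplace", converged = converged,
      muAlpha = muAlpha, SigmaAlpha = (SigmaAlpha + t(SigmaAlpha)) / 2,
      muBeta = muBeta, SigmaBeta = (SigmaBeta + t(SigmaBeta)) / 2,
      sp = sp, elboTrace = trace, iterations = length(trace))
}

#' Fit an occupancy model by variational Bayes
#'
#' Approximates the posterior of the single-season occupancy model with a
#' product of Gaussian factors `q(alpha) q(beta)` and independent Bernoulli
#' factors `q(z_i)`, by coordinate ascent on the variational lower bound.
#' Two schemes are available:
#'
#' * `"laplace"`: each Gaussian factor is the Laplace approximation of its
#'   optimal-density update (mode by an inner Newton cycle, covariance from
#'   the curvature at the mode); the conditional occupancy update evaluates
#'   the Gaussian expectation of the softplus by quadrature.
#' * `"tangent"`: the logistic terms are replaced by the quadratic
#'   (Jaakkola-Jordan) tangent bound, giving exact closed-form Gaussian
#'   updates plus per-row variational parameters `xi`; the monitored bound
#'   is a true lower bound and increases at every cycle.
#'
#' Both stop when the monitored bound changes by no more than
#' `control$tolerance` (default `1e-6`) between outer cycles.
#'
#' @param data an [OccupancyData-class] object.
#' @param prior a [PriorSpec-class]; default vague `N(0, 1000 I)` priors.
#' @param method `"laplace"` or `"tangent"`.
#' @param control see [vbControl()].
#' @return an [OccuFitVB-class] object.
#' @examples
#' set.seed(1)
#' sim <- genDataset(n = 60, K = 4, alpha = c(0, 1.75), beta = c(-0.1, 2.5))
#' fit <- fitOccu(sim$data, method = "laplace")
#' parameterSummary(fit)
#' @export
fitOccu <- function(data, prior = defaultPrior(data),
                    method = c("laplace", "tangent"), control = vbControl()) {
  method <- match.arg(method)
  stopifnot(is(data, "OccupancyData"), is(prior, "PriorSpec"))
  validObject(data); validObject(prior)
  fit <- switch(method,
                laplace = .fitLaplace(data, prior, control),
                tangent = .fitTangent(data, prior, control))
  if (!fit@converged)
    warning("variational fit did not reach the bound tolerance within ",
            control$maxOuter, " outer cycles")
  fit
}
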