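#' Maximum-likelihood fit of the occupancy model
#'
#' Maximizes the marginal log-likelihood (latent occupancy states summed
#' out) by BFGS from multiple starting points, and reports Wald standard
#' errors from the numerically differentiated observed information at the
#' optimum. Estimates with very large fitted linear predictors are flagged
#' as boundary solutions (the classic degeneracy where the fitted occupancy
#' probability drifts to 1 when detection is poor).
#'
#' @param data an [OccupancyData-class] object.
#' @param nStarts number of optimizer starts: the first is the zero vector,
#'   the rest are mild random perturbations (seed the RNG for
#'   reproducibility).
#' @param startSd standard deviation of the random starts.
#' @param boundaryThreshold flag the fit as boundary when any fitted
#'   `|linear predictor|` exceeds this.
#' @return an [OccuFitML-class] object.
#' @export
fitOccuMLE <- function(data, nStarts = 5L, startSd = 1.5,
                       boundaryThreshold = 15) {
  stopifnot(is(data, "OccupancyData"))
  s <- ncol(data@W); r <- ncol(data@X)
  negll <- function(theta)
    -marginalLogLik(data, theta[seq_len(s)], theta[s + seq_len(r)])
  neggr <- function(theta)
    -.marginalGrad(data, theta[seq_len(s)], theta[s + seq_len(r)])
  starts <- vector("list", nStarts)
  starts[[1]] <- rep(0, s + r)
  for (k in seq_len(nStarts - 1L))
    starts[[k + 1L]] <- stats::rnorm(s + r, 0, startSd)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, negll, neggr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  alpha <- theta[seq_len(s)]; beta <- theta[s + seq_len(r)]
  H <- stats::optimHess(theta, negll)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  seAvailable <- !is.null(ch)
  V <- if (seAvailable) chol2inv(ch) else matrix(NA_real_, s + r, s + r)
  eta <- c(drop(data@W %*% alpha), drop(data@X %*% beta))
  names(alpha) <- paste0("alpha", seq_len(s) - 1L)
  names(beta) <- paste0("beta", seq_len(r) - 1L)
  new("OccuFitML", method = "mle", converged = best$convergence == 0,
      alpha = alpha, beta = beta, vcov = V, logLik = -best$value,
      boundary = max(abs(eta)) > boundaryThreshold, seAvailable = seAvailable)
}
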