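#' L1 accuracy of a Gaussian approximation against posterior draws
#'
#' `acc = 1 - (1/2) * integral |q(x) - qref(x)| dx`, where `q` is the
#' Gaussian variational marginal and `qref` a kernel-density estimate of the
#' reference (MCMC) draws. 1 means the densities coincide; values near 0
#' mean essentially disjoint support. The KDE uses a Gaussian kernel with
#' Silverman's bandwidth, evaluated on a common grid spanning both
#' distributions by 5 standard deviations; the L1 integral is trapezoidal
#' and the result is clipped to `[0, 1]`.
#'
#' @param vbMean,vbSd mean and standard deviation of the Gaussian marginal
#'   (`vbSd > 0`).
#' @param draws reference sample (non-degenerate; at least 1000 draws are
#'   recommended for a stable estimate).
#' @param gridPoints grid resolution (default 2048).
#' @param bw kernel bandwidth; default Silverman's rule-of-thumb.
#' @return scalar accuracy in `[0, 1]`.
#' @examples
#' acc <- accStat(0, 1, rnorm(5000))
#' @export
accStat <- function(vbMean, vbSd, draws, gridPoints = 2048L, bw = NULL) {
  if (vbSd <= 0) stop("vbSd must be positive")
  sdd <- stats::sd(draws)
  if (!is.finite(sdd) || sdd == 0) stop("draws are degenerate")
  if (is.null(bw)) bw <- stats::bw.nrd0(draws)
  lo <- min(vbMean - 5 * vbSd, mean(draws) - 5 * sdd)
  hi <- max(vbMean + 5 * vbSd, mean(draws) + 5 * sdd)
  kde <- stats::density(draws, bw = bw, kernel = "gaussian",
                        from = lo, to = hi, n = gridPoints)
  qvb <- stats::dnorm(kde$x, vbMean, vbSd)
  l1 <- pracma::trapz(kde$x, abs(qvb - kde$y))
  min(max(1 - l1 / 2, 0), 1)
}

#' Coverage and median width of interval estimates over replicates
#'
#' @param fits list of `parameterSummary()` data frames (one per replicate;
#'   all sharing the same parameter order).
#' @param truth named or ordered numeric vector of generating parameter
#'   values.
#' @return data.frame with per-parameter `coverage`, `medianWidth`, and the
#'   number of replicates with usable (finite) intervals.
#' @export
intervalSummary <- function(fits, truth) {
  if (length(fits) == 0L) stop("no fits supplied")
  pars <- fits[[1]]$parameter
  lower <- vapply(fits, function(f) f$lower, numeric(length(pars)))
  upper <- vapply(fits, function(f) f$upper, numeric(length(pars)))
  lower <- matrix(lower, nrow = length(pars))
  upper <- matrix(upper, nrow = length(pars))
  ok <- is.finite(lower) & is.finite(upper)
  cov <- wid <- nUsed <- numeric(length(pars))
  for (j in seq_along(pars)) {
    use <- ok[j, ]
    nUsed[j] <- sum(use)
    cov[j] <- mean(lower[j, use] <= truth[j] & truth[j] <= upper[j, use])
    wid[j] <- stats::median(upper[j, use] - lower[j, use])
  }
  data.frame(parameter = pars, coverage = cov, medianWidth = wid, n = nUsed)
}

#' Posterior-predictive distribution of the occupied-site count
#'
#' Draws the number of occupied sites by sampling each latent state
#' independently from its variational Bernoulli factor: detected sites
#' contribute 1 deterministically, undetected sites are
#' `Bernoulli(sp_i)`. Divide by `n` for the PAO proportion.
#'
#' @param fit an [OccuFitVB-class] object.
#' @param data the [OccupancyData-class] the model was fitted to.
#' @param nDraws number of predictive draws (default 10000).
#' @param seed optional RNG seed.
#' @return a [PaoSample-class] object.
#' @export
paoPredictive <- function(fit, data, nDraws = 10000L, seed = NULL) {
  if (nDraws < 1L) stop("nDraws must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  det <- detectedSites(data)
  m <- sum(det)
  spU <- fit@sp[!det]
  draws <- if (length(spU)) {
    zmat <- matrix(stats::rbinom(length(spU) * nDraws, 1L, spU),
                   nrow = length(spU))
    m + colSums(zmat)
  } else rep(m, nDraws)
  new("PaoSample", draws = as.numeric(draws), n = length(det),
      nDetected = as.integer(m))
}

#' @rdname paoPredictive
#' @param mcmcFit an [OccuFitMCMC-class] object with stored latent-state
#'   draws; each retained iteration contributes `sum_i z_i`.
#' @export
paoPredictiveMcmc <- function(mcmcFit, data) {
  if (nrow(mcmcFit@zDraws) == 0L) stop("latent-state draws were not stored")
  det <- detectedSites(data)
  new("PaoSample", draws = as.numeric(rowSums(mcmcFit@zDraws)),
      n = length(det), nDetected = as.integer(sum(det)))
}

#' Summary table of a PAO predictive sample
#'
#' @param pao a [PaoSample-class] object.
#' @return one-row data.frame with columns `Mean`, `Std`, `Median`,
#'   `Q2.5`, `Q97.5`.
#' @export
paoSummary <- function(pao) {
  q <- stats::quantile(pao@draws, c(0.025, 0.5, 0.975))
  data.frame(Mean = mean(pao@draws), Std = stats::sd(pao@draws),
             Median = q[[2]], Q2.5 = q[[1]], Q97.5 = q[[3]])
}

setMethod("show", "PaoSample", function(object) {
  cat(sprintf("PAO predictive sample: %d draws, %d sites (%d detected)\n",
              length(object@draws), object@n, object@nDetected))
  print(paoSummary(object), digits = 4, row.names = FALSE)
})
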