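#' Coefficient combinations of the simulation study
#'
#' The four (alpha, beta) pairs used throughout the simulation design. With
#' standardized covariates they give approximate average (detection,
#' occupancy) probabilities of (0.5, 0.3), (0.7, 0.3), (0.5, 0.5) and
#' (0.5, 0.7) respectively.
#'
#' @param combo combination index 1-4.
#' @return list with `alpha` and `beta`.
#' @export
simCombo <- function(combo) {
  combos <- list(
    list(alpha = c(0, 1.75),    beta = c(-1.85, 2.5)),
    list(alpha = c(1.35, 1.75), beta = c(-1.85, 2.5)),
    list(alpha = c(0, 1.75),    beta = c(-0.1, 2.5)),
    list(alpha = c(1.35, 1.75), beta = c(-0.1, 2.5))
  )
  if (!combo %in% 1:4) stop("combo must be in 1:4")
  combos[[combo]]
}

#' The 32-cell simulation design
#'
#' All combinations of `n` in \{50, 100\}, `K` in \{2, 3, 4, 5\} and the four
#' coefficient combinations.
#'
#' @return data.frame with columns `n`, `K`, `combo`.
#' @export
simDesign <- function() {
  expand.grid(n = c(50L, 100L), K = 2:5, combo = 1:4,
              KEEP.OUT.ATTRS = FALSE)
}

#' Generate standardized covariates for a simulated dataset
#'
#' The occupancy covariate is a standardized Uniform(-2, 2) draw per site;
#' the detection covariate a standardized Uniform(-5, 5) draw per visit row.
#' Both are standardized to sample mean 0 and sample standard deviation 1,
#' and an intercept column is prepended.
#'
#' @param n number of sites (at least 2, or standardization is undefined).
#' @param K visits per site: a scalar or a length-`n` vector.
#' @return list with design matrices `X` (`n x 2`) and `W` (`sum(K) x 2`).
#' @export
genCovariates <- function(n, K) {
  if (n < 2) stop("n must be at least 2")
  K <- as.integer(if (length(K) == 1L) rep(K, n) else K)
  N <- sum(K)
  xo <- scale(stats::runif(n, -2, 2))
  xd <- scale(stats::runif(N, -5, 5))
  list(X = cbind(1, drop(xo)), W = cbind(1, drop(xd)), K = K)
}

#' Simulate a dataset from the single-season occupancy model
#'
#' Draws covariates via [genCovariates()], then
#' `z_i ~ Bernoulli(psi_i)` and `y_ij | z_i ~ Bernoulli(z_i d_ij)` under the
#' logistic links at the supplied coefficients.
#'
#' @param n number of sites.
#' @param K visits per site (scalar or vector).
#' @param alpha,beta generating coefficients (intercept and slope each).
#' @param combo alternatively, a combination index 1-4 (see [simCombo()]).
#' @return list with the [OccupancyData-class] object (`data`) and the
#'   generating truth: `z`, `psi`, `d`, `alpha`, `beta`.
#' @export
genDataset <- function(n, K, alpha = NULL, beta = NULL, combo = NULL) {
  if (!is.null(combo)) {
    cb <- simCombo(combo); alpha <- cb$alpha; beta <- cb$beta
  }
  cov <- genCovariates(n, K)
  psi <- stats::plogis(drop(cov$X %*% beta))
  d <- stats::plogis(drop(cov$W %*% alpha))
  z <- stats::rbinom(n, 1L, psi)
  zt <- expandSiteToVisits(z, cov$K)
  y <- stats::rbinom(sum(cov$K), 1L, zt * d)
  list(data = occuData(y = y, K = cov$K, W = cov$W, X = cov$X),
       z = z, psi = psi, d = d, alpha = alpha, beta = beta)
}

#' Deterministic per-replicate seed stream
#'
#' A pure function of the base seed, design-cell index and replicate index,
#' kept below 2^31 so it is a valid R integer seed.
#'
#' @param baseSeed integer base seed.
#' @param cell design-cell index.
#' @param rep replicate index.
#' @return integer seed.
#' @export
replicateSeed <- function(baseSeed, cell, rep) {
  as.integer((as.double(baseSeed) * 100003 + cell * 10007 + rep * 101) %%
               2147483629)
}

# fit one replicate with one method; returns parameterSummary or NULL on
# failure; warnings (e.g. a non-converged VB fit) are muffled, the summary
# is still usable
.fitOne <- function(method, data, prior, level, mcmc) {
  tryCatch(
    withCallingHandlers({
      fit <- switch(method,
        laplace = fitOccu(data, prior, method = "laplace"),
        tangent = fitOccu(data, prior, method = "tangent"),
        mle = fitOccuMLE(data),
        mcmc = fitOccuMCMC(data, prior, nIter = mcmc$nIter,
                           nBurnin = mcmc$nBurnin, storeZ = FALSE),
        stop("unknown method: ", method))
      parameterSummary(fit, level = level)
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
}

#' Run a replicated simulation study
#'
#' For each requested design cell and fitter: simulate `replicates`
#' datasets, fit, and summarize per-parameter interval coverage and median
#' width against the generating coefficients. Replicate seeds derive
#' deterministically from `baseSeed`, so identical inputs give identical
#' tables. Fitter failures are recorded and the replicate excluded for that
#' fitter, never fatal.
#'
#' @param cells data.frame with columns `n`, `K`, `combo` (see
#'   [simDesign()] for the full grid).
#' @param methods character vector from "laplace", "tangent", "mle", "mcmc".
#' @param replicates replicates per cell.
#' @param baseSeed integer base seed.
#' @param level interval level.
#' @param priorVariance prior variance per coefficient for the Bayesian
#'   fitters.
#' @param mcmcIter,mcmcBurnin chain settings when "mcmc" is among the
#'   methods (defaults are desk-scale, far below the full-study settings).
#' @return data.frame with one row per (cell, method, parameter):
#'   `n`, `K`, `combo`, `method`, `parameter`, `coverage`, `medianWidth`,
#'   `nFitted`, `nFailed`.
#' @export
runStudy <- function(cells, methods = c("laplace", "mle"), replicates = 50L,
                     baseSeed = 1L, level = 0.95, priorVariance = 1000,
                     mcmcIter = 8000L, mcmcBurnin = 2000L) {
  stopifnot(all(c("n", "K", "combo") %in% names(cells)))
  mcmc <- list(nIter = mcmcIter, nBurnin = mcmcBurnin)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; K <- cells$K[ci]; combo <- cells$combo[ci]
    cb <- simCombo(combo)
    truth <- c(cb$alpha, cb$beta)
    sums <- stats::setNames(vector("list", length(methods)), methods)
    fails <- stats::setNames(integer(length(methods)), methods)
    for (rep in seq_len(replicates)) {
      set.seed(replicateSeed(baseSeed, ci, rep))
      sim <- genDataset(n, K, combo = combo)
      prior <- defaultPrior(sim$data, variance = priorVariance)
      for (m in methods) {
        ps <- .fitOne(m, sim$data, prior, level, mcmc)
        if (is.null(ps)) fails[m] <- fails[m] + 1L
        else sums[[m]] <- c(sums[[m]], list(ps))
      }
    }
    for (m in methods) {
      if (length(sums[[m]]) == 0L) next
      isum <- intervalSummary(sums[[m]], truth)
      out[[length(out) + 1L]] <- data.frame(
        n = n, K = K, combo = combo, method = m,
        parameter = isum$parameter, coverage = isum$coverage,
        medianWidth = isum$medianWidth, nFitted = isum$n,
        nFailed = fails[m], row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Median coverage and width across coefficient combinations
#'
#' Aggregates [runStudy()] output the way the study tables are laid out:
#' for fixed `(n, K)`, method and parameter, the median of the per-combo
#' coverage values and median widths across the four combinations.
#'
#' @param study output of [runStudy()].
#' @return data.frame with `n`, `K`, `method`, `parameter`,
#'   `medianCoverage`, `medianWidth`.
#' @export
studyMedians <- function(study) {
  agg <- stats::aggregate(cbind(coverage, medianWidth) ~
                            n + K + method + parameter,
                          data = study, FUN = stats::median)
  names(agg)[names(agg) == "coverage"] <- "medianCoverage"
  agg[order(agg$n, agg$K, agg$method, agg$parameter), , drop = FALSE]
}
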