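.paramNames <- function(s, r)
  c(paste0("alpha", seq_len(s) - 1L), paste0("beta", seq_len(r) - 1L))

#' @describeIn parameterSummary Gaussian equal-tailed credible intervals,
#'   `mu +/- z * sqrt(diag(Sigma))`.
#' @export
setMethod("parameterSummary", "OccuFitVB", function(object, level = 0.95) {
  est <- c(object@muAlpha, object@muBeta)
  se <- sqrt(c(diag(object@SigmaAlpha), diag(object@SigmaBeta)))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(parameter = .paramNames(length(object@muAlpha),
                                     length(object@muBeta)),
             estimate = est, se = se,
             lower = est - zq * se, upper = est + zq * se)
})

#' @describeIn parameterSummary Wald confidence intervals from the observed
#'   information; `se`/bounds are `NA` when the Hessian was not PD.
#' @export
setMethod("parameterSummary", "OccuFitML", function(object, level = 0.95) {
  est <- c(object@alpha, object@beta)
  se <- sqrt(diag(object@vcov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(parameter = .paramNames(length(object@alpha), length(object@beta)),
             estimate = unname(est), se = se,
             lower = unname(est) - zq * se, upper = unname(est) + zq * se)
})

#' @describeIn parameterSummary posterior means, SDs and equal-tailed
#'   quantile intervals from the retained draws.
#' @export
setMethod("parameterSummary", "OccuFitMCMC", function(object, level = 0.95) {
  draws <- cbind(object@alphaDraws, object@betaDraws)
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
  data.frame(parameter = colnames(draws),
             estimate = colMeans(draws), se = apply(draws, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
})

#' @describeIn conditionalOccupancy the variational Bernoulli probabilities
#'   `sp`.
#' @export
setMethod("conditionalOccupancy", "OccuFitVB", function(object, ...) object@sp)

#' @describeIn conditionalOccupancy posterior mean of the latent-state draws
#'   (requires `storeZ = TRUE`).
#' @export
setMethod("conditionalOccupancy", "OccuFitMCMC", function(object, ...) {
  if (nrow(object@zDraws) == 0L) stop("latent-state draws were not stored")
  colMeans(object@zDraws)
})

setMethod("show", "OccuFitVB", function(object) {
  cat(sprintf("Variational occupancy fit (%s), %d outer cycles, converged: %s\n",
              object@method, object@iterations, object@converged))
  print(parameterSummary(object), digits = 4)
  cat("final bound:", format(utils::tail(object@elboTrace, 1), digits = 8), "\n")
})

setMethod("show", "OccuFitML", function(object) {
  cat("Maximum-likelihood occupancy fit; logLik =",
      format(object@logLik, digits = 7), "\n")
  if (object@boundary) cat("  note: boundary estimate flagged\n")
  print(parameterSummary(object), digits = 4)
})

setMethod("show", "OccuFitMCMC", function(object) {
  cat(sprintf("MCMC occupancy fit: %d retained draws (burn-in %d), accept %.2f/%.2f\n",
              nrow(object@alphaDraws), object@nBurnin,
              object@accept[1], object@accept[2]))
  print(parameterSummary(object), digits = 4)
})

#' Serialize a fitted occupancy model to JSON
#'
#' A schema shared by all four fitters (method, parameter table, convergence
#' flag), so downstream tooling can consume any of them interchangeably.
#'
#' @param fit a fitted model object.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
writeFitJson <- function(fit, path = NULL) {
  obj <- list(method = fit@method, converged = fit@converged,
              parameters = parameterSummary(fit))
  if (is(fit, "OccuFitVB")) {
    obj$sp <- fit@sp
    obj$elbo <- utils::tail(fit@elboTrace, 1)
    obj$iterations <- fit@iterations
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
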