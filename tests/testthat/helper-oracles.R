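# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths: plain products, exhaustive
# enumeration, and dense grids.

# term-by-term product evaluation of p(y, z | alpha, beta)
bruteJointLogLik <- function(data, z, alpha, beta) {
  W <- detectionDesign(data); X <- occupancyDesign(data)
  K <- visitCounts(data); yl <- detectionHistory(data)
  total <- 0
  row <- 0L
  for (i in seq_along(K)) {
    psi <- 1 / (1 + exp(-sum(X[i, ] * beta)))
    total <- total + log(ifelse(z[i] == 1, psi, 1 - psi))
    for (j in seq_len(K[i])) {
      row <- row + 1L
      d <- 1 / (1 + exp(-sum(W[row, ] * alpha)))
      pr <- z[i] * d
      lik <- ifelse(yl[[i]][j] == 1, pr, 1 - pr)
      total <- total + log(lik)
    }
  }
  total
}

# exhaustive sum over all admissible latent-state completions
bruteMarginalLogLik <- function(data, alpha, beta) {
  det <- detectedSites(data)
  free <- which(!det)
  n <- nSites(data)
  zBase <- as.numeric(det)
  tot <- -Inf
  for (mask in 0:(2^length(free) - 1)) {
    z <- zBase
    if (length(free))
      z[free] <- as.numeric(bitwAnd(mask, 2^(seq_along(free) - 1)) > 0)
    lj <- bruteJointLogLik(data, z, alpha, beta)
    m <- max(tot, lj)
    if (is.finite(m)) tot <- m + log(exp(tot - m) + exp(lj - m))
  }
  tot
}

# intercept-only dataset: detection counts per site at constant K
interceptOnlyData <- function(y, K) {
  n <- length(K)
  occuData(y = y, K = K, W = matrix(1, sum(K), 1), X = matrix(1, n, 1))
}

# dense-grid posterior for the intercept-only model with N(0, sd0^2) priors;
# returns posterior means of (alpha, beta) and the log evidence
gridPosteriorInterceptOnly <- function(data, sd0 = 2, lim = 8, step = 0.02) {
  K <- visitCounts(data)
  si <- vapply(detectionHistory(data), sum, numeric(1))  # detections per site
  a <- seq(-lim, lim, by = step)
  b <- seq(-lim, lim, by = step)
  d <- 1 / (1 + exp(-a))                 # detection prob per alpha grid point
  psi <- 1 / (1 + exp(-b))               # occupancy prob per beta grid point
  # site likelihood: psi * d^s (1-d)^(K-s) + (1-psi) * 1{s == 0}
  logLikA <- matrix(0, length(a), length(b))
  for (i in seq_along(K)) {
    pz1 <- d^si[i] * (1 - d)^(K[i] - si[i])
    lik <- outer(pz1, psi) + outer(rep(si[i] == 0, length(a)), 1 - psi)
    logLikA <- logLikA + log(lik)
  }
  logPost <- logLikA + dnorm(a, 0, sd0, log = TRUE) +
    rep(dnorm(b, 0, sd0, log = TRUE), each = length(a))
  w <- exp(logPost - max(logPost))
  Z <- sum(w)
  list(meanAlpha = sum(rowSums(w) * a) / Z,
       meanBeta = sum(colSums(w) * b) / Z,
       logEvidence = max(logPost) + log(Z * step^2))
}

# crude effective sample size from the autocorrelation function
essDraws <- function(x, maxLag = 200L) {
  ac <- acf(x, lag.max = maxLag, plot = FALSE)$acf[-1]
  pos <- ac[seq_len(max(1, which(ac < 0.05)[1] - 1))]
  length(x) / (1 + 2 * sum(pos))
}

# deterministic small simulated dataset under study-style conditions
studyDataset <- function(seed, n = 50, K = 3, combo = 1) {
  set.seed(seed)
  genDataset(n, K, combo = combo)
}
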