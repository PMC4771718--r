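test_that("Gaussian softplus expectation matches high-resolution integration", {
  expect_equal(expectedBGaussian(1.3, 0), softplus(1.3))
  # Jensen: E b >= b(m) for b convex
  set.seed(1)
  m <- rnorm(20, 0, 2); v <- rexp(20)
  expect_true(all(expectedBGaussian(m, v) >= softplus(m)))
  for (case in list(c(0, 4), c(-2, 1), c(3, 0.25), c(1, 9))) {
    ref <- integrate(function(u) softplus(u) * dnorm(u, case[1], sqrt(case[2])),
                     -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(expectedBGaussian(case[1], case[2]), ref, tolerance = 1e-8)
  }
  expect_error(expectedBGaussian(0, -1), "non-negative")
})

test_that("inner Newton reproduces penalized logistic solutions", {
  # scalar intercept-only problem: root of g1 = 0 found by bisection
  d <- interceptOnlyData(y = c(1, 0, 1, 1, 0), K = rep(1L, 5))
  spT <- rep(1, 5)
  g1 <- function(mu) sum(spT * d@y - spT * plogis(mu)) - mu / 1000
  root <- uniroot(g1, c(-10, 10), tol = 1e-12)$root
  nb <- occuVB:::.newtonBlock(0, d@W, resp = spT * d@y, wt = spT,
                              mu0 = 0, S0inv = matrix(1 / 1000),
                              tol = 1e-10, maxIter = 100)
  expect_equal(drop(nb$mu), root, tolerance = 1e-8)
  expect_true(nb$converged)
  # stationary point is a fixed point
  nb2 <- occuVB:::.newtonBlock(nb$mu, d@W, resp = spT * d@y, wt = spT,
                               mu0 = 0, S0inv = matrix(1 / 1000),
                               tol = 1e-10, maxIter = 100)
  expect_equal(nb2$mu, nb$mu, tolerance = 1e-10)
})

test_that("all-detected data reduce to Laplace Bayesian logistic regression", {
  # every site detected every visit: the occupancy factor is the Laplace
  # approximation of logistic regression with all-ones response + prior.
  set.seed(8)
  X <- cbind(1, rnorm(40))
  d <- occuData(y = rep(1, 80), K = rep(2L, 40), W = cbind(1, rnorm(80)), X = X)
  fit <- fitOccu(d, prior = defaultPrior(d, variance = 4), method = "laplace")
  expect_equal(unname(fit@sp), rep(1, 40))
  pen <- function(b) sum(drop(X %*% b) - softplus(drop(X %*% b))) -
    sum(b^2) / (2 * 4)
  opt <- optim(c(0, 0), pen, control = list(fnscale = -1, reltol = 1e-14))
  expect_equal(fit@muBeta, opt$par, tolerance = 1e-5)
  H <- -pracma::hessian(pen, opt$par)
  expect_equal(fit@SigmaBeta, solve(H), tolerance = 1e-4)
})

test_that("conditional occupancy recovers the exact Bayes rule at degenerate q", {
  # psi = d = 0.5, K = 1, no detection: P(z=1|y=0) = 1/3
  d <- interceptOnlyData(y = 0, K = 1L)
  sp <- occuVB:::.spLaplace(d, muAlpha = 0, SigmaAlpha = matrix(0),
                            muBeta = 0, nodes = 30L)
  expect_equal(sp, 1 / 3, tolerance = 1e-12)
  # general known parameters, several visits and covariates
  set.seed(2)
  sim <- genDataset(30, 3, combo = 1)
  a <- sim$alpha; b <- sim$beta
  sp <- occuVB:::.spLaplace(sim$data, a, diag(0, 2), b, 30L)
  pr <- linkProbs(sim$data, a, b)
  prodMiss <- as.numeric(tapply(1 - pr$d, rep(seq_len(30), visitCounts(sim$data)), prod))
  exact <- pr$psi * prodMiss / (pr$psi * prodMiss + 1 - pr$psi)
  und <- !detectedSites(sim$data)
  expect_equal(unname(sp[und]), exact[und], tolerance = 1e-12)
  expect_equal(unname(sp[!und]), rep(1, sum(!und)))
})

test_that("entropy terms of the bound take their closed-form values", {
  expect_equal(occuVB:::.bernEntropy(c(0, 1)), 0)
  expect_equal(occuVB:::.bernEntropy(0.5), log(2))
  expect_equal(occuVB:::.gaussEntropy(diag(2)), 1 + log(2 * pi))
})

test_that("the monitored bound never exceeds the exhaustively computed evidence", {
  set.seed(21)
  for (rep in 1:4) {
    y <- rbinom(12, 1, 0.4)
    d <- interceptOnlyData(y = y, K = rep(2L, 6))
    prior <- priorSpec(0, matrix(4), 0, matrix(4))
    ev <- gridPosteriorInterceptOnly(d, sd0 = 2)$logEvidence
    fl <- suppressWarnings(fitOccu(d, prior, method = "laplace"))
    ft <- suppressWarnings(fitOccu(d, prior, method = "tangent"))
    expect_lt(max(fl@elboTrace), ev + 1e-6)
    expect_lt(max(ft@elboTrace), ev + 1e-6)
  }
})

test_that("Laplace fit converges with pinned detected sites and PD covariances", {
  set.seed(31)
  sim <- genDataset(100, 4, combo = 3)
  fit <- fitOccu(sim$data, method = "laplace")
  expect_true(fit@converged)
  expect_equal(unname(fit@sp[detectedSites(sim$data)]),
               rep(1, sum(detectedSites(sim$data))))
  expect_true(all(eigen(fit@SigmaAlpha, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(fit@SigmaBeta, symmetric = TRUE)$values > 0))
  # monitored bound converges: last change negligible, drops are a small
  # fraction of the total ascent (the Laplace substitution is not an exact
  # coordinate-ascent step, so exact monotonicity is not expected)
  tr <- fit@elboTrace
  expect_lt(abs(diff(tail(tr, 2))), 1e-6)
  expect_gt(min(diff(tr)), -0.05 * (max(tr) - tr[1]) - 1e-8)
})

test_that("a near-point-mass prior pins sp at the exact Bayes conditional", {
  set.seed(5)
  sim <- genDataset(25, 3, combo = 1)
  a <- sim$alpha; b <- sim$beta
  prior <- priorSpec(a, diag(1e-8, 2), b, diag(1e-8, 2))
  fit <- suppressWarnings(fitOccu(sim$data, prior, method = "laplace"))
  pr <- linkProbs(sim$data, a, b)
  prodMiss <- as.numeric(tapply(1 - pr$d, rep(seq_len(25), visitCounts(sim$data)), prod))
  exact <- pr$psi * prodMiss / (pr$psi * prodMiss + 1 - pr$psi)
  und <- !detectedSites(sim$data)
  expect_equal(unname(fit@sp[und]), exact[und], tolerance = 1e-4)
})

test_that("Laplace posterior means recover the truth on simulated data", {
  set.seed(77)
  hits <- 0L; total <- 0L
  for (rep in 1:12) {
    sim <- genDataset(400, 5, alpha = c(0, 1.75), beta = c(-0.1, 2.5))
    fit <- suppressWarnings(fitOccu(sim$data, method = "laplace"))
    ps <- parameterSummary(fit)
    truth <- c(sim$alpha, sim$beta)
    hits <- hits + sum(abs(ps$estimate - truth) <= 3 * ps$se)
    total <- total + 4L
  }
  expect_gte(hits / total, 0.9)
})
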