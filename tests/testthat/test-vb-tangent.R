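test_that("tangent-bound functions take their closed-form values", {
  expect_equal(jjLambda(0), 0.125)
  expect_equal(jjLambda(c(0.5, 3)), jjLambda(c(-0.5, -3)))      # even
  expect_equal(jjLambda(1), (plogis(1) - 0.5) / 2, tolerance = 1e-12)
  # the bound log sigma(x) >= log sigma(xi) + (x-xi)/2 - lambda(xi)(x^2-xi^2)
  # holds and is tight at x = xi
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(1, 0, 3); xi <- rnorm(1, 0, 3)
    bound <- -softplus(-xi) + (x - xi) / 2 - jjLambda(xi) * (x^2 - xi^2)
    expect_gte(-softplus(-x), bound - 1e-12)
  }
  x <- 1.7
  expect_equal(-softplus(-x), jjC(x) - x / 2 - jjLambda(x) * x^2 + x,
               tolerance = 1e-12)
})

test_that("variational parameter updates equal the root second moment", {
  mu <- c(0, 0); S <- diag(2)
  expect_equal(sqrt(occuVB:::.rowSecondMoment(rbind(c(1, 0)), mu, S)), 1)
  mu <- c(0.7, -1.2)
  expect_equal(sqrt(occuVB:::.rowSecondMoment(rbind(c(2, 1)), mu, diag(0, 2))),
               abs(sum(c(2, 1) * mu)))
  set.seed(9)
  Z <- matrix(rnorm(10), 5, 2)
  A <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
  direct <- vapply(seq_len(5), function(i)
    drop(Z[i, ] %*% (A + tcrossprod(mu)) %*% Z[i, ]), numeric(1))
  expect_equal(occuVB:::.rowSecondMoment(Z, mu, A), direct)
})

test_that("closed-form Gaussian updates solve the 1-D case by hand", {
  # single site, single visit, scalar covariate w, fixed xi and sp:
  # B1 = 1/s0 + 2 lambda(xi) sp w^2, B2 = sp (y - 1/2) w
  w <- 1.6; y <- 1; sp <- 0.8; xi <- 0.9; s0 <- 5
  B1 <- 1 / s0 + 2 * jjLambda(xi) * sp * w^2
  muHand <- (sp * (y - 0.5) * w) / B1
  d <- occuData(y = y, K = 1L, W = matrix(w), X = matrix(1))
  spT <- sp
  B1pkg <- 1 / s0 + 2 * drop(crossprod(d@W * (jjLambda(xi) * spT), d@W))
  expect_equal(B1pkg, B1)
  expect_equal(drop(crossprod(d@W, spT * (y - 0.5))) / B1pkg, muHand)
  # prior recovery: with sp = 0 weights the alpha factor returns the prior
  expect_equal(1 / (1 / s0 + 2 * drop(crossprod(d@W * (jjLambda(xi) * 0), d@W))), s0)
})

test_that("tangent conditional occupancy is tight at point-mass q", {
  # psi = d = 0.5, K = 1: with Sigma = 0 and xi = |w mu|, c reduces to
  # x mu_beta - b(w mu_alpha), giving the exact Bayes conditional 1/3
  d <- interceptOnlyData(y = 0, K = 1L)
  sp <- occuVB:::.spTangent(d, muAlpha = 0, SigmaAlpha = matrix(0),
                            muBeta = 0, xiDet = 0)
  expect_equal(sp, 1 / 3, tolerance = 1e-12)
  # nonzero parameters: still exact when the bound is tight
  sp2 <- occuVB:::.spTangent(d, muAlpha = 0.8, SigmaAlpha = matrix(0),
                             muBeta = -0.3, xiDet = 0.8)
  expect_equal(sp2, plogis(-0.3 - softplus(0.8)), tolerance = 1e-12)
})

test_that("tangent conditional occupancy lower-bounds the Laplace one", {
  set.seed(14)
  for (rep in 1:10) {
    sim <- genDataset(20, 3, combo = sample(1:4, 1))
    mu <- rnorm(2, 0, 0.5); S <- crossprod(matrix(rnorm(4, 0, 0.4), 2)) + diag(0.05, 2)
    muB <- rnorm(2, 0, 0.5)
    xi <- sqrt(occuVB:::.rowSecondMoment(detectionDesign(sim$data), mu, S))
    spT <- occuVB:::.spTangent(sim$data, mu, S, muB, xi)
    spL <- occuVB:::.spLaplace(sim$data, mu, S, muB, 30L)
    und <- !detectedSites(sim$data)
    expect_true(all(spT[und] <= spL[und] + 1e-10))
  }
})

test_that("all-detected data match an independent tangent-EM logistic fit", {
  set.seed(16)
  X <- cbind(1, rnorm(50))
  d <- occuData(y = rep(1, 50), K = rep(1L, 50), W = cbind(1, rnorm(50)), X = X)
  fit <- fitOccu(d, prior = defaultPrior(d, variance = 9), method = "tangent",
                 control = vbControl(tolerance = 1e-12, maxOuter = 5000L))
  # independent bound-EM iteration for Bayesian logistic regression with
  # all-ones response, coded directly from the quadratic bound
  S0inv <- diag(1 / 9, 2)
  z <- rep(1, 50)
  xi <- rep(1, 50)
  m <- c(0, 0)
  repeat {
    lam <- jjLambda(xi)
    S <- solve(S0inv + 2 * t(X) %*% (X * lam))
    mNew <- drop(S %*% crossprod(X, z - 0.5))
    xi <- sqrt(rowSums((X %*% (S + tcrossprod(mNew))) * X))
    if (max(abs(mNew - m)) < 1e-12) { m <- mNew; break }
    m <- mNew
  }
  expect_equal(fit@muBeta, m, tolerance = 1e-5)
  expect_equal(fit@SigmaBeta, S, tolerance = 1e-5)
})

test_that("the tangent bound increases at every cycle and is a fixed point", {
  set.seed(23)
  for (rep in 1:6) {
    sim <- genDataset(sample(c(50, 100), 1), sample(2:5, 1),
                      combo = sample(1:4, 1))
    fit <- suppressWarnings(fitOccu(sim$data, method = "tangent"))
    expect_true(all(diff(fit@elboTrace) >= -1e-10))
  }
  sim <- genDataset(60, 4, combo = 3)
  f1 <- fitOccu(sim$data, method = "tangent")
  # rerunning coordinate updates from the converged state barely moves it
  f2 <- fitOccu(sim$data, method = "tangent",
                control = vbControl(maxOuter = f1@iterations + 3L))
  expect_equal(f1@muAlpha, f2@muAlpha, tolerance = 1e-6)
  expect_equal(f1@muBeta, f2@muBeta, tolerance = 1e-6)
})

test_that("tangent covariances never exceed the prior in the Loewner order", {
  set.seed(29)
  sim <- genDataset(40, 3, combo = 2)
  prior <- defaultPrior(sim$data, variance = 50)
  fit <- suppressWarnings(fitOccu(sim$data, prior, method = "tangent"))
  expect_true(all(eigen(prior@SigmaAlpha - fit@SigmaAlpha,
                        symmetric = TRUE)$values > -1e-8))
  expect_true(all(eigen(prior@SigmaBeta - fit@SigmaBeta,
                        symmetric = TRUE)$values > -1e-8))
})
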