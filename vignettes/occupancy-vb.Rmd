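---
title: "Variational inference for single-season occupancy models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational inference for single-season occupancy models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuVB)
```

## The model and its variational treatment

A single-season occupancy survey visits $n$ sites, site $i$ receiving $K_i$
visits ($N = \sum_i K_i$ visit rows in total). The latent occupancy state
$z_i$ and the detections $y_{ij}$ follow

$$z_i \sim \mathrm{Bernoulli}(\psi_i), \qquad
  y_{ij} \mid z_i \sim \mathrm{Bernoulli}(z_i\, d_{ij}),$$

with logistic regressions $\operatorname{logit}\psi_i = x_i\beta$ on site
covariates and $\operatorname{logit} d_{ij} = w_{ij}\alpha$ on visit
covariates, and independent Gaussian priors on $\alpha$ and $\beta$. False
positives are excluded, so any detection at a site fixes $z_i = 1$; only
the undetected sites carry posterior uncertainty about occupancy.

The posterior $p(\alpha, \beta, z \mid y)$ is approximated by a factorized
density $q(\alpha)\,q(\beta)\prod_i q(z_i)$, chosen to maximize the
evidence lower bound
$\mathcal{L}(q) = \mathbb{E}_q\!\left[\log p(y, z, \alpha, \beta) - \log q\right]$.
The Bernoulli factors have success probabilities $sp_i$ (the *conditional
occupancy probabilities*); coordinate ascent alternates between updating
the Gaussian factors given $sp$ and updating $sp$ given the Gaussians. The
difficulty is the softplus term $b(x) = \log(1 + e^x)$, whose Gaussian
expectation has no closed form. The two fitters differ exactly there.

### The Laplace scheme

Given $sp$, the optimal $q(\alpha)$ is proportional to
$\exp\{y^\top \tilde P W \alpha - \tilde p^\top b(W\alpha) + \log \pi(\alpha)\}$,
where $\tilde p$ expands $sp$ to visit rows and $\tilde P =
\operatorname{diag}(\tilde p)$; the $\beta$ factor is analogous with the
site-level $p = sp$. These densities are not of a standard family, so each
is replaced by its Laplace approximation: an inner Newton cycle (with
step-halving on the penalized objective and a $10^{-8}$ max-norm gradient
tolerance, capped at 100 iterations) finds the mode, and the covariance is
the inverse curvature there. The conditional-occupancy update for an
undetected site is

$$c_i = x_i \mu_\beta - \sum_{j=1}^{K_i} \mathbb{E}_{q(\alpha)}
  b(w_{ij}\alpha), \qquad sp_i = \operatorname{logit}^{-1}(c_i),$$

with the expectation taken under the univariate projection
$w_{ij}\alpha \sim N(w_{ij}\mu_\alpha,\, w_{ij}\Sigma_\alpha w_{ij}^\top)$
and evaluated by Gauss–Hermite quadrature.

### The tangent scheme

Every logistic likelihood term is bounded below via
$\log\sigma(x) \ge \log\sigma(\xi) + (x-\xi)/2 - \lambda(\xi)(x^2 - \xi^2)$
with $\lambda(\xi) = \tanh(\xi/2)/(4\xi)$ ($\lambda(0) = 1/8$). The bound
is quadratic in the coefficients, so given the variational parameters $\xi$
(one per visit row for the detection side, one per site for the occupancy
side) the Gaussian updates are exact one-step solves:
$\Sigma_\alpha = B_1^{-1}$, $\mu_\alpha = B_1^{-1}B_2^\top$ with
$B_1 = \Sigma_{\alpha 0}^{-1} + 2\,W^\top\!\operatorname{diag}(\lambda(\xi)
\odot \tilde p)\,W$ and
$B_2 = (\tilde P y - \tfrac12 \tilde p)^\top W + \mu_{\alpha 0}^\top
\Sigma_{\alpha 0}^{-1}$, and analogously $D_1, D_2$ for $\beta$. The
optimal variational parameters equal the root second moment of the linear
predictor, $\xi^2 = \mathbb{E}_q[(w\alpha)^2]$, which also makes the bound
tight at a point-mass $q$ — the property the test suite uses to check the
reconstruction against the exact Bayes conditional
$sp_i = \psi_i\prod_j(1-d_{ij}) / \{\psi_i\prod_j(1-d_{ij}) + 1-\psi_i\}$.

Because the $sp$ update, the Gaussian solves and the $\xi$ updates each
exactly maximize the same bound in their own coordinates, the monitored
tangent bound increases at every cycle; any decrease is a bug and the
tests treat it as such.

### Monitoring and convergence

Both fitters monitor the bound surrogate
$\mathbb{E}_q \log p(y, z, \alpha, \beta) - \mathbb{E}_q\log q$ after each
outer cycle and stop when its absolute change is at most `tolerance`
(default $10^{-6}$, cap 500 cycles). For the Laplace scheme this surrogate
uses quadrature for every Gaussian softplus expectation and is a genuine
lower bound on the log evidence at the current $q$ — the test suite
verifies it never exceeds an exhaustively computed evidence on small
problems. It is, however, *not* guaranteed to increase monotonically: the
Laplace mode/curvature pair is not the bound-optimal Gaussian factor, and
on datasets with weak information (few visits, near-separation) the bound
can drop by more than rounding error between cycles before settling.
Numerical experiments against directly optimized Gaussian factors show
gaps of order $10^{-2}$ on routine datasets, so the package treats
"negligible change", not monotonicity, as the Laplace stopping rule, and
only the tangent bound is asserted monotone.

## Numerical choices

* **Gaussian softplus expectations.** 150-node Gauss–Hermite quadrature on
  the univariate projection (`expectedBGaussian()`). The integrand is
  analytic but its poles at $\pm i\pi$ slow the geometric convergence;
  150 nodes keep the relative error below $10^{-9}$ for variances up to
  ~16, far beyond the curvature-scale variances a fit produces, at
  negligible cost (one `N x nodes` matrix per cycle). The node count is a
  `vbControl()` knob.
* **Initialization.** $\mu = 0$, $\Sigma$ = prior covariance, $sp_i = 1$
  for detected sites and the observed detected-site proportion otherwise;
  tangent $\xi \equiv 1$ (any positive value works; one is scale-neutral
  for standardized covariates).
* **Degenerate inputs.** Impossible configurations ($z_i = 0$ with a
  detection) yield $-\infty$ from `jointLogLik` so samplers and optimizers
  can reject; constructors and readers raise instead. Non-positive-definite
  curvature (collinear designs) is a hard error.
* **Intervals.** VB intervals are Gaussian equal-tailed
  $\mu \pm z_{0.975}\sqrt{\operatorname{diag}\Sigma}$; MLE intervals are
  Wald from the numerically differentiated observed information (flagged
  unavailable if the Hessian is not positive-definite, which happens at
  boundary estimates); MCMC intervals are equal-tailed sample quantiles.

## Reference fitters

`fitOccuMLE()` maximizes the marginal likelihood (latent states summed
out, evaluated in log space with an analytic gradient) by BFGS from five
starts — zeros plus four $N(0, 1.5^2)$ perturbations. Random restarts this
mild cover the multimodality seen near boundaries; diffuse-prior-scale
starts would begin in the flat region of the likelihood where
quasi-Newton methods stall. Fits with linear predictors beyond ±15 are
flagged as boundary solutions (the familiar $\hat\psi \to 1$ degeneracy of
sparse designs).

`fitOccuMCMC()` is a data-augmentation sampler kept free of external
engines so it can serve as the in-package accuracy oracle: the latent
states are drawn exactly from
$z_i \mid \text{rest} \sim \mathrm{Bernoulli}(\operatorname{logit}^{-1}
(x_i\beta + \sum_j \log(1-d_{ij})))$ for undetected sites, and the
$\alpha$ and $\beta$ blocks use random-walk Metropolis with Robbins–Monro
scale adaptation towards 0.35 acceptance and empirical proposal
covariances re-estimated during burn-in only — the retained chain is a
fixed-kernel sample. Defaults mirror the full study settings (100000
iterations, 25000 burn-in, no thinning); the harness and tests use shorter
chains sized by their effective-sample-size needs.

## Evaluation tools

`accStat()` computes $1 - \tfrac12\int |q(x) - q_{\mathrm{MCMC}}(x)|\,dx$
between a Gaussian VB marginal and a kernel-density estimate of MCMC
draws: Gaussian kernel, Silverman bandwidth, a 2048-point grid spanning
both distributions ±5 SD, trapezoidal integration, clipped to $[0, 1]$.
The bandwidth and grid are not externally prescribed; the tests document
the choice's robustness by showing the statistic moves by < 0.02 under
±50% bandwidth changes in a Gaussian-vs-Gaussian case.

`paoPredictive()` draws the posterior-predictive number of occupied sites
by summing independent $\mathrm{Bernoulli}(sp_i)$ draws, with detected
sites contributing 1 deterministically — draws are therefore bounded below
by the observed detected-site count, matching the no-false-positive
assumption. Counts are reported rather than proportions (divide by $n$ for
the PAO proportion). The default 10000 draws put the Monte-Carlo SE of the
mean below 0.03 sites at survey sizes of interest.

## The synthetic-data generator and study harness

`genDataset()` emulates a standardized-covariate design: the occupancy
covariate standardizes a per-site Uniform(−2, 2) draw, the detection
covariate a per-visit Uniform(−5, 5) draw (both to sample mean 0, SD 1,
intercepts prepended), then $z$ and $y$ are drawn from the hierarchical
model. Four coefficient combinations are built in (`simCombo()`),
producing average (detection, occupancy) probabilities of approximately
(0.5, 0.3), (0.7, 0.3), (0.5, 0.5) and (0.7, 0.5); with
`n ∈ {50, 100}` and `K ∈ {2, 3, 4, 5}` they form the 32-cell design of
`simDesign()`. Covariates are redrawn each replicate — the standard choice
when studying frequentist properties of interval estimators — and every
replicate's seed is a pure function of the base seed (`replicateSeed()`),
so `runStudy()` tables are bit-reproducible. Per-cell coverage and median
interval widths are aggregated across the four combinations by medians
(`studyMedians()`), the layout used for reporting.

What the generator does *not* emulate: spatial or temporal correlation,
visit-level heterogeneity beyond one covariate, covariate measurement
error, or false positives. Passing recovery and coverage tests under this
design therefore demonstrates correctness of the inference machinery under
the model's own assumptions, not robustness to their violation.

Problem sizes in the tests and the reproduction script are deliberate
package choices balancing Monte-Carlo error against desk-scale runtimes:
table cells use the full 350 replicates (coverage SE ≈ 0.012); PAO cells
average 100 replicate fits; accuracy-versus-MCMC cells use 20 replicates
with 16000-iteration chains, which split-half checks show are converged
for these smooth two-parameter blocks.

## Known limitations

* The tangent scheme's closed-form covariances are systematically too
  small: its intervals undercover (the tests assert only the qualitative
  width ordering against the Laplace scheme). It remains useful as a fast
  initializer or where only posterior means are needed.
* Both Gaussian approximations inherit the skewness blindness of their
  family: with $K \le 2$, low detection, or near-boundary occupancy the
  true marginals are skewed and VB interval coverage drops below nominal.
  The MLE's Wald intervals degrade similarly at boundary estimates.
* The Laplace bound trace can decrease transiently (see above); treat the
  trace as a convergence monitor, not as a quantity to compare across
  models.
* `accStat()` needs a few thousand reasonably mixed draws; it rejects
  degenerate samples but cannot detect an unconverged chain.
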