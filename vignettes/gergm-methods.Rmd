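---
title: "Modelling valued networks with generalized exponential random graph models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling valued networks with generalized exponential random graph models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gergm)
```

## The model

Exponential random graph models (ERGMs) describe a binary network through
a vector of statistics counting local configurations — mutual ties,
triangles, stars — but their normalizing sum diverges as soon as edges
take continuous values on an unbounded support.  This package implements
the generalized ERGM (GERGM), which solves that problem in two stages.

**Stage 1 — dependence on a restricted network.**  Let $X$ be an
$n \times n$ directed network whose off-diagonal edges lie in the open
unit interval.  Its density is the exponential family

$$ f(x \mid \theta) \;=\; \frac{\exp\{\theta' h(x)\}}
   {\int_{[0,1]^m} \exp\{\theta' h(z)\}\, dz}, $$

where each component of $h$ is a sum of products of edge values over
small subgraphs: total edge weight (`edge_sum`), dyadic products
(`reciprocity`), ordered-triple products closing a two-path
(`transitive_triads`), directed three-cycles (`cyclic_triads`), and
shared-receiver / shared-sender products (`in_two_stars`,
`out_two_stars`).  Because every edge enters each product at most
linearly, $h$ is bounded on the unit hypercube and the normalizing
integral always converges — any statistic of this subgraph-product form
is admissible.  When $\theta = 0$ the edges of $X$ are independent
uniforms.

**Stage 2 — marginal transformation.**  The observed network $Y$ is
obtained edgewise through a strictly increasing parameterized map
$y_{ij} = T(x_{ij}, \beta)$, chosen as the quantile function of a
marginal family.  Then $X = F(Y \mid \beta)$ is the network of joint
quantiles of the data — the construction mirrors a copula — and the
density of $Y$ is the restricted-network density evaluated at $F(y)$
times the diagonal Jacobian $\prod_{ij} f(y_{ij} \mid \beta)$.  Three
families are built in:

* **gaussian** — $y_{ij} \sim N(z_{ij}'\eta,\ \alpha^2)$, edge
  covariates $z_{ij}$ entering the location;
* **cauchy** — location-scale Cauchy, for heavy-tailed edges such as
  year-to-year changes in flow volumes (the motivating application class);
* **interval** — the linear map onto fixed bounds $(a, b)$; with
  $(-1, 1)$ this models correlation networks directly.

With $\theta = 0$ the model collapses exactly to the corresponding
independent regression (linear regression for the Gaussian family,
Cauchy regression otherwise), so "no network dependence" is a testable
restriction rather than an assumption: `wald_block_test()` tests all
dependence parameters jointly against that nested model.

## Sampling

Multilinearity gives each edge a closed-form full conditional: holding
the rest of the network fixed, $\theta'h(x) = a\,x_{ij} + c$ with
$a = \theta'\Delta_{ij}h$ the per-edge change score, so the conditional
density is the truncated exponential $a e^{a x}/(e^a - 1)$ on $(0,1)$.
`draw_edge()` inverts its CDF exactly,
$x = \log\{1 + u(e^a - 1)\}/a$, with two numerical guards: $|a| \le
10^{-8}$ falls back to the uniform limit (the closed form is unstable
near $a = 0$, where the density degenerates to the uniform), and
$a > 30$ is evaluated in log space so $e^a$ never overflows.  A Gibbs
sweep (`gibbs_sweep()`, C++ core) redraws every ordered pair once in a
fixed row-major enumeration; a random scan is available by
configuration, but the fixed order makes runs exactly reproducible from
a seed.  Chains for multi-chain diagnostics start from a U-shaped
Beta(1/2, 1/2) overdispersed initialization.

## Estimation

`gergm()` alternates two maximizations:

1. **Marginal parameters.**  The normalizing integral does not involve
   $\beta$, so updating $\beta = (\eta, \log\alpha)$ is a smooth
   maximization of $\theta'h(F(y \mid \beta)) + \sum \log f(y_{ij} \mid
   \beta)$ (BFGS; for $\theta = 0$ with the Gaussian family the exact
   least-squares solution is used).  The scale is carried on the log
   scale so the optimizer is unconstrained.
2. **Dependence parameters.**  The intractable ratio
   $C(\theta)/C(\tilde\theta)$ is estimated by importance sampling over
   $M$ networks Gibbs-simulated at the provisional $\tilde\theta$
   (log-sum-exp throughout), and the resulting approximate likelihood is
   maximized with an analytic gradient.  Starting values come from the
   maximum pseudolikelihood estimate — the product of the exact
   truncated-exponential conditionals — which is itself the exact MLE
   for the independent-edge (`edge_sum`-only) model.

A finite maximizer of the importance-sampled objective exists only when
the observed statistic vector lies inside the convex hull of the
simulated statistics.  Exact hull membership in $q$ dimensions is a
linear program; the implementation uses the componentwise-range
necessary condition plus detection of optimizer divergence and
non-vanishing gradients, which in practice catches hull violations, and
raises an error asking for a fresh, larger sample (the fitting loop
retries with doubled burn-in automatically).

**Convergence.**  Successive $\theta$ updates jitter by their own Monte
Carlo standard error (roughly the statistical standard error divided by
$\sqrt{M}$), so a fixed small tolerance on parameter changes can never
be met at finite $M$.  The loop therefore stops when every parameter
changes by less than $\max(\text{tol},\ 2 \times \text{MC SE of the
update})$, where the MC SE is estimated from the importance weights, and
never before a second resampled update (the first sample is generated at
the MPLE, which can sit off the MLE).  `tol` (default $10^{-4}$) governs
in the large-$M$ limit.

**Covariance.**  The covariance matrix is the negative inverse of the
numerical Hessian (via `stats::optimHess`; second differences at the
machine-default step, which is less noise-prone than very small custom
steps) of the approximated joint log likelihood at the final estimates,
using a fresh sample simulated at $\hat\theta$.  At desk-scale $n$ the
joint information is often nearly singular — the density statistic and
the marginal intercept shift the quantile network in almost the same
way — so directions of non-negative curvature are treated as carrying no
information: their curvature is capped at a tiny negative value, which
yields very large variances along them rather than meaningless negative
ones.  A blockwise variant (`vcov_estimate(fit, blockwise = TRUE)`)
inverts the $\theta$ and $\beta$ blocks separately; its $\beta$ block
reproduces the classical regression covariance exactly in the
independence case, at the price of ignoring the cross-block
collinearity.

## Diagnostics

Exponential-family network models degenerate: for much of the parameter
space the distribution piles onto the full or empty graph.
`degeneracy_report()` flags a fitted model whose simulated grand mean
edge value is closer to 0 or 1 than to the observed mean, and summarizes
chain convergence with the Geweke window diagnostic (window means
compared on the spectral-density scale, windows 10% / 50% by default,
spectral density at zero from an AIC-selected autoregressive fit) and
the Gelman-Rubin shrink factor across chains
($\hat R = \sqrt{\hat\sigma^2 / W}$, no degrees-of-freedom correction by
default, the corrected variant by flag; values at or above 1.1 flag
non-convergence).  `gof_dependence()` simulates networks from the fitted
dependence model and locates each observed statistic within the
simulated distribution; a feature is adequately reproduced when it falls
inside the simulated inter-quartile range.

## Synthetic scenarios and what the tests show

`make_scenario()` generates fully reproducible data sets from stated
truths; `dependence_grid()` reruns the behavioural experiments that link
each statistic to its network feature.  Parameter magnitudes were chosen
once, inside the non-degenerate region, and verified by
`degeneracy_report()`:

* the two-vertex scenario uses $\theta = (-2, +2)$ (negative density,
  positive reciprocity).  $(-1, +2)$ was rejected because that density
  is symmetric under $(x, y) \mapsto (1-x, 1-y)$, which hides the
  density effect in the marginal mean;
* the recovery scenario uses 15 vertices, $\theta =
  (\text{edge\_sum} = -0.5,\ \text{reciprocity} = 0.8)$, a Gaussian
  marginal with a standard-normal nodal attribute expanded to sender and
  receiver columns, $\eta = (1, 0.5, -0.5)$, $\alpha = 1$;
* the reciprocity grid is $\{-1, 0, 1, 2\}$ at $n = 25$; the
  in-two-stars grid is $\{-0.1, -0.05, 0, 0.05, 0.1\}$, because positive
  two-star coupling raises in-degree heterogeneity only up to
  saturation — by $\theta = 0.2$ the mean edge reaches $\approx 0.74$
  and the variance begins to fall again — so the grid sits below
  saturation where the effect is monotone.

Problem sizes in the test suite (100,000 conditional draws, $M = 5000$
importance samples on 5 vertices, 50 replicated fits at $n = 15$ with
$M = 500$, 1000 networks per grid point at $n = 25$, 500 diagnostic
replicates on chains of length 10,000) were chosen so the whole suite
completes in about a minute on one CPU while keeping Monte Carlo error
well below each assertion's margin.

The generator emulates the model's own data-generating process — exact
in that sense — but not features of real valued networks that the model
does not describe: zero-inflated or discrete edge values, missing dyads,
temporal dependence, or marginal families outside the three implemented.
Passing recovery tests therefore demonstrates correctness of the
machinery, not adequacy of any particular specification for a given data
set; that judgement belongs to `gof_dependence()` and the degeneracy
checks on the data at hand.

## Numerical choices and limitations

* Restricted-network values are clamped to $[10^{-10}, 1-10^{-10}]$;
  CDF transforms of extreme observations would otherwise hit machine 0
  or 1, where the dependence density is undefined.
* Edge enumeration is row-major over ordered pairs $(i, j)$, $i \ne j$;
  all per-edge vectors (covariate rows, locations, simulation draws)
  follow it.
* Undirected networks are accepted by the containers, but reciprocity
  and the triadic statistics are refused for them (direction collapses),
  and estimation requires a directed network.
* The Gibbs scan order is fixed, not random, by default: reproducibility
  was preferred; a random scan is one flag away.
* The likelihood-ratio test (`lr_block_test()`) uses the approximated
  log likelihood at the last iteration and inherits its Monte Carlo
  noise; the Wald test is the recommended default.
* Degeneracy-resistant statistic families (geometrically weighted
  terms) are out of scope: the implemented statistics are the classical
  subgraph products, and for larger $|\theta|$ or larger $n$ the
  non-degenerate region shrinks — always check `degeneracy_report()`.
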