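---
title: "Maximal point-polyserial correlation: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximal point-polyserial correlation: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxppc)
```

## The model

Let $X$ be absolutely continuous with density $f$, CDF $F$, mean $\mu$ and
variance $\sigma^2$, and let $X_d$ be discrete on $x_1 < \dots < x_k$ with
probabilities $p_i$ and cumulative probabilities $F_i$. Among all joint
distributions with these margins, Pearson's correlation
$\mathrm{cor}(X, X_d)$ is maximized when the pair is comonotonic — both
increasing functions of one driver. Under comonotonicity category $i$
occupies the quantile band $(F^{-1}(F_{i-1}), F^{-1}(F_i)]$ of $X$, so the
mixed moment is a weighted sum of partial moments,
$$
\mathbb{E}_c(X X_d) = \sum_{i=1}^k x_i
\int_{F^{-1}(F_{i-1})}^{F^{-1}(F_i)} x f(x)\,dx,
\qquad
\rho_{PP,\max} = \frac{\mathbb{E}_c(X X_d) - \mu\,\mathbb{E}(X_d)}
{\sigma \sqrt{\mathrm{Var}(X_d)}}.
$$
Everything else in the package is an optimization or specialization of
this formula. The substrate is the family of closed-form antiderivatives
$\int x f(x)\,dx$: $-\varphi(x)$ for the normal, $x^2/2$ uniform,
$-(x + 1/\lambda)e^{-\lambda x}$ exponential,
$\frac{\alpha}{1-\alpha} x^{1-\alpha}$ Pareto,
$x e^x/(1+e^x) - \log(1+e^x)$ logistic,
$\frac{\alpha}{\alpha+1} x^{\alpha+1}$ power, and
$e^{\mu+\sigma^2/2}\,\Phi\!\big(\tfrac{\log x - \mu - \sigma^2}{\sigma}\big)$
lognormal. Only standardized normal/uniform/logistic forms are provided:
Pearson correlation is invariant under positive affine maps, so
location-scale variants change nothing the package computes. An adaptive
quadrature fallback (`partial_moment_numeric`) exists purely as a
cross-check and is exercised only by the tests.

Two optimization problems sit on top:

* **CIS** — scores fixed at $1..k$, maximize over the probability simplex.
* **OPT** — maximize over probabilities *and* support values. For fixed
  probabilities the optimal scores are the cell-conditional means
  $x_i^* = \int x f / p_i$; optimizing the cells as well makes the problem
  identical to minimum-MSE quantization, whose solution is the set of $k$
  principal points, with
  $\mathrm{Var}(X_d) = \sigma^2 - \mathrm{MSE}$ and
  $\rho = \sqrt{1 - \mathrm{MSE}/\sigma^2}$.

At a CIS optimum with $k \ge 4$ the thresholds that the optimal cumulative
probabilities induce on $X$ are equally spaced (the stationarity conditions
difference out to $F^{-1}(F_{i+1}) - F^{-1}(F_i) = C/V$). The package
exposes this both as a check (`threshold_spacing`) and as an equivalent
two-variable formulation (`maximize_cis_ab`): cut points
$c_i = a + b(i + \tfrac12)$, probabilities $p_i = F(c_i) - F(c_{i-1})$,
optimized over the shift $a$ and scale $b > 0$.

## Algorithms and numerical choices

**CIS solver.** Two stages. Stage one searches the $(a, \log b)$ plane
(Nelder–Mead, then BFGS), initialized by regressing the equal-probability
quantiles on the cut indices; by the spacing property this parametrization
already contains the optimum for every $k$. Stage two polishes on the full
simplex through a softmax parametrization ($p = \mathrm{softmax}(z)$, first
logit pinned to 0) with BFGS, which certifies the stage-one solution against
the general problem and resolves $k \in \{2, 3\}$ corner cases directly.
Probabilities below $10^{-12}$ are treated as exactly zero in mixed-moment
sums (the $0 \log 0 := 0$ limit of the closed forms); during optimization
they are clipped at $10^{-9}$ so quantiles stay finite, and the final vector
is renormalized. Optional multistart jitter draws Dirichlet(1) starting
points under a caller-supplied seed; every reported table value is
reproduced from the deterministic default start, so the multistart is a
safeguard, not a dependence.

**OPT solver.** Lloyd's fixed point: support values to cell-conditional
means, cut points to midpoints, iterated until the largest support-value
move is below $10^{-10}$. Initialization at the equal-probability quantiles
$F^{-1}((i - \tfrac12)/k)$; the iteration is deterministic and, for the
log-concave families here, converges to the unique principal-point
configuration (a few hundred sweeps at $k = 7$).

**Equal-probability closed forms and limits.** Each family's
equal-probability correlation is evaluated directly from its finite-sum
closed form (the sums use R's long-double accumulation, accurate through
the $k = 10^6$ evaluations used to confirm limits). The printed limit
constants are typeset without radicals in the source material; the
implemented placements — normal $\sqrt{3/\pi}$, exponential $\sqrt3/2$,
Pareto $\sqrt{3\alpha(\alpha-2)}/(2\alpha-1)$, logistic $3/\pi$, power
$\sqrt{3\alpha(\alpha+2)}/(2\alpha+1)$ — reproduce every printed decimal
and are additionally unit-tested against the finite-$k$ formulas at large
$k$, so the reconstruction is verified, not assumed.

**Attainable bounds.** $\rho_{\max} = \mathrm{cor}(F_1^{-1}(U),
F_2^{-1}(U))$ and its countermonotonic twin are integrated with a composite
Gauss–Legendre rule whose panels subdivide dyadically toward both endpoints
(breakpoints $2^{-j}$ and $1 - 2^{-j}$ down to the double-precision
resolution, ~2048 nodes total). A single global rule of that size was
measured to miss the lognormal $\sigma = 2$ tail by almost $10^{-2}$ —
roughly 16% of the integrand's mass sits above $u = 1 - 3\times10^{-5}$ —
while the graded rule reproduces the closed form to six decimals. Identical
models short-circuit to $\rho_{\max} = 1$; the lognormal–lognormal pair
uses its closed form.

**Copulas.** Densities are closed-form (the Gumbel one assembled in log
space). The band integrals of the mixed moment are *not* done by 2-D
cubature: the inner coordinate integrates exactly through the conditional
distribution $\partial C/\partial u$, leaving a 1-D adaptive quadrature
$\int_0^1 u\,h(i/k \mid u)\,du$, split at $u = i/k$ because $h$ approaches
a step there under strong dependence. The 2-D tensor-quadrature route is
retained in the test-suite as an independent oracle. The Frank conditional
is evaluated in the cancellation-free form
$a(1-b)/(a + b - ab - t)$ with $a = e^{-\theta u}$ etc., which survives the
large-$\theta$ calibrations near $\rho = 1$. Spearman calibration inverts
the family's $\rho_S(\theta)$: closed form for Gauss, Debye-function
identity for Frank, tensor quadrature of $12\iint C - 3$ with geometric
bracket expansion for Clayton/Gumbel.

**Moment matching.** The $k$-point law matching the first $2k-1$ raw
moments is the Gaussian quadrature rule for the density as weight, computed
by eigen-decomposition of the Jacobi matrix. Normal, uniform and
exponential use their exact Hermite / shifted-Legendre / Laguerre
recurrence coefficients (stable at any $k$); other families run the
Chebyshev algorithm on exact raw moments, which in double precision is
trustworthy only to about $k = 12$ — beyond that the computation refuses
rather than degrades silently. Extended-precision arithmetic would lift the
cap but would add a dependency the package deliberately avoids.

## What the synthetic generator emulates — and what it does not

`generate_pair` draws one uniform driver per observation, maps it through
the family quantile function (so every family reuses the same tested code
path) and cuts a second, possibly dependent, uniform at the
discretization's cumulative probabilities. Comonotone and countermonotone
couplings share/reflect the driver; copula couplings use conditional
inversion (closed form for Gauss/Frank/Clayton) or the positive-stable
frailty construction (Gumbel). This emulates the *population* objects the
formulas describe — it contains no measurement error, no ties beyond those
inherent to discretization, and no model misspecification. A green
Monte-Carlo test therefore establishes agreement between two computations
of the same model, not robustness to real-data violations. One consequence
is documented in the tests themselves: for Pareto $\alpha = 4$ the fourth
moment diverges, the sample correlation's own sampling noise at $n = 10^6$
is ~0.0035, and a 0.003 reproduction band is not robustly attainable for
that family — the corresponding test is kept at the stated band with
pre-registered seeds rather than widened.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| CIS/OPT convergence tolerance | $10^{-10}$ on the objective | table values need 4 stable decimals; cost is negligible |
| Lloyd stopping rule | max support move $< 10^{-12}$ | probabilities inherit ~$10^{-10}$ accuracy |
| probability clip during search | $10^{-9}$ | keeps $F^{-1}$ finite on open-support families |
| attainable-bounds quadrature | ~2048 graded nodes | resolves lognormal tails; $<10$ ms |
| copula quadrature | `integrate`, rel.tol $10^{-10}$, split at the band edge | stable through $\rho = 0.99$ calibrations |
| moment-matching cap (non-classical families) | $k \le 12$ | double-precision Chebyshev conditioning |
| reporting | values 3 decimals, probabilities/correlations 4 | matches the tables the package reproduces |

## Known limitations

* The minimum (countermonotonic) point-polyserial correlation is not
  implemented — only the attainable *bounds* for two continuous margins.
* Families outside the seven listed are unsupported by construction;
  general location-scale fitting and estimation from data (e.g. maximum
  likelihood polyserial estimation) are out of scope. The sorted-sample
  estimator is the only data-facing entry point.
* CIS optima are certified by multistart agreement and the spacing
  property, not by a global-optimality proof; for the monotone-density and
  symmetric families covered, all published optima are reproduced.
* Copula ratio curves are reproduced as data; the underlying experiment
  has no printed per-point values to compare against, so its tests assert
  bounds, limits and dual-route agreement instead of table equality.
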