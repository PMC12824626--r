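---
title: "Likelihood-based estimation of molecular mediation from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based estimation of molecular mediation from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limamr)
```

## The problem

An exposure $X$ (say, body mass index) has a total causal effect
$\theta$ on an outcome $Y$ (say, HDL cholesterol). Part of that effect
may flow through molecular mediators $M_1,\dots,M_k$ — metabolites,
proteins, transcripts. Writing $\gamma_j$ for the causal effect of $X$
on $M_j$ and $\delta_j$ for the effect of $M_j$ on $Y$, the total effect
decomposes as

$$\theta = \alpha + \omega, \qquad \omega = \gamma'\delta,$$

with $\alpha$ the direct effect. The **mediation proportion** is
$\mathrm{MP} = 1 - \alpha/\theta = \omega/\theta$.

None of these quantities is observed. What is observed are GWAS/QTL
association summary statistics: effects $\hat\beta$ of $m$ exposure
instruments on $X$, effects $\hat{\mathbf{C}}$ ($m \times k$) of those
instruments on the mediators, effects $\hat{\mathbf{B}}$ ($l \times k$)
of the mediator instruments on the mediators, and outcome effects
$\hat c$ (length $m$) and $\hat b$ (length $l$). With all traits
standardized, each block is the true effect plus Gaussian estimation
noise whose variance is (approximately) the reciprocal of the study
sample size, optionally inflated by a pleiotropy variance component:

$$
\hat\beta \sim N(\beta, \tfrac{1}{n_X} I), \quad
\mathrm{vec}(\hat{\mathbf{B}}) \sim N(\mathrm{vec}(\mathbf{B}),
  \tfrac{1}{n_M}\,\Sigma \otimes I), \quad
\mathrm{vec}(\hat{\mathbf{C}}) \sim N(\mathrm{vec}(\beta\gamma'),
  (\tfrac{1}{n_M}+\sigma^2_C)\,\Sigma \otimes I),
$$
$$
\hat c \sim N(\beta(\alpha + \gamma'\delta),
  (\tfrac{1}{n_Y}+\sigma^2_c) I), \qquad
\hat b \sim N(\mathbf{B}\delta, (\tfrac{1}{n_Y}+\sigma^2_b) I),
$$

where $\Sigma$ is the phenotypic correlation matrix of the mediators.
The package assumes independent (pre-clumped) instruments, mediator
instruments with no effect on the exposure, and the InSIDE condition
(pleiotropic effects independent of instrument strength, mean zero).

The practical difficulty is that molecular QTL studies are one to two
orders of magnitude smaller than complex-trait GWAS
($n_M \approx 10^3\!-\!10^4$ vs $n_X, n_Y \approx 10^5\!-\!10^6$). The
classical two-step analysis regresses outcome effects on *estimated*
instrument effects, treating them as exact regressors. Measurement error
in $\hat{\mathbf{C}}$ and $\hat{\mathbf{B}}$ then dilutes the mediator
coefficients (regression dilution / weak-instrument bias), the direct
effect absorbs the lost mediated signal, and MP is underestimated —
by half or more under realistic sample-size ratios.

## The three estimators

**MR+MVMR (baseline).** Univariable inverse-variance weighted (IVW)
regression of $\hat c$ on $\hat\beta$ gives $\hat\theta$; multivariable
MR on the stacked design
$\hat\Pi = [\,\hat\beta\; \hat{\mathbf{C}}; 0\; \hat{\mathbf{B}}\,]$
gives $(\hat\alpha, \hat\delta)$ with the usual WLS covariance
$(\hat\Pi'\Lambda^{-1}\hat\Pi)^{-1}$. `mr_mvmr_mediation()` implements
both steps; $\mathrm{Var}(\hat\omega)$ is taken as
$\mathrm{Var}(\hat\theta)+\mathrm{Var}(\hat\alpha)$ because the two
steps are separate regressions whose covariance the two-step design
does not expose.

**LiMA.** `fit_lima()` maximizes the joint log-likelihood of all five
blocks over the $2k+1$ parameters $(\alpha, \gamma, \delta)$,
conditioning each outcome-side block on the estimated regressors. The
conditioning is what removes the dilution: given $\hat{\mathbf{B}}$,
the conditional law of $\hat b_i$ is
$N(\hat{\mathbf{B}}_{i\cdot}\delta,\; 1/n_Y + \sigma^2_b +
\delta'\Sigma\delta/n_M)$ — the regressor noise is moved into the
residual variance instead of being ignored. Analogously
$\hat c_i \mid \hat\beta_i \sim N(\hat\beta_i(\alpha+\gamma'\delta),\,
1/n_Y+\sigma^2_c+(\alpha+\gamma'\delta)^2/n_X)$ and
$\hat{\mathbf{C}}_{i\cdot} \mid \hat\beta_i \sim
N(\hat\beta_i\gamma,\, (1/n_M+\sigma^2_C)\Sigma + \gamma\gamma'/n_X)$.
Averaged over the I-LiMA prior below, these inflated variances
reproduce the integrated model's moments exactly; the test suite
asserts this consistency.

**I-LiMA.** With hundreds of candidate mediators, $2k+1$ parameters are
too many, and per-mediator effects are not actually needed to estimate
MP. `fit_ilima()` places a Gaussian prior
$(\gamma_j, \delta_j) \sim N(0, [\sigma^2_\gamma, \sigma_{\gamma\delta};
\sigma_{\gamma\delta}, \sigma^2_\delta])$ and integrates the pair out.
The stacked vector $(\hat b, \hat c, \mathrm{vec}(\hat{\mathbf{C}}))$
is then Gaussian with mean $(0,\; \hat\beta(\alpha + k\sigma_{\gamma\delta}),\; 0)$
and a block covariance combining diagonal noise, rank-one terms
$\sigma^2_\omega \hat\beta\hat\beta'$ and
$\sigma^2_\delta\hat{\mathbf{B}}\hat{\mathbf{B}}'$, and the cross-block
coupling $\sigma_{\gamma\delta}(\hat{\mathbf{B}} \otimes \hat\beta')$,
where $\sigma^2_\omega = k(\sigma^2_\gamma\sigma^2_\delta +
\sigma^2_{\gamma\delta})$. Only four parameters are estimated
regardless of $k$, and
$\hat\omega = k\hat\sigma_{\gamma\delta}$,
$\hat\theta = \hat\alpha + \hat\omega$. Mediator independence
($\Sigma = I_k$) is assumed inside the marginal for tractability; the
fast evaluation exploits the block-zero pattern with
Sherman–Morrison/Woodbury identities and costs $O(lk^2 + mk)$ per call,
validated against a dense element-by-element construction
(`ilima_loglik_dense()`, retained as the reference implementation).

Because the prior treats $\omega$ as random with variance
$\sigma^2_\omega$, I-LiMA deliberately attributes part of the
along-$\hat\beta$ variation in $\hat c$ to indirect-effect variability
rather than to $\alpha$. Its interval estimates are therefore wider and
better calibrated than those of LiMA or the two-step baseline — the
mechanism behind its improved type-I-error control and its lower power.

### Variances and MP

For the likelihood methods, `lrt_variances()` converts likelihood-ratio
statistics into variances via the LRT–Wald correspondence
$\mathrm{Var}(\hat\alpha) = \hat\alpha^2/\chi^2_\alpha$ with
$\chi^2_\alpha = -2\log[L(0, \hat\omega)/L(\hat\alpha, \hat\omega)]$
(and analogously for $\omega$);
$\mathrm{Var}(\hat\theta) = \mathrm{Var}(\hat\alpha) +
\mathrm{Var}(\hat\omega)$. For LiMA the profile likelihood is the
$\hat c$ block (the only component depending on $\alpha$ and $\omega$);
for I-LiMA it is the full marginal. An estimate exactly at its null
gives $\chi^2 = 0$ and an infinite variance, reported as such.

A single pair's MP is $\widehat{\mathrm{MP}} = 1 - \hat\alpha/\hat\theta$
with the delta-method variance
$(\hat\alpha^2/\hat\theta^2)(\mathrm{Var}(\hat\alpha)/\hat\alpha^2 +
\mathrm{Var}(\hat\theta)/\hat\theta^2)$ — no covariance term, following
the estimator's definition; the estimate is flagged undefined outside
$[0,1]$ or when $\hat\alpha$ and $\hat\theta$ disagree in sign. Groups
of pairs (or replicates of a simulation) are aggregated by the
no-intercept regression of $\hat\alpha_i$ on $\hat\theta_i$:
$\widehat{\mathrm{MP}} = 1 - \sum\hat\alpha_i\hat\theta_i /
\sum\hat\theta_i^2$, with variance $\sigma^2/\sum\hat\theta_i^2$ where
$\sigma^2$ is the residual variance estimated as
$\mathrm{RSS}/(n-1)$ (one slope parameter, no intercept; the denominator
convention is a package choice, immaterial at $n = 300$). Non-converged
fits are excluded from aggregation and counted.

## The generator

`lima_scenario()` + `generate_replicate()` emulate a complete
summary-statistics mediation study:

1. **Slab covariance.** Given targets MP, $E(\theta)$, the outcome
   variance explained by mediators $\sigma^2_{Y,M}$ and the effect
   correlation $\rho_{\gamma\delta}$, `solve_prior_variances()` sets
   $\sigma^2_\delta = \sigma^2_{Y,M}/k_s$ and solves
   $\sigma^2_\gamma$, $\sigma_{\gamma\delta}$ so that
   $E(\omega)^2 + \mathrm{Var}(\omega) = (\mathrm{MP}\cdot E(\theta))^2$.
2. **Spike-and-slab effects.** The first $k_s = \mathrm{round}(p_k k)$
   mediators draw $(\gamma_j,\delta_j)$ from the bivariate slab; the
   rest are exactly null.
3. **Direct effect.** $\alpha = \frac{1-\mathrm{MP}}{\mathrm{MP}}
   \gamma'\delta$, making $\mathrm{MP} = 1-\alpha/\theta$ hold exactly
   in every replicate. Under the no-mediation null (`mp = 0`), $\alpha
   \sim U(0.5\,E(\theta), 1.5\,E(\theta))$ — the interval is a package
   choice: symmetric about $E(\theta)$ and bounded away from zero so
   the MP ratio stays estimable.
4. **Architecture.** Mediator heritabilities are truncated
   Weibull(0.5, 0.05) (the heavy right skew of cis-QTL variance
   explained); per-mediator instrument counts are zero-truncated
   geometric with mean 3 (configurable, or user-supplied), mimicking the
   skewed "effective instruments" distribution of cis-QTL data without
   requiring any external dataset; instrument effects are Gaussian,
   rescaled post hoc so heritabilities are matched exactly.
5. **Noise.** Summary statistics are drawn from the block model above,
   with $\hat{\mathbf{B}}$/$\hat{\mathbf{C}}$ row noise correlated via
   the Cholesky factor of $\Sigma$ (identity, 10-dimensional
   random-vector correlations, or a user matrix; shrinkage
   $\lambda = 10^{-6}$ toward identity restores rank when needed).
   `vec` ordering is column-major throughout, verified against a dense
   covariance oracle.
6. **Selection.** Each mediator is screened by univariable IVW MR of
   exposure on mediator; only mediators passing the threshold $P$ enter
   the fitted model. If none passes, the replicate is re-simulated (the
   count is logged; this mild winner's curse is accepted). $P = 1$
   bypasses selection — the oracle design.

### The no-mediation null

A subtlety worth spelling out. If the null ($\mathrm{MP}=0$) were
simulated with $\gamma = \delta = 0$ exactly, then $\hat\omega$ would
concentrate so tightly around zero that no method ever rejects, and
type-I error would be trivially zero — a regime in which comparing
T1E control across estimators is meaningless. The null implemented here
instead keeps the mediators looking like genuine candidates: their
$(\gamma_j, \delta_j)$ are drawn from the same slab an alternative with
`null_slab_mp` (default 0.15) would use, but with the $\gamma$–$\delta$
coupling removed, so the *expected* indirect effect is exactly zero
while each replicate's realized $\omega_i$ fluctuates around it. Type-I
error then measures what it should: how often a method's confidence
interval excludes zero when the average mediation is null.

### Default study conditions

The defaults describe the motivating design: complex-trait exposure and
outcome at $n_X = n_Y = 300{,}000$, molecular mediators at
$n_M = 10{,}000$, $E(\theta) = 0.15$, $\mathrm{MP} = 0.15$,
$h^2_X = 0.35$, $k = 10$ mediators all non-null ($p_k = 1$),
$\sigma^2_{Y,M} = 0.05$, $\rho_{\gamma\delta} = 0$, $\Sigma = I$, no
pleiotropy, Bonferroni selection $P = 0.05/k$, 300 replicates. The
number of exposure instruments defaults to $m = 100$, a typical count
of independent genome-wide-significant loci for a heritable complex
trait at this sample size; it was fixed on that reasoning before any
benchmark was run. With $\rho_{\gamma\delta} = 0$ the per-replicate
total effect $\theta_i = \omega_i/\mathrm{MP}$ is symmetric around zero
with root-mean-square $E(\theta)$ — $E(\theta)$ acts as a scale, and
per-replicate MP is still exactly 0.15 by construction. Interval-based
metrics (coverage, power, T1E) are sensitive to this spread through the
many small-$|\theta_i|$ replicates it creates, and a design that
concentrates $\theta_i$ (larger $\rho_{\gamma\delta}$) would trade
lower coverage for higher power at identical bias; the bias ranking of
the three methods is insensitive to this choice.

## What the simulations do and do not show

The generator reproduces the statistical structure of a summary-level
mediation study: sample-size-scaled Gaussian noise, spike-and-slab
mediation signal, skewed mediator architectures, selection-induced
winner's curse, correlated mediators, pleiotropy variance components.
It does **not** simulate individual genotypes, LD between instruments
(instruments are independent by construction; the pipeline expects
pre-clumped variants), sample overlap between studies, binary-trait
effect-scale issues, or non-Gaussian pleiotropy. Passing benchmarks
therefore demonstrate correctness of the estimators under the stated
model, not robustness to every failure mode of real data.

## Numerical choices

* LiMA: BFGS from a warm start at the two-step estimates, up to 3
  jittered restarts; convergence is the optimizer's own criterion
  (relative tolerance $10^{-12}$, `maxit` 1000); non-convergence is a
  flag, never an exception. A warning is emitted above $k = 30$, where
  the $2k+1$-dimensional search becomes slow — I-LiMA is the intended
  tool there.
* I-LiMA: the three-step fit (the step structure follows the method's
  published parameter count: the two prior variances are estimated from
  their own blocks, then $(\alpha,\sigma_{\gamma\delta})$ jointly on
  the full marginal). One-dimensional profile maximizations use
  golden-section search on $[0, 1]$ — on the standardized scale both
  prior variances are bounded well below 1. The covariance parameter is
  optimized as $\rho \in [-1, 1]$ times $\sigma_\gamma\sigma_\delta$
  (L-BFGS-B box), which enforces the positive-semidefinite prior
  throughout; a solution at the boundary is flagged (`psd_boundary`).
  Parameter combinations making a covariance block non-PD score
  $-\infty$ and are rejected by the optimizer.
* Pleiotropy variances default to zero and fixed; the likelihood
  accepts them as data-level constants. Degenerate inputs (all-zero
  instruments, duplicated mediators) raise descriptive errors;
  estimator ties ($\chi^2 = 0$, $\hat\theta = 0$) produce infinite
  variances or undefined-MP results rather than exceptions.
* Replicate $r$ of a scenario uses a sub-seed drawn once from the
  scenario seed, so results are identical regardless of which methods
  or how many replicates are evaluated together.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the default scenario and
the single-null-mediator scenario at the published 300 replicates
(about half a minute each on one core), and the $k = 500$ / 5%-non-null
selection scenario at 100 replicates — the package's documented
reduced-replication mode, which widens the Monte-Carlo intervals but
leaves the comparisons interpretable. Monte-Carlo distributional checks
in the unit tests use $10^4\!-\!10^5$ draws.

## Known limitations

* The delta-method MP variance omits $\mathrm{Cov}(\hat\alpha,
  \hat\theta)$ (as the estimator is defined); when the two estimates
  are strongly correlated the claimed variance is conservative, and
  per-replicate coverage of all methods is imperfect even in easy
  regimes.
* The two-step baseline's $\mathrm{Var}(\hat\omega)$ ignores the
  covariance between its two regression steps.
* I-LiMA's $\Sigma = I$ assumption is a deliberate trade-off; with
  strongly correlated mediators its bias advantage persists but its
  intervals are not guaranteed calibrated. Orthogonalizing mediators
  (e.g. by principal components) is out of scope here.
* MP is undefined when direct and indirect effects have opposite
  signs; results carry a `defined` flag and should be read with the
  direct/indirect estimates.
* The correlated-instrument variant (user-supplied LD weighting matrix
  in the IVW/MVMR steps) is exposed but has no published example to
  validate against.
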