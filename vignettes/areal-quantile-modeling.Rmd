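---
title: "Quantile modeling of spatiotemporal relative risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile modeling of spatiotemporal relative risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealquant)
```

## The estimation problem

Areal surveillance data are counts $y_{it}$ of health events in region
$i = 1,\dots,n$ and period $t = 1,\dots,T$, paired with expected counts
$e_{it}$ from indirect standardization.  The quantity of epidemiological
interest is the relative risk $\mu_{it}$, with $\mu = 1$ the null.
Ordinary disease-mapping regression models the conditional *mean* of risk;
many surveillance questions, however, concern chosen *quantiles* — the
upper tail of risk during an outbreak, or the stability of the lower tail.
Quantile regression for counts is obstructed by the discreteness of the
outcome's distribution function (jittering the counts imposes
pseudo-continuity at the price of badly distorting small counts), so this
package instead models quantiles of the relative risk, which is
continuous, through a log-Laplace distribution.

## The log-Laplace quantile model

The three-parameter log-Laplace density $LL(\delta, a, b)$ is a
power-function distribution below the scale $\delta$ and a Pareto tail
above it.  Substituting $a = \tau/\sigma$, $b = (1-\tau)/\sigma$,
$\delta = e^{\mu_\tau}$ gives the quantile parameterization used
throughout,

$$f(\mu;\mu_\tau,\tau,\sigma) = \frac{1}{\mu}\,
  \frac{\tau(1-\tau)}{\sigma}\,
  \exp\{-\rho_\tau(\log\mu - \mu_\tau)/\sigma\},$$

with $\rho_\tau(r) = r(\tau - 1\{r<0\})$ the check loss.  Two properties
make this the right prior for quantile-targeted risk estimation:

* $P(\mu \le e^{\mu_\tau}) = \tau$ exactly — the location **is** the
  $\tau$-quantile; and
* maximizing the log-density in $\mu_\tau$ minimizes summed check loss of
  $\log\mu - \mu_\tau$, the defining objective of $\tau$-quantile
  estimation, so the fit targets the quantile even under error-law
  misspecification.

Equivalently, $\log\mu$ is asymmetric-Laplace (AL); the sampler works on
the log scale for numerical stability, and the linear-scale `dloglap()` is
a thin wrapper over the log-space computation.  Parameter validation is
strict everywhere — $\tau$ outside $(0,1)$ or $\sigma \le 0$ raises an
error rather than being clamped, because silent repair of the quantile
level corrupts every downstream interpretation.

The hierarchical model is

$$y_{it} \sim \text{Poisson}(e_{it}\mu_{it}), \qquad
  \log \mu_{it} = \eta_{\tau,it} + \epsilon_{\tau,it}, \qquad
  \epsilon_{\tau,it} \sim AL(0, \tau, \sigma),$$
$$\eta_{\tau,it} = X_{it}^\top\beta_\tau + u_{\tau,i} + v_{\tau,i}
  + \lambda_{\tau,t} + \theta_{\tau,it},$$

with the BYM convolution spatial prior ($u$ intrinsic CAR with conditional
variance $\sigma_u^2/n_{\delta i}$; $v$ exchangeable Gaussian), a
first-order random walk $\lambda_t \sim N(\lambda_{t-1}, \sigma_\lambda^2)$
for the trend, and exchangeable Gaussian interaction $\theta_{it}$.  The
estimated quantile surface is $\hat Q_\tau(\mu_{it}) =
\exp(\hat\eta_{\tau,it})$ with the posterior mean of $\eta$ as the default
point estimate (posterior median available).

### Priors, with defaults and rationale

| parameter | prior / default | rationale |
|---|---|---|
| $\sigma_u, \sigma_v, \sigma_\lambda, \sigma_\theta$ | $\text{Unif}(0, 10)$ on the SD scale | weakly informative on log-risk scales, where an SD of 10 is already absurdly large |
| $\sigma$ (AL scale) | fixed at 1 (`ll_scale = 1`); optionally sampled | see below — the central identification decision |
| $\beta$ | $N(0, 100^2)$ | effectively flat at log-risk magnitudes |
| $\lambda_1$ | $N(0, \sigma_\lambda^2)$ | anchors the random walk so the prior is proper without an intercept |
| $\tau$ | fixed by the analyst | the quantile being modeled is a design choice, not a parameter |

**The AL scale.**  The AL error is a *working likelihood*: its location
targets the quantile regardless of its scale, and fixing the scale (at 1,
the long-standing convention in Bayesian quantile regression) is the
package default.  The alternative — sampling $\sigma$ under a
$\text{Unif}(0,10)$ prior — is available via `model_config(ll_scale = NA)`
but is *unidentified against the exchangeable interaction* $\theta$: both
terms are i.i.d. per cell, so only shape distinguishes them, and when the
realized noise is near-Gaussian the posterior drives $\sigma \to 0$ while
$\sigma_\theta$ absorbs the noise.  The quantile surface then degenerates
to the realized risks (we observed exactly this collapse in long
diagnostic chains started from well-separated states).  With the fixed
scale the error term retains its variance and $\hat\eta$ is a genuinely
smoothed quantile surface.

**Identification of the ICAR level.**  The intrinsic CAR prior is flat in
the constant direction.  After each sweep the sampler re-centers $u$ to
mean zero and moves the removed level into $\lambda$, so the fitted
surface $\eta$ is untouched and the level lands where a proper prior (the
anchored random walk) governs it.  When an intercept is present,
$\lambda$'s own level is identified against it the same way.  Disconnected
maps are rejected outright: islands under an intrinsic CAR require
conventions (per-component constraints, island variances) that silently
guessing would get wrong.

## The sampler

`fit_quantile_model()` and `fit_mean_model()` share an adaptive
Metropolis-within-Gibbs engine, written so every update is vectorized:

* $z = \log\mu$ and $\theta$: elementwise Metropolis (cells are
  conditionally independent);
* $v$: elementwise over regions; $u$: block updates over graph color
  classes (a greedy proper coloring guarantees no two adjacent regions
  update simultaneously, so neighbor sums stay valid);
* $\lambda$: alternating even/odd periods;
* scales: log-scale random walks with the Jacobian correction, hard
  rejection outside $(0, 10)$;
* two dedicated mixing moves, both leaving $\eta$ invariant or nearly so:
  a $u$/$v$ *exchange* that shifts shares between the confounded BYM
  components at fixed sum (prior-only acceptance ratio), and a
  *non-centered global rescale* of $\theta$ that carries the interaction
  magnitude and $\sigma_\theta$ through their funnel.  Without these, the
  BYM and interaction scales showed $\hat R$ up to 1.5 at desk-scale chain
  lengths; with them, $\hat R \le 1.03$.

The mean model replaces the AL error with a Gaussian, making every
random-effect conditional conjugate; there the engine uses exact Gibbs
draws for $\theta$, $v$, $u$ and $\lambda$ instead of Metropolis steps.

Proposal scales adapt per scalar during burn-in by a Robbins–Monro
recursion targeting 0.44 acceptance (0.234 for the joint moves) and are
frozen afterwards, so retained draws come from a fixed kernel.  Chains
start overdispersed (jittered crude rates, spread scale starts) on RNG
streams derived from the configured seed, making every fit bit-reproducible.
Convergence is summarized by the classic between/within two-chain
Gelman–Rubin $\hat R$ on a monitored set (all scales, the surface-average
predictor, any coefficients); the conventional threshold 1.1 triggers a
warning, never a silent pass.  The newer rank-normalized split variant is
deliberately not used, to stay aligned with the classical diagnostic.

Numerical safeguards: scale proposals below $10^{-8}$ are rejected (an
unidentified scale — e.g. the ICAR SD of a one-region map — would
otherwise drift to underflow), and non-finite acceptance ratios count as
rejections.

## Exceedence probabilities and adverse-risk detection

The Monte-Carlo exceedence probability $\hat P(\mu_{it} \ge c)$ is the
fraction of retained draws at or above the cut-off (inclusive), with $c=1$
the null benchmark and $c=2$ a doubled-risk criterion; conventional
flagging thresholds are 0.95/0.975/0.99 (`classify_adverse()`).

The quantile-level reformulation inverts the roles: fix the quantile
location of $\log\mu$ at $\log c$ and let the level be unknown,

$$\log c = \log\mu_{it} + \epsilon_{\tau,it},\qquad
  \tau_{it} \sim \text{Beta}(1,1),$$

so that by the quantile constraint $\tau_{it} = P(c \le \mu_{it})$.  The
constraint replaces the linear predictor, which leaves no slot for the
random-effect structure; the error scale is treated exactly as in the main
model.  (How much of the hierarchical structure should survive inside the
constrained model is genuinely ambiguous; this implementation takes the
minimal coherent reading and documents it here.)

Each unit's level is informed by a single residual, so the posterior of
$\tau_{it}$ is *conservative*: with $|\log c - \log\mu| = r$ the posterior
mean behaves like $2\sigma/r$ near the extremes and cannot reach 0 or 1.
On null data at extreme cut-offs ($c = 100$, $c = 0.01$) the surface sits
near 0.30 / 0.70 rather than 0 / 1, while preserving the ordering of
units (rank correlation with the Monte-Carlo estimator above 0.9 in our
evaluation).  This damping is the estimator's practical virtue: mean
regression's narrow posteriors saturate exceedence probabilities and flag
aggressively, whereas the quantile-level surface grades the same units
moderately.

## The synthetic-data generator

`simulate_counts()` reproduces the generative process the evaluation is
built on, on any connected graph: per replicate, $u$ from the ICAR law
(drawn exactly by spectral decomposition of the graph Laplacian restricted
to its non-null eigenspace — covariance $\sigma_u^2 Q^+$ — rather than by
long Gibbs chains), $v$, $\lambda$ (random walk from a zero-mean start),
$\theta$, and log-scale errors from a zero-center *t* distribution
rescaled to unit variance, with degrees of freedom equal to the region's
expected count — sparse regions get heavy tails, populous regions
near-Gaussian errors.  Since rescaling requires a finite variance, degrees
of freedom at or below 2 are rejected with an explanatory error.  The
error law is deliberately neither Gaussian nor Laplace, so neither fitted
model matches the truth exactly.

Defaults are the study conditions used throughout: 5 periods; variances
$(\sigma_u^2, \sigma_v^2, \sigma_\lambda^2, \sigma_\theta^2) =
(1, 0.2, 0.2, 0.2)$; quantile levels $0.9, 0.5, 0.1$; 50 replicates; and,
when no expected counts are supplied, per-region $e_i$ drawn log-uniformly
between 20 and 2000 — the spread a mid-sized state's counties produce
under internal standardization, and wide enough that the $df = e_i$ rule
yields a genuine mixture of tail behaviors.  Under these settings the
middle 80% of generated relative risks spans roughly two orders of
magnitude, matching the extremes real outbreak data exhibit.  True
quantile surfaces are analytic — $Q_\tau(\mu_{it}) = \exp\{\eta_{it} +
F^{-1}_{t,df_i}(\tau)\sqrt{(df_i-2)/df_i}\}$, reducing to $\exp(\eta_{it})$
at the median — so evaluation never relies on empirical quantiles of the
truth.

What the generator does **not** emulate: real county adjacency (the rook
lattice stands in for a county map), reporting artifacts (delays,
zero-inflation, weekday effects), population drift over time, and
covariate effects (the evaluation fixtures use the no-intercept,
no-covariate design).  Passing recovery tests on these simulations
therefore demonstrates correctness of the machinery under the stated
process, not robustness to everything real surveillance data do.

`expected_rates_endemic()` implements the companion standardization for
real series: expected counts from an endemic window,
$e_i = pop_i \cdot \sum_i\sum_{t\in T_{en}} y_{it}/|T_{en}| / \sum_i pop_i$,
constant over time, with $|T_{en}|$ counted in periods.

## Evaluation protocol and problem sizes

`compare_models()` runs the ground-truth comparison: per replicate, the
quantile model is fitted at each level and the mean model once; quantile
surfaces come from `estimate_quantile_surface()` for the former and from
per-unit empirical posterior quantiles (`mean_model_quantiles()`, type-7
interpolation — stated because conventions differ) for the latter; both
are scored by MSE against the analytic truth.  Mean and summed MSE
aggregations are both available (the per-unit mean is the default; totals
depend on panel size and are hard to compare across designs).

The shipped tests and the acceptance script use desk-scale sizes chosen to
finish in minutes on one CPU: a $4\times4$ lattice over 5 periods (80
cells), 2 chains with 3000–4000 retained draws (the recovery fixture thins
a 24k-iteration run), and 5–10 replicates for the model comparison.
Production analyses should scale the chain lengths up by an order of
magnitude; every size is exposed through `model_config()` and
`sim_config()`.

## Known limitations

* **Per-cell quantile recovery is information-bounded.**  With one
  observation per cell, the interaction $\theta$ (variance 0.2) cannot be
  separated from the unit-variance error; even an oracle knowing the true
  structured effects and applying optimal shrinkage reaches a correlation
  of only about 0.87 between $\hat Q_{0.5}$ and the true $\exp(\eta)$ on
  an 80-cell panel, and realistic fits land near 0.7–0.85 depending on
  the replicate.  Larger panels and longer series tighten this; the model
  comparison (where the quantile model consistently dominates mean
  regression in MSE) is the meaningful desk-scale check, not absolute
  surface accuracy.
* The fixed AL scale trades a small amount of adaptivity for
  identification; users with strong prior information on the error scale
  can set `ll_scale` accordingly.
* The quantile-level exceedence surface compresses toward 1/2 (see
  above); comparisons across units are reliable, absolute probabilities
  are conservative.
* The intrinsic CAR implementation requires a connected map; negative
  binomial and zero-inflated likelihoods are out of scope.
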