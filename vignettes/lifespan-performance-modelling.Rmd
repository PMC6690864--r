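---
title: "Modelling lifespan performance curves with latent development and aging factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lifespan performance curves with latent development and aging factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Complex real-life skills rise steeply early in a career, peak in the late
twenties, and decline afterwards — but not symmetrically, not linearly, and
not identically across people. Long archival records (the motivating case
is season-level statistics of professional basketball players) make it
possible to estimate the whole age function, provided the model can
(i) represent competing nonlinear shapes, (ii) let every individual have
their own rate of change, and (iii) relate those rates to covariates
without the generated-regressor bias of two-stage approaches. This package
implements a single joint Bayesian model for all three, plus the
changepoint machinery for estimating when growth turns into decline, and a
simulator that makes every fitter testable against known ground truth.

## Model structure

### Age-change families and transforms

Four families describe expected performance within one phase: power law
$\alpha\,\mathrm{age}^{\beta}$, exponential $\alpha e^{\beta\,\mathrm{age}}$,
logistic $\delta/(1+\alpha e^{\beta\,\mathrm{age}})$, and linear
$\alpha+\beta\,\mathrm{age}$. Power-law and exponential fits are linearized
(log performance against log age, or against age), with an explicit offset
added to performance before the log because metrics such as win shares can
be zero or negative. The default offset is the smallest value that lifts
the minimum of the data to 0.1; it is recorded in every fit's transform
metadata, since conclusions on the log scale depend on it. The noise model
is additive Gaussian on the transformed scale — equivalently multiplicative
log-normal on the raw scale — matching the linearized estimation strategy;
the logistic family has no linearization and is fit on the raw scale, and
is allowed to fail gracefully (reported as unavailable, mirroring the
common experience that a logistic decline phase cannot be estimated).

### Phase splitting and the changepoint

The two phases are separated either at a fixed cutoff age — default 27,
with the convention that the cutoff season itself still belongs to the
rising phase — or by estimating a per-player inflection age $\tau_p$ with a
Heaviside-gated broken-stick model: below $\tau_p$ only the pre-peak slope
is active, from $\tau_p$ on the post-peak slope, the segments meeting
continuously at the inflection. The step is exact (an indicator on the
slope terms), which is unproblematic for the Gibbs-type sampler used here;
a smooth approximation is unnecessary. $\tau_p$ follows a truncated normal
population distribution whose support defaults to ages 24–33, the range in
which individual inflection points are empirically observed; the population
mean has a uniform prior over those bounds. When the data carry no
changepoint signal the $\tau$ posterior reverts to something close to that
flat prior — the fit detects this (posterior nearly as wide as the prior,
or chains settling in unrelated places) and flags itself as non-identified
rather than reporting a spurious inflection.

### The latent-variable layer

Per-player rates $\beta_{1p}$ (pre-peak) and $\beta_{2p}$ (post-peak) are
treated as indicators of latent development and aging factors
$(\phi_{1p}, \phi_{2p})$, with both loadings fixed at 1 so the factors live
on the slope scale; the slope-indicator error sd is estimated. Covariates
enter as further indicators: phase-aggregated minutes per game loads on its
phase's factor, and the numeric position code — one observed variable —
loads on both factors in a single measurement equation. The factors are
bivariate normal with correlation $\rho$, the model's headline quantity.
Model 1 fixes the phase split at the cutoff and has one likelihood per
phase; Model 2 replaces the cutoff with the estimated $\tau_p$ inside a
single likelihood. Model 2 is substantially harder to sample (changepoints,
slopes and factors are estimated jointly), so its convergence diagnostics
are a mandatory part of the output.

Sign conventions: a larger $\phi_1$ means steeper growth; a larger
(less negative) $\phi_2$ means a shallower decline. A positive $\rho$
therefore means fast developers age gently.

## Priors and parameterization

The model structure leaves priors open; the package uses weakly
informative defaults, all on the transformed scale: Normal(0, 10²) for
location parameters (intercepts, mean slopes), half-Normal(1) for
hierarchical and residual sds, Uniform(−1, 1) for $\rho$, and a truncated
normal for $\tau_p$ as above. Covariate indicators are standardized
internally, so their intercepts get Normal(0, 1) and their error sds
half-Normal(1) truncated below at 0.1 — the truncation removes the
Heywood-case likelihood spike at zero error variance that otherwise lets a
factor collapse onto a covariate. Covariate weights $\gamma$ are reported
per unit of latent factor on the standardized indicator scale.

Two purely computational choices matter and deserve a record:

* **Centered likelihood parameterization.** With age (or log age) far from
  zero, a global intercept and the mean slope are nearly collinear and a
  Gibbs sampler crawls along the ridge. All linearized fits therefore
  sample a level-at-mean-x plus zero-centered slope deviations — an exact
  reparameterization of the same model — and recover the raw intercept as a
  derived node.
* **Least-squares starting values.** The remaining slow direction is the
  exchange between the mean slope and the average of the per-player
  deviations. Chains are started at pooled and per-player least-squares
  estimates (with a small deterministic per-chain jitter so split-R-hat
  keeps its power). Without this, a chain started at zero can park the
  slope mean inside the factor deviations; a zero-mean bivariate ellipse
  fit through the resulting off-center cloud drags $\rho$ toward an
  artefactual ±1.

Sampling is by JAGS (Gibbs/slice), with split-R-hat and effective sample
size computed for every monitored scalar. Thresholds R-hat < 1.01 and
ESS > 100 annotate fits; violations are surfaced as flags, never trigger
automatic reruns, and `extract_interaction()` refuses flagged fits unless
explicitly overridden. Default chain settings (1000 adaptation, 1000
burn-in, 1000 retained draws, 4 chains) are desk-scale; production-scale
settings in the tens of thousands are reached through `mcmc_config()`.
Thinning is a pure stride. Summaries are posterior means with central 95%
intervals using type-7 (linear-interpolation) quantiles.

## Model comparison

DIC is computed in-package from the retained draws and a deviance
evaluator: $\bar D$ is the mean deviance, $\hat D$ the deviance at the
posterior mean, $p_D = \bar D - \hat D$, $\mathrm{DIC} = \bar D + p_D$ —
the identity $\mathrm{DIC} = 2\bar D - \hat D$ holds exactly by
construction, and the conditional (per-player-slope) likelihood is the
focus. Because different families are fit on different scales, every
deviance is evaluated on the observed raw-performance scale, including the
log-normal Jacobian term for log-scale fits; without that correction,
cross-family DIC ordering would be meaningless. Failed fits appear in the
comparison table as unavailable rather than being dropped.

## The synthetic-data generator

`simulate_careers()` inverts the model's graph: factors
$(\phi_{1p},\phi_{2p})$ bivariate normal with correlation $\rho$; slopes
$\beta_{ip}=\phi_{ip}+e$; covariates $X_{ip}=\gamma_i\phi_{ip}+e'$ (minutes
per game, plus a position code that is pure noise by default, matching the
empirical null finding for position); seasons evaluated through the phase
family with noise on the transformed scale. Defaults encode the study
conditions: 400 players entering at ages 19–23, careers of 5–18 contiguous
seasons, cutoff 27, exponential growth then power-law decline, factor means
(0.06, −1.2) and sds (0.04, 0.5) on the transformed-slope scale, slope
measurement sds (0.01, 0.12), $\rho = 0.5$, minutes loadings (60, 5)
minutes per unit factor with sd-4 noise around phase means of 25 and 24
minutes. These values were chosen once to give careers that look like
elite-sport records (growth from roughly 3 to 5 performance points by the
peak, a 30–40% decline over the following decade, minutes-performance
correlations near 0.5) and are not revisited.

Two trajectory modes exist because the two changepoint treatments imply
different generative processes. `phase` mode (the default) mirrors the
two-likelihood structure exactly: global per-phase intercepts with a
Heaviside switch at the cutoff, which can leave a per-player discontinuity
at the cutoff — precisely the assumption Model 1 makes. `hinge` mode
generates continuous piecewise-linear careers bending at $\tau_p$, the
process the broken-stick model and Model 2 estimate. Fitting Model 1 to
hinge data is well specified only when all players share one inflection
and age is centered there (`center_age`), which is how the cross-model
consistency check is constructed.

What the simulator deliberately does not emulate: gap seasons and trades,
season-level variation in minutes within a phase, score-keeping changes
across eras, and the selection processes of a real league. An optional
dropout mechanism (career ends early with probability tied to the aging
factor) exists, off by default, for studying survivorship distortion of the
post-peak tail. Passing tests on synthetic data therefore demonstrate that
the estimators recover the parameters of this generative structure — not
that real careers follow it.

## Data handling rules

CSV input is validated row-wise: ages outside 17–45, negative minutes,
unknown position codes and non-finite performance are rejected with a
per-row report; duplicate player-season pairs are a hard error. Positions
use a fixed guard-to-center ordinal coding (PG=1 … C=5), exposed and
replaceable in `encode_position()`; treating position as ordinal rather
than dummy-coded is a documented package choice, since only a single
numeric covariate enters the measurement model. Phase aggregation of
covariates defaults to the mean (a `sum` option exists); a player with no
seasons in a phase gets a missing value, never zero, and missing covariate
indicators drop out of that player's measurement equations rather than
being imputed. Players with fewer than 2 seasons in a phase (4 for
changepoint fits) are pooled to the population slope instead of receiving
an unidentifiable individual one.

## Problem sizes and known limitations

The bundled tests and the acceptance script run, per fit, 2 chains with a
few hundred to ~1800 retained draws on 50–400 simulated players — sizes
chosen so the full recovery studies (20 replicates at n = 400 for the
$\rho$ study; 10 replicates at n = 200 for family selection) complete on a
single CPU in minutes while still leaving Monte-Carlo error comfortably
inside the tolerances being checked.

Known limitations: the global slope means are weakly identified relative to
the phase intercepts (a property of the model, visible as low ESS on those
coordinates — the deviations, $\rho$ and $\gamma$ are what mix well); the
factor-variance/slope-noise split is only softly identified at small n,
which can widen $\rho$ intervals; covariates are modeled as indicators of
the factors, not causes (a MIMIC-style variant is a possible extension,
and no causal reading of the minutes-played weights is licensed); the error
matrix of the measurement model is assumed diagonal; and DIC is the only
comparison criterion provided.
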