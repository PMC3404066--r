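---
title: "Water flux and zero-inflated pupal counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water flux and zero-inflated pupal counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `aedesflux`: the
survey data model, the water-flux covariates, the hierarchical
zero-inflated Poisson (ZIP) mixed model and its MCMC sampler, the
fixed-effects model comparison, and the synthetic-survey generator used
to exercise all of it. It also records the design decisions that were
genuinely open and why they were settled the way they were.

## The data and the flux covariates

A survey dataset is a static container table (household, capacity,
type, location, lid status) plus one record per container per survey:
wet status, water volume as a percentage of capacity, presence of I/II
instars, an ordinal abundance category for III/IV instars (0, 1–10,
11–100, 101–1000, 1000+), a pupal count, and predator presence.
Containers are *large* when capacity is at least 500 L, otherwise
*small*; the published classes ("greater than 500 L" / "less than
500 L") leave the boundary itself unassigned, and we place 500 L in the
large class.

Water flux between consecutive surveys is measured in percentage points
of capacity (not relative to the previous volume): a change of at least
+20 points is an *increase* event, at most −20 points a *decrease*, and
anything in between *stable*. Both thresholds are inclusive. Dry
containers stay in the data with volume 0 and zero pupae, and they
participate in flux: refilling a dry container is an increase event.
Because flux needs a previous survey, model data cover surveys 2
onward, and only containers examined at every survey (containers
switched to other uses mid-study are excluded, as in the survey the
package is modelled on).

Per-day event probabilities divide the per-interval event frequency by
the interval length (2 days by default). The geometric alternative,
solving $1-(1-p)^d = \hat p_{\text{interval}}$, differs by less than
0.005 at the observed magnitudes and is available via
`daily_flux_probability(..., method = "geometric")`. Reported
percentages are rounded half-up to one decimal, matching the convention
of printed survey tables (base R's round-half-even would turn a
2.25-fold rise into 2.2 instead of the reported 2.3).

## The hierarchical ZIP model

For container $i$ in household $j$ at survey $k$, the pupal count
$Y_{ijk}$ is zero-inflated Poisson. We parameterize the zero component
through the *productive-state* probability $\pi_{ijk}$:

$$\text{logit}(\pi_{ijk}) = \beta_0 + \beta_1 C1_{ijk} + \beta_2
C2_{ijk} + \beta_3 k + u_i + v_j$$

$$\log(\lambda_{ijk}) = \delta_0 + \delta_1 C1_{ijk} + \delta_2
C2_{ijk} + \delta_3 k + w_i + z_j$$

$$P(Y=y) = (1-\pi)\,1\{y=0\} + \pi\, e^{-\lambda}\lambda^y/y!$$

so the structural-zero probability is $1-\pi$. **Why this orientation:**
with the reported coefficient signs (zero-component intercept around
−3.6, positive temporal trend), only the productive-state reading
reproduces the observed data pattern — 77–95% of container-surveys
negative for pupae, per-survey container positivity of roughly 5–21%
*rising* over the study, and cumulative container positivity near 46%.
Under the alternative reading (the same linear predictor as the logit of
the structural-zero probability itself) those defaults would imply
nearly all containers positive at every survey, which contradicts the
descriptives the model is meant to explain. The standalone
`zip_log_pmf(y, p, lambda)` keeps the conventional parameterization
with `p` the structural-zero probability; the hierarchical model maps
its linear predictor through $p = 1 - \text{logit}^{-1}(\eta)$.

Covariates are the two flux dummies ($C1$ increase, $C2$ decrease;
stable is the reference) and a temporal trend. The trend covariate is
the survey index $k$ (2–15), uncentered; calendar day is available via
`build_model_data(..., trend = "day")` since the original description
does not say which was used. Container and household effects enter as
separate additive (crossed) terms in both components, as written; we do
not impose nesting.

Priors follow the original analysis protocol: fixed effects are normal
with mean 0 and precision $10^{-4}$; random effects are normal with
mean 0 and component-specific precisions carrying Gamma(0.01, 0.01)
priors (shape–rate). All four random-effect vectors are centered on
zero, so "a container with a random effect significantly greater than
the overall mean" is operationalized as a 95% credible interval whose
lower bound exceeds zero.

## The sampler

`fit_zip_mixed()` uses data augmentation with Metropolis-within-Gibbs,
implemented in C++:

1. **Latent productive indicators.** For every zero count, the
   indicator $S_{ijk}$ is drawn from its exact conditional,
   $P(S=1\mid y=0) = \pi e^{-\lambda} / (1-\pi+\pi e^{-\lambda})$,
   computed on the log scale. Positive counts force $S=1$. Given $S$,
   the zero component is a Bernoulli-logit likelihood over all rows and
   the count component a Poisson likelihood over productive rows only.
2. **Fixed and random effects** are updated by scalar random-walk
   Metropolis with cached linear predictors, so each proposal costs one
   pass over the affected rows. Proposal scales adapt per parameter by
   Robbins–Monro toward 44% acceptance (the scalar-update optimum) with
   step $t^{-0.6}$, and adaptation is frozen at the end of burn-in so
   the post-burn-in chain is a genuine Markov chain.
3. **Random-effect precisions** have conjugate gamma full conditionals
   and are Gibbs-updated.

The original analysis used WinBUGS, whose internal samplers are not
specified; any correct scheme is acceptable, and ours is validated
against an independent two-dimensional grid-integration oracle on a
reduced model (random effects clamped, intercepts free): posterior
means agree within three Monte Carlo errors. A second reduction check
pins the productive probability near 1 and recovers the Poisson GLM
maximum-likelihood estimates. The additive confounding between an
intercept and the mean of its random-effect vector is anchored only by
the zero-centered prior; a dedicated test checks that
$\delta_0 + \bar w$ is stable across seeds.

The full published protocol — burn-in 5,000, then 100,000 iterations
thinned by 10 (10,000 stored draws) — is the default of
`mcmc_config()`. Tests and the acceptance script use shortened chains
(burn-in 1,000–2,000; 10,000–50,000 iterations), sizes chosen to make
the whole suite and parameter-recovery experiments convenient to run
routinely; the protocol-length run remains a single configuration
change. Posterior summaries report the mean, equal-tailed 2.5/97.5
percentile credible intervals (the WinBUGS convention), batch-means
Monte Carlo error with 50 batches, and the MCE/SD ratio with the
< 0.05 sufficiency rule. Degenerate (constant) chains are flagged
rather than summarized. All randomness flows through R's RNG, so a
seed makes fits bit-reproducible.

## Fixed-effects model comparison

The pre-screening step fits Poisson, negative binomial (mean–dispersion
parameterization; Poisson limit as $r\to\infty$) and ZIP regressions on
the same design by maximum likelihood — `stats::glm` and `MASS::glm.nb`
where they apply, with a direct BFGS optimization for the ZIP fit and as
a fallback for the negative binomial when the dispersion diverges on
equi-dispersed data. Models are compared by AIC ($-2\log L + 2k$) and
the uncorrected Vuong statistic
$V = \sqrt{n}\,\bar m / s_m$ with $m_i = \log f_1(y_i) - \log f_2(y_i)$;
$|V| > 1.96$ is decisive, anything else indeterminate. Identical
pointwise fits make $V$ undefined (zero variance) and raise an error by
design. The comparison is fixed-effects only — the standard pre-screen
before committing to the mixed model; mixed-effects Poisson/NB
variants and ZINB are out of scope.

## The synthetic generator

The generator emulates the targeted study design: 41 households;
containers per household zero-truncated Poisson with mean 4.8 (the
rate solved numerically so the *truncated* mean is 4.8); a 119/171
probability of being large; container types and capacities drawn to
match the published inventory mix (moulded tanks of 2000 L, cylindrical
tanks 1000–2000 L, box tanks, jars/drums, small jars under 100 L); 15
surveys at 2-day intervals.

**Water dynamics.** Each container evolves daily: a fill event
(probability 0.05/day large, 0.11/day small) adds U(20, 60) percentage
points capped at 100; otherwise a draw-down event (0.07 large, 0.13
small) removes U(20, 60) points floored at 0; on event-free days the
container loses a constant consumption rate drawn once per container
from U(0, 1.75) points/day. Containers start wet with probability 0.80
at U(30, 85)% of capacity. The event magnitudes, consumption rates and
initial conditions are not published quantities; they were calibrated
once, before any tests were written, so that (a) the realized daily
≥20-point increase rate for large containers is 0.05 ± 0.01 and (b) the
per-survey wet fraction stays within ±10 points of the published
72.8–82.1% band. A homogeneous per-day consumption draw of up to 5
points/day — a natural first choice — fails (b): it drains the
container population to ~50–57% wet by the final surveys regardless of
initial conditions, so consumption was made a smaller per-container
rate, which also reflects real between-household heterogeneity in water
use.

**Counts.** Pupal counts are generated from the inferential ZIP mixed
model itself, not from a mechanistic egg-bank/hatching simulation: flux
dummies are derived from the trajectories with the same ≥20-point rule
the analysis applies, random effects are drawn once per
container/household, and each wet container-survey draws its productive
state and Poisson count. True parameters default to the published
posterior means ($\beta = (-3.58, -0.48, 0.16, 0.04)$,
$\delta = (1.45, 0.95, 0.06, 0.06)$, variances 2.43/0.06 and
0.78/0.03). Dry records are forced to zero pupae (a physical
constraint the fitted model does not know about); this makes the
generator slightly misspecified relative to the fitted model for the
zero component, visible as mild undercoverage of the zero-component
intercept and trend in recovery experiments, while the count component
is essentially unbiased. Larval-stage fields are produced by simple
presence models anchored to the pupal count (I/II presence probability
$\text{logit}^{-1}(-2.3 + 1.3\cdot 1\{y>0\})$; III/IV from a Poisson
latent count $1.5y + 0.25$ binned into the ordinal categories); they
exist so descriptive tables have all stages, and carry no deeper
ecological claim. Predator presence is 2% of wet records.

What passing recovery tests show — and what they do not: with 20
study-scale replicates and shortened chains, pooled 95% credible
interval coverage of the eight fixed effects is above 80%, the positive
filling effect on counts ($\delta_1$) is detected with posterior
probability > 0.95 in every replicate, and household random effects are
(correctly) never significant. Because counts come from the model
family itself, these experiments validate the *estimation machinery*,
not the ecological realism of ZIP counts for real containers; rainfall
forcing, predation, overcrowding and egg-bank dynamics are all outside
the generator.

## Numerical choices and degenerate inputs

* ZIP pmf evaluation uses pairwise log-sum-exp for the zero term; it is
  exact at the boundaries ($p \in \{0, 1\}$, $\lambda = 0$) and stable
  for extreme $\lambda$.
* Proposals that overflow the Poisson mean produce $-\infty$
  log-likelihood deltas and are rejected rather than propagating
  non-finite values; any non-finite stored draw aborts the fit with a
  diagnostic.
* `glm.nb`'s dispersion iteration diverges when data are equi- or
  under-dispersed; the fallback optimizes the exact likelihood over
  $(\text{coefficients}, \log r)$ with $\log r$ capped at 15, where the
  negative binomial is numerically Poisson.
* Aliased (constant) covariate columns in the GLMs get coefficient 0
  rather than NA so per-observation likelihoods stay defined.
* Batch-means MCE uses 50 batches, dropping the remainder at the front
  of the chain; chains shorter than twice the batch count are rejected.
* CSV reading reports malformed rows by file line number (accounting
  for provenance comment lines) and validation errors list every
  violated invariant at once.

## Scope and limitations

The package deliberately omits: GIS/spatial random effects, rainfall
covariate modelling (weather series can ride along as pass-through
columns), *Culex* modelling beyond storage, predator ecology, ZINB and
mixed-effects NB/Poisson variants, and DIC/WAIC comparison of the
hierarchical fit. The Vuong variant is the uncorrected statistic. The
sampler is single-chain; between-chain diagnostics (e.g. R-hat across
independent seeds) are left to the user, who can run `fit_zip_mixed`
with different seeds and compare — determinism per seed makes this
straightforward.
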