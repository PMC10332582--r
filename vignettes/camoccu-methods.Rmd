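---
title: "Models and methods in camoccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in camoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the defaults and why they
were chosen, the numerical decisions, and what the synthetic-data tests do
and do not demonstrate about real data.

## From photographs to detection histories

A camera-trap record table (station, species, timestamp) is reduced to one
*independent detection* per station, species and calendar day
(`filter_independent`). The pooling bin is the calendar day, not a rolling
24-h window: fixed bins are order-independent, idempotent, and match the
convention of counting "independent detections" per 24-h period. Guild
pooling (`pool_guild`) is applied *before* the day filter, so a guild
detection day is any member's record.

Histories (`build_history`) collapse each station's deployment into
consecutive 7-day occasions starting at that station's activation date.
Deployment-aligned (rather than calendar-aligned) blocks were chosen
because multi-reserve surveys typically run in disjoint calendar windows; a
global calendar grid would manufacture structural missingness. The final
partial block keeps its remaining days as reduced effort rather than being
truncated, because per-occasion effort is itself a candidate detection
covariate. A cell is missing exactly when effort is zero; this invariant is
enforced on the round-trip CSV readers as well. Weekly pooling exists to
thin the zeros in the matrix: daily occasions for a species detected about
once per station-month are almost all zero, which destabilizes fitting.

## Covariates

All numeric covariates are z-scored ((x − mean)/sample SD) so slope
magnitudes are comparable and the weakly-informative priors below are
meaningful. The collinearity screen flags pairs with |r| strictly above
0.65 and *reports* them; it never drops a column, because choosing which
member of a collinear pair to keep is an ecological decision, not a
numerical one. Landscape metrics can be summarized by PCA on the
correlation matrix (the metrics are heterogeneous in units, so covariance
PCA would let one metric dominate); components with eigenvalue > 1 are
retained (Kaiser rule), and the sign of PC1 is anchored so the
forest-amount style metric (the first column by convention) loads
negatively — PCA signs are arbitrary, and fixing one makes "negative scores
= more, better-connected forest" stable across runs. Quadratic terms are
squares of the already-scaled column and are *not* re-scaled after
squaring, so the turning point of a quadratic response,
x\* = −β₁/(2β₂), stays interpretable on the scaled axis.

## The occupancy likelihood and its two engines

The single-season model assumes closure (the site's true state does not
change over the season), independence across sites, and conditional
independence of occasions given the state. The site likelihood marginalizes
the latent state:

L_i = ψ_i ∏_j p_ij^y (1−p_ij)^(1−y) + (1−ψ_i)·[no detection at i],

with missing occasions contributing nothing. The all-zero branch is
combined in log space (log-sum-exp); linear predictors are clipped to
|η| ≤ 35 before the inverse logit, which keeps likelihoods finite at
boundary fits with error below double precision (plogis(35) differs from 1
by ~6e−16).

**Maximum likelihood** (`fit_ml`) runs BFGS from five deterministic starts
(both intercepts at the logit of the naive rates, offset by 0/±1 in the
four sign combinations; slopes at zero), then polishes with Newton steps on
a central-difference gradient until the gradient sup-norm is below 1e−5 —
that threshold is also the `converged` flag. Deterministic multistart was
preferred over random restarts purely for reproducibility. Standard errors
come from the inverse observed information (the polishing Hessian reused).
Fits with any fitted probability above 0.9999 carry a boundary warning.

**MCMC** (`fit_bayes`) samples the same marginal likelihood plus
Normal(0, 2.5) priors on every coefficient. On z-scored covariates this
prior is effectively uninformative for plausible effect sizes while
preventing the separation pathologies a truly flat prior allows. The
sampler is an adaptive random-walk Metropolis: the proposal scale is tuned
toward the 0.234 acceptance optimum during burn-in (default half of 30,000
iterations per chain, 3 chains) and then frozen, so retained draws form a
valid Markov chain. Acceptance-rate targeting is this sampler's
calibration knob — gradient-based samplers' controls (e.g. target
acceptance of 0.99 during adaptation) have no direct analogue here, and the
achieved acceptance rates are reported on the fit. Chains start at the ML
estimate with fixed offsets; convergence is summarized by split-chain
R-hat with the conventional 1.1 threshold (a warning, not an error).
Credibility intervals are equal-tailed 2.5/97.5% posterior quantiles.

## Two-species conditional co-occurrence

The ψBa parameterization conditions the subordinate species B on the
dominant species A: occupancy ΨA, ΨBA, ΨBa; detection pA (A alone), pB (B
alone), rA (A, both present), rBA/rBa (B, both present, A detected / not
detected). The site likelihood sums the four latent states, each weighted
by its occasion-product detection terms; states inconsistent with an
observation vanish through zero detection products. The rBA/rBa switch is
resolved *per occasion* — B's detection on occasion j depends on whether A
was detected on that same occasion j — which is the standard convention
when the time grain is not otherwise specified. The 2×2 variant grid
aliases parameters (ΨBA = ΨBa and/or pA = rA, pB = rBA = rBa), giving
4/5/7/8 free parameters; covariates are allowed on the ψB-side linear
predictors (shared slopes, separate intercepts), mirroring the practice of
carrying the best single-species occupancy covariates into the
co-occurrence stage.

Φ = ΨBA/(ΨA·ΨBA + (1−ΨA)·ΨBa) is the ratio of joint occupancy to its
independence value; δ = rBA/(rA·rBa) its detection analogue. Both are ratio
statistics with skewed sampling distributions, so uncertainty is assessed
by seeded parametric bootstrap (default 500 refits) rather than the delta
method. Co-occurrence selection uses AICc with n = number of sites — the
frequentist pathway — while single-species Bayesian selection uses elpd;
the package keeps both because the two stages of the motivating workflow
use different engines, and a shared likelihood core keeps them consistent.

## Model selection

AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with Akaike weights and the ΔAICc < 2
retention flag. The Bayesian pathway computes PSIS-LOO elpd in-package:
per-site importance ratios 1/L_i(θ_s), generalized-Pareto smoothing of the
top 20% of log-weights (Zhang–Stephens profile fit), truncation at the raw
maximum, and a k̂ > 0.7 reliability flag. Δelpd to the best model is
reported with SE(Δ) = √(n·var(pointwise differences)) and the
"less support when |Δ| > SE(Δ)" flag. elpd weights are exp-renormalized
(pseudo-BMA); no Bayesian-bootstrap correction — the simplest defensible
scheme, stated here because "elpd weight" is ambiguous in the wild.

The p-first sequential strategy models detection first (one candidate term
at a time against ψ(.)), fixes the winning p-structure, then ranks
occupancy terms the same way. It is a pure function of (data, candidates,
seed).

## Goodness of fit

The MacKenzie–Bailey statistic compares observed and expected counts of
detection histories: sites are grouped into cohorts sharing a missingness
pattern, each observed unique history contributes (O−E)²/E with
E_h = Σ_i Pr(h | θ, x_i) over the cohort, and one pooled never-observed
cell per cohort carries the remaining expectation — so no 2^J enumeration
is needed. With many occasions, most observed histories are nearly unique
and the statistic's magnitude is dominated by tiny expected counts; it is
therefore only interpretable against a simulated reference, never against
a χ² table. The ML pathway uses a parametric bootstrap (simulate at θ̂ with
the observed missingness, refit from the observed fit as start point — a
speed/stability choice — and recompute). The Bayesian pathway computes, per
posterior draw, the statistic for the data and for a replicate simulated at
that draw (Bayesian P = fraction of draws where the replicate exceeds the
observed; > 0.05 passes). Both report lower-tail/two-sided companions so
underdispersion is visible rather than silently corrected. A
proportion-of-zeros discrepancy is available as an alternative statistic
(`statistic = "zero_prop"`) since zero-inflation is the most common failure
mode; the χ² form is the primary.

## Spatial diagnostics

Occupancy residuals are conditional-minus-marginal occupancy:
Pr(z_i = 1 | history) − ψ̂_i for ML; for Bayesian fits the residual is
averaged over draws using the analytic conditional probability rather than
sampled latent states — the expectation is identical and the extra Monte
Carlo noise disappears. Global Moran's I uses row-standardized inverse
distance weights with no cutoff (the parameter-free default; the weight
scheme is otherwise a free choice), with the normal-approximation variance,
and haversine distances when coordinates are geographic. The correlogram
bins pairs into equal-count distance classes with binary in-bin weights
and wraps a permutation envelope (residuals shuffled over sites) around
the per-bin I; bins with fewer than 20 pairs are flagged. A binned
correlogram with an explicit envelope was preferred over a smoothing-spline
correlogram: same inferential target, no smoothing-basis dependency, and
the envelope makes "no pattern" a testable statement.

## The synthetic-data generator

`sim_scenario`/`simulate_single`/`simulate_cooc` invert the likelihoods
exactly (latent Bernoulli state, then conditional Bernoulli detections,
with the per-occasion rBA/rBa switch in the paired generator), which is
verified by enumeration tests comparing empirical history frequencies with
likelihood values. The preset `scenario_middle_cauca()` encodes the
design constants of a three-reserve montane survey: 58 stations, weekly
occasions capped at 19, intercept-only truth ψ = 0.68 and p = 0.15, and
deployment lengths drawn Normal(130, 24) days truncated at ≥ 30 (only mean
± SD of deployment duration is typically reported, so a truncated normal
is the least-committal choice), converted to trailing missingness; random
mid-survey gaps (camera theft or failure) are available via the
`missingness` rate. The generator emulates the *statistical* structure of
such surveys — imperfect detection, ragged effort, covariate-linked
Bernoulli responses. It does not emulate animal movement, spatially
autocorrelated occupancy surfaces, temporal non-closure, misidentification,
or detector-level heterogeneity beyond its covariates; passing
recovery tests therefore demonstrates the estimators are correct for the
model, not that the model is correct for any particular forest.

## Problem sizes and numerical tolerances used in the test suite

Enumeration oracles run at J ≤ 4 (single species) and J ≤ 3 (paired) with
tolerance 1e−10. The grid-search oracle for the intercept-only MLE uses a
1e−3 step, n = 20 sites. Recovery runs use n = 500 × J = 19 (single,
tolerance 0.05), n = 800 × J = 12 (full 8-parameter model, tolerance
0.07), and 50 replicates of n = 200 for Wald coverage (≥ 40/50). GOF
calibration uses 20 runs × 200 bootstrap replicates at n = 60; the
posterior-predictive power check uses the 0.05/0.6 detection mixture at
n = 300, J = 12 — the same scale as its well-specified companion. MCMC
tests run short chains (1,200–2,500 iterations); the 30,000-iteration
default is for analyses, not tests. These sizes were chosen as the
smallest at which the asymptotic checks are stable.

## Known limitations

Single season only (no dynamic occupancy); no random effects on ψ or p
(with only three blocks, a block random effect has too few levels to
estimate a variance usefully — blocks belong in the fixed effects); no
spatially explicit occupancy (the spatial module diagnoses residual
autocorrelation, it does not model it); co-occurrence is two-species,
asymmetric and frequentist; PSIS-LOO assumes pointwise likelihoods from a
well-mixed posterior — check R-hat and k̂ before trusting elpd ranks. The
MacKenzie–Bailey p-value inherits the usual caveat of posterior-predictive
checks: it uses the data twice and is conservative.
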