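---
title: "Inverse-probability weighting for staggered treatments: models, weights, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse-probability weighting for staggered treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvtpanel)
```

## The problem

Panel studies of policy adoption typically observe units (states, firms,
clinics) at times $t = 1, \dots, T$ with a binary treatment $D_t$ that is
*absorbing*: once a unit adopts, it stays treated. Adoption is staggered, so
units are indexed by their adoption time $G = \min\{t : D_t = 1\}$ (with
$G = \infty$ for never-adopters). Two traditions analyze such data:

* **Difference-in-differences (DiD)** compares outcome *changes* between
  adopters and non-adopters. Its identifying assumption, parallel trends,
  tolerates unmeasured confounders that shift the *level* of the outcome but
  not its trend.
* **Time-varying treatment (TVT) methods** from longitudinal biostatistics
  model the probability of treatment at every time point and reweight the
  sample. Their identifying assumption, sequential exchangeability, is a
  conditionally randomized experiment at each time given measured treatment
  and covariate history. It tolerates *time-varying* confounders — even ones
  affected by earlier treatment (treatment–confounder feedback), which break
  regression and matching adjustment.

`tvtpanel` implements both families, hybrids of the two, a
structural-equation simulator with known truth, and a Monte Carlo harness
that measures each estimator's bias and variability where its assumption
holds or fails.

## Estimands

For a static strategy $\bar d = (d_1, \dots, d_T)$ let $Y_t(\bar d)$ be the
potential outcome. Under absorbing treatment the relevant strategies are
"initiate at $g$": $\bar d^{(g)} = (\mathbf 0_{g-1}, \mathbf 1_{T-g+1})$.
The package's central estimands are

* ATE-type contrasts $E[Y_t(\bar d) - Y_t(\bar d')]$, reported through
  marginal structural model (MSM) coefficients, and
* group–time average effects on the treated,
  $\mathrm{ATT}(g,t) = E[Y_t(\bar d^{(g)}) - Y_t(\mathbf 0_T) \mid G = g]$
  for $t \ge g$.

## The synthetic world

`simulate_population()` draws from one of four structural-equation setups,
all with independent standard-normal errors, a logistic treatment equation,
and a confounding-strength multiplier $m$ scaling every confounder loading
(defaults in `default_coefficients()`):

| | confounding | sequential exchangeability given $X$ | parallel trends |
|---|---|---|---|
| Setup 1 | time-invariant, measured ($X$) | holds | holds |
| Setup 2 | adds time-invariant unmeasured $U$ | fails | holds |
| Setup 3 | time-varying $U_t$ with proxy $X_t$, feedback $D_{t-1} \to X_t$, outcome autoregression | holds | fails |
| Setup 4 | adds time-varying unmeasured $W_t$ | fails | fails |

Setups 1–2 use $X = \varepsilon_X$, treatment log-odds
$-1 - 0.5\,m X\,(-\,0.5\,m U)$ and outcome
$Y_t = 0.5\,m X\,(+\,0.5\,m U) + 0.5 D_t + 0.1 X D_t + \varepsilon_{Yt}$.
Setups 3–4 use AR(1) latents $U_t$ (and $W_t$),
$X_t = 0.5 U_t + 0.5 D_{t-1} + \varepsilon_{Xt}$, treatment log-odds
$-1 - 0.5\,m X_t - 0.5\,m X_{t-1}\,(-\,0.5\,m W_t) + 0.5 D_{t-1}$, and
$Y_t = 0.5\,m U_t\,(+\,0.5\,m W_t) + 0.5 D_t + 0.5 Y_{t-1} + 0.1 U_t D_t +
\varepsilon_{Yt}$. Every setup has treatment-effect heterogeneity through
the $0.1 \cdot (\text{modifier}) \cdot D_t$ interaction.

Implementation details that the tests pin down:

* **Time-1 initialization.** At $t = 1$ every lagged term is *deleted* from
  its equation, not imputed as zero. The two conventions coincide
  numerically here, but the code implements deletion, and a test asserts
  that coefficients multiplying only lagged quantities cannot affect $t=1$.
* **Absorbing rule.** Once $D_{t-1} = 1$ the treatment equation is ignored
  and $D_t = 1$. The $+0.5 D_{t-1}$ term in the Setup 3–4 treatment
  equation is retained literally in the linear predictor but is vacuous —
  the absorbing rule always overrides it.
* **Common random numbers.** All exogenous draws are stored in the
  population object. `simulate_counterfactual()` replays the structural
  recursion with treatment fixed, reusing those draws, so evaluating each
  unit at its factual treatment path reproduces the factual outcomes
  bit-for-bit, and truth computations are exact up to Monte Carlo error in
  the population mean.
* **Truth by intervention.** `compute_truth()` simulates each initiation
  strategy once on the whole population; $\mathrm{ATT}(g,t)$ averages
  potential-outcome differences over the units whose *natural* adoption
  time is $g$. An empty group yields a flagged undefined estimand, never a
  silent zero. The reference design uses a $10^6$-unit population; the test
  suite and acceptance script use $2 \times 10^5$, which keeps truth error
  an order of magnitude below estimator Monte Carlo error at the study's
  sample size.

What the generator does **not** emulate: missing data, unbalanced panels,
discrete outcomes, non-absorbing (on/off) treatment paths, anticipation, or
clustered/serial dependence beyond the stated AR structures. A green test
therefore certifies the estimation machinery against this stated world, not
robustness to those complications.

## Treatment models and weights

`fit_propensity_models()` fits, at each time $t$, a logistic regression of
treatment *initiation* on covariate terms among the at-risk set (units with
$D_{t-1} = 0$; continuation is deterministic under absorbing treatment), and
an intercept-only numerator model whose fit is the at-risk initiation
proportion. The covariate specification mirrors the generating treatment
equation: concurrent $X$ in Setups 1–2, concurrent plus one-period-lagged
$X$ in Setups 3–4 (`default_covariate_lags()`); it is user-configurable
since the "right" functional form is an assumption, not an observable.

**Stabilized ATE weights** (`compute_ate_weights()`) for outcome horizon $t$:

$$W^{ATE}_i(t) = \prod_{k=1}^{t}
  \frac{P(D_k = d_{ik} \mid \bar D_{k-1} = \bar d_{i,k-1})}
       {P(D_k = d_{ik} \mid \bar D_{k-1} = \bar d_{i,k-1}, \bar X_{ik})},$$

with every factor after the unit's initiation equal to 1. The product stops
at the outcome time: the treatment pattern entering the MSM for $Y_t$
conditions only on $D_1,\dots,D_t$, and the weighted density of each
pattern is then covariate-free, which is exactly what weighted least
squares needs.

**ATT weights** (`compute_att_weights()`) for target group $g$ at time $t$
give weight 1 to $G = g$ units, 0 to invalid units, and to each valid
control the product of (probability of the *target* strategy's treatment
value at $k$, at the control's own covariates) over (probability of the
control's own value). With one period this is the familiar odds
$p(X)/(1-p(X))$.

*The product horizon is where the design was genuinely open*, and the
package resolves it by a density-matching argument. A control group is a
*selected* set: never-treated units are selected on remaining untreated
through $T$, so their covariate density carries factors $1 - p_k(x)$ for
every $k \le T$; not-yet-treated controls (for outcome time $t$) are
selected only through $t$. The weight denominator must undo precisely the
selection that defines the group, so the package runs the product to $T$
for never-treated controls and to $t$ for not-yet-treated controls. The
truncated-at-$t$ alternative for never-treated controls is measurably wrong
in this world: in Setup 1 — no unmeasured confounding at all — it produced
a Monte Carlo bias of $-0.13$ (16 standard errors) for the
outcome-weighting estimator, while the matched-horizon weights are
unbiased.

`normalize_att_weights()` rescales control weights to sum to the number of
treated units (idempotent); normalized weights make the weighted-regression
slope and the difference-of-weighted-means routes coincide exactly, and
both are computed and cross-checked.

Numerical policy: fitted probabilities are used as-is. An exact 0 or 1
(separation), or a time point whose at-risk set shows no variation, raises
a positivity error naming the unit/time — silent clipping would hide a
violated assumption. An optional trimming flag was considered and rejected:
none of the estimators here needs it in the stated world, and trimming
changes the estimand.

## Estimators

* `fit_msm()` — weighted least squares of $Y_t$ on $(D_1, \dots, D_t)$ with
  ATE weights at horizon $t$. Under absorbing treatment the design is
  saturated ($t + 1$ realizable patterns, $t + 1$ coefficients), so each
  slope is a contrast of adjacent initiation strategies; a missing pattern
  raises a rank error rather than returning a silently extrapolated fit.
* `estimate_att_tvt_outcome()` — group mean of $Y_t$ minus ATT-weighted
  control mean. Works for $g = 1$: outcome weighting needs no pre-period,
  which is the one estimand the change-score tradition must discard.
* `estimate_att_tvt_changescore()` — the hybrid: ATT-weighted regression of
  $\Delta_{g,t} = Y_t - Y_{g-1}$ on the group indicator. Differencing
  removes level-only confounding (measured or not); the weights handle
  measured time-varying confounding. Undefined for $g = 1$.
* `estimate_att_gt_did()` — staggered-adoption DiD on change scores with
  never- or not-yet-treated controls, first-period adopters dropped.
  "Adjusted" fits a linear model of $\Delta$ on the first-period covariate
  among controls and averages treated residuals (an outcome-regression
  flavor; doubly robust machinery is out of scope). Optional sampling
  weights make it a hybrid.

The study harness passes *horizon-$T$* stabilized ATE weights as the
gt-did sampling weights: a single weight set serves every estimand, and the
full product is what de-confounds the never-treated control group (the
horizon-$t$ alternative left the weighted estimator 7 standard errors
biased in Setup 3, where it should succeed).

One honest caveat, visible at Monte Carlo resolution: in the ATE-weighted
pseudopopulation the weighted DiD targets the *population* strategy
contrast, not the ATT. With effect heterogeneity the two differ by
$0.1 \cdot E[\text{modifier} \mid G = g] \approx 0.02$ at $m = 1$ — about
one part in twenty-five of the effect, at or below 3 Monte Carlo standard
errors at 100 replicates. It is a property of the estimator, not a bug; the
test matrix evaluates the canonical never-treated configuration, and the
gap is documented here rather than absorbed into a tolerance.

## The simulation study

`run_study()` reproduces the reference design by default: populations of
$10^6$ per (setup, $m$), 100 samples of 3000 units, $T = 4$, the full
estimator roster, truth computed once per cell. "Standard error" in the
results table is the Monte Carlo standard deviation of the point estimates
(denominator $n - 1$); the package takes that reading because no
within-dataset standard errors are produced at all (by design — the study's
uncertainty summary is across replicates). Replicate-level failures
(degenerate cells, separation) are logged and skipped, never fatal, and the
summary reports how many replicates each cell lost.

Seeding: one master seed; `set.seed(master)` followed by one
`sample.int(2^31 - 1)` draw per cell population and per replicate, in
cell-major order, so any single replicate can be regenerated in isolation.

The headline qualitative result the acceptance suite checks, at $m = 1$,
$\mathrm{ATT}(2,2)$, never-treated controls: outcome weighting fails exactly
where sequential exchangeability fails (Setups 2, 4); the change-score
hybrid fails only when both assumptions fail (Setup 4); unweighted DiD
fails exactly where parallel trends fails (Setups 3, 4); ATE-weighted DiD
fails only in Setup 4. Bias grows with $m$ and Monte Carlo SE grows with
lag $t - g$.

## Worked example

```{r example, eval = FALSE}
cfg <- structural_config(setup = 3, m = 1)
pop <- simulate_population(cfg, 2e5, seed = 1)
true_att(pop, g = 2, t = 2)

panel <- draw_sample(pop, 3000, seed = 2)
models <- fit_propensity_models(panel, default_covariate_lags(3))
w <- normalize_att_weights(compute_att_weights(panel, models, 2, 2, "never"))
estimate_att_tvt_changescore(panel, w, 2, 2)
```

## Known limitations

* Static strategies only; no dynamic (covariate-responsive) regimes.
* Point estimation only: no within-dataset standard errors, confidence
  intervals, or bootstrap.
* Logistic main-effects treatment models; no machine-learning propensities.
* The simulator is absorbing-only, though the weight formulas accept any
  static strategy encoded by an initiation time.
* Study configuration files are JSON (no YAML parser among the package's
  dependencies).
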