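# tvtpanel

Causal effect estimation for **staggered, absorbing treatments** in panel
data, combining the inverse-probability-weighting toolkit for time-varying
treatments (TVT) with staggered-adoption difference-in-differences (DiD),
plus the hybrid estimators that fuse the two.

## Who this is for

Analysts with long-format panel data — one row per unit per time, a binary
treatment that switches on once and stays on, a continuous outcome, and
covariates that may vary over time and be affected by earlier treatment.
Standard DiD assumes parallel trends and breaks under time-varying
confounding; TVT weighting assumes sequential exchangeability (all
confounders measured at each time point) and breaks under unmeasured
level confounders. This package implements both, and the hybrids that are
robust when only one assumption holds.

## What it computes

For adoption groups $G = g$ (first-treatment time) and outcome times
$t \ge g$, the group–time average treatment effect on the treated

$$\mathrm{ATT}(g,t) \;=\; E\!\left[\,Y_t(\mathbf 0_{g-1},\mathbf 1_{T-g+1}) - Y_t(\mathbf 0_T)\;\middle|\;G=g\,\right],$$

and population strategy contrasts via marginal structural models
$E[Y_t] = \beta_{t0} + \sum_{d \le t}\beta_{td} D_d$ fit by weighted least
squares. Four estimator families:

| estimator | weights | quantity weighted | robust to |
|---|---|---|---|
| `fit_msm` | stabilized ATE, $\prod_k \frac{P(D_k \mid \bar D_{k-1})}{P(D_k \mid \bar D_{k-1}, \bar X_k)}$ | outcome $Y_t$ | measured time-varying confounding |
| `estimate_att_tvt_outcome` | ATT odds-type | outcome $Y_t$ | measured time-varying confounding |
| `estimate_att_tvt_changescore` | ATT odds-type | change score $Y_t - Y_{g-1}$ | measured time-varying **and** unmeasured level confounding |
| `estimate_att_gt_did` | none / sampling | change score | unmeasured level confounding (add TVT-ATE sampling weights for measured time-varying) |

A structural-equation simulator (`simulate_population`) provides four
benchmark worlds — confounding time-invariant or time-varying, measured or
unmeasured, with treatment–confounder feedback and outcome autoregression —
with an exact counterfactual oracle (`simulate_counterfactual`,
`compute_truth`) via common random numbers, and `run_study` reproduces the
full bias/SE Monte Carlo comparison. See the vignette
(`vignettes/tvt-did-weighting.Rmd`) for the model equations and every
numerical design choice.

## Worked example

```r
library(tvtpanel)

# a world with time-varying confounding and treatment-confounder feedback
cfg <- structural_config(setup = 3, m = 1)
pop <- simulate_population(cfg, 2e5, seed = 1)
true_att(pop, g = 2, t = 2)
#> [1] 0.4754276         # oracle truth by intervention simulation

panel  <- draw_sample(pop, 3000, seed = 2)        # what an analyst sees
models <- fit_propensity_models(panel, default_covariate_lags(3))
models
#> <tvt_propensity_models> T = 4
#>   t=1: at risk 3000, initiation 0.272, coef [-1.034, -0.511]
#>   t=2: at risk 2185, initiation 0.263, coef [-1.048, -0.550, -0.540]
#>   ...                 # recovers the generating log-odds (-1, -0.5, -0.5)

w <- normalize_att_weights(compute_att_weights(panel, models, 2, 2, "never"))
estimate_att_tvt_changescore(panel, w, 2, 2)$estimate
#> [1] 0.2703064          # hybrid estimate, one 3000-unit dataset

estimate_att_gt_did(panel, 2, 2, "never")$estimate
#> [1] 0.2996071          # plain DiD, biased downward in this world

aw <- compute_ate_weights(panel, models, 2)
fit_msm(panel, aw, 2)
#> <tvt_msm> outcome time 2, n = 3000, ATE-weighted
#> beta_2_0 beta_2_1 beta_2_2
#>   0.0373   0.2955   0.4509  # beta_2_2 estimates the 0.5 concurrent effect
```

A single 3000-unit dataset is noisy (the hybrid's Monte Carlo SD here is
about 0.13 — the draw above happens to be low); the study harness is what
separates the estimators. Averaged over 100 replicates the hybrid is
unbiased in this world while plain DiD is off by 29 Monte Carlo standard
errors:

```r
st <- run_study(study_config(setups = 3, m_grid = 1, population_n = 2e5,
                             master_seed = 1, control_types = "never"))
subset(as.data.frame(st$results),
       g == 2 & t == 2 & estimator %in% c("tvt-cs", "gt-did") &
         (is.na(adjusted) | !adjusted) & (is.na(weighted) | !weighted),
       select = c(estimator, truth, mc_mean, bias, se))
#>   estimator     truth   mc_mean        bias         se
#>      gt-did 0.4765722 0.2867732 -0.18979893 0.06475958
#>      tvt-cs 0.4765722 0.4602276 -0.01634457 0.09260700
```

## Command line

```sh
tvtpanel simulate --config sim.json --out pop.csv --sample-out sample.csv
tvtpanel truth    --config sim.json --out truths.csv
tvtpanel weights  --panel sample.csv --estimand att --g 2 --t 2 --control never --normalize --out w.csv
tvtpanel estimate --panel sample.csv --estimator tvt-cs --g 2 --t 2 --out est.csv
tvtpanel study    --config inst/extdata/study_config.json --out-dir results/
```

(`exec/tvtpanel` after installation, or `Rscript -e 'tvtpanel::tvt_cli()' --args ...`.)

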