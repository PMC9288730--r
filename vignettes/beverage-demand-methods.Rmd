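---
title: "Estimating beverage price elasticities from unit values: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating beverage price elasticities from unit values: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Household expenditure surveys record, per household, the quantity purchased
and the amount spent on each good, but not market prices. The ratio of the
two — the *unit value* — is a price proxy with two well-known defects.
First, when prices rise consumers shade down quality as well as quantity,
so unit values move less than prices do ("quality shading"); a naive
regression of quantities on unit values therefore overstates the price
response. Second, any reporting error in quantity or expenditure
contaminates the unit value, attenuating cluster-average price signals.
`asbdemand` implements the two-equation unit-value method that corrects
both problems, applied to aerated/sugar-sweetened beverages (ASBs) and
companion beverages (fruit juice, milk, tea) in clustered surveys of the
kind India's consumer expenditure rounds provide, and couples it with an
affordability analysis and a tax simulation.

## The model

Clusters (a village or an urban block, surveyed at one point in time) are
assumed to face a single market price per good; all price variation within
a cluster is quality choice plus measurement error. For household $h$ in
cluster $c$ and goods $G$:

$$\ln v_{hc} = \alpha^1 + \beta^1 \ln x_{hc} + \gamma^1 z_{hc}
  + \Psi \ln \pi_c + u^1_{hc}$$
$$w_{hc} = \alpha^0 + \beta^0 \ln x_{hc} + \gamma^0 z_{hc}
  + \Theta \ln \pi_c + f_c + u^0_{hc}$$

with $v$ the unit value, $w$ the budget share, $x$ total household
expenditure, $z$ household covariates (log household size, number of
children, mean education years), $\pi_c$ the unobserved cluster prices,
$f_c$ a cluster fixed effect and $u^0, u^1$ idiosyncratic terms that absorb
measurement error.

**Stage 1** estimates the household-level coefficients with cluster fixed
effects (within-cluster demeaning): the share equation over all retained
households, the unit-value equation over purchasers of each good. Its
residual covariance matrices $\Sigma_{11}$, $\Sigma_{01}$ quantify the
within-cluster noise.

**Stage 2** purges the household effects, averages within clusters
($y^1$: purged log unit values over purchasers — the price signal; $y^0$:
purged shares), and regresses $y^0$ on $y^1$ *between clusters* with an
errors-in-variables correction: the noise that cluster averaging leaves in
$y^1$ (of order $\Sigma_{11}/n^+_c$ for $n^+_c$ purchasers) is subtracted
from the second-moment matrices,

$$\hat B^\top = (R - M_{11})^{-1} (S - M_{01}),$$

where $R$ and $S$ are the between-cluster covariance matrices of
$(y^1, y^1)$ and $(y^1, y^0)$ and $M_{11}, M_{01}$ average the per-cluster
attenuation terms $\Sigma/n^+$ over clusters (pairwise purchase overlaps
for cross-good terms). Without this correction the share-on-unit-value
slope is biased toward zero, which — because the elasticity is
$B/\bar w - 1$ at small shares — *overstates* the price-response magnitude.

**The elasticity transform.** With the expenditure elasticity
$\epsilon_x = 1 + \beta^0/\bar w - \beta^1$ and quality elasticity
$\zeta = \beta^1/\epsilon_x$, the share-response matrix relates to the
price-elasticity matrix $E$ through
$\Theta = D(\bar w)(I+E)$, $\Psi = I + D(\zeta)E$, $B = \Theta\Psi^{-1}$,
inverted in closed form as

$$E = \bigl(I - D(\bar w)^{-1} B\, D(\zeta)\bigr)^{-1}
      \bigl(D(\bar w)^{-1} B - I\bigr).$$

With $\zeta = 0$ this reduces exactly to $E = D(\bar w)^{-1}B - I$. The
quality-shading literature contains several refinements of this mapping;
the package commits to the system above on both sides — the synthetic
generator derives $(\Theta, \Psi)$ from a target $E$ through the same
equations (`implied_theta_psi()`) — so estimator validation is a genuine
round trip rather than an assertion about any one variant. Entry $(i, j)$
of $E$ is the effect of the price of good $j$ on the quantity of good $i$;
no symmetry or homogeneity restriction is imposed.

**Standard errors** come from a cluster bootstrap of the second stage:
clusters are resampled with replacement (1000 draws by default), the
moment matrices, corrections and transform are recomputed per draw with
the stage-1 coefficients held fixed, and the SE is the SD across draws.
Draws failing the positive-definiteness check on $(R - M_{11})$ are
dropped and counted; more than 10% failures raises a warning (escalatable
to an error). A full-pipeline bootstrap is intentionally not the default:
the second-stage cluster resample matches how the published estimates were
computed, and stage-1 coefficients are estimated from two orders of
magnitude more observations than the between-cluster stage.

**Income groups.** Tertiles of total household expenditure (the income
proxy) are assigned deterministically: ranking ties break on household id
and remainders go to the lower tertiles, so tertile sizes differ by at
most one. Group-wise estimation keeps the cluster-price assumption intact:
the price signal $y^1$ is computed from *all* households of a cluster
pooled across groups, while the share side uses each group's households
only. Rural/urban estimates simply split clusters by sector.

## The estimation filter

Only households consuming the focal good enter the estimation sample, and
only clusters with at least two of them are retained (a single purchaser
gives no within-cluster information and an unusable cluster average). At
the default survey scale (25,428 clusters of 8 households, prevalence
1–10%) this leaves roughly 1,400 clusters — the same order as the ~2,300
clusters the published analysis retained. Tertiles can be formed before or
after this filter; the default is after, but the recovery experiments
assign them before filtering so the estimation groups coincide with the
groups whose behaviour the generator made heterogeneous.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` samples surveys directly from the two equations
above, with:

* between-cluster log-price SD of 0.20 for ASBs (transport costs and
  state-level tax differences), within-cluster unit-value noise 0.134 so
  that ~69% of log unit-value variance lies between clusters, matching the
  variance split observed in the real surveys. Note that the R² of a
  regression on cluster *indicators* sits above the underlying variance
  share when clusters contribute only 2–3 purchasers (overfitting
  inflation of roughly $(1-\rho)\,C/N$); the designed variance-split check
  therefore uses 50 purchasers per cluster, where the inflation is under
  one point.
* purchase prevalence rising from 1.0% (low tertile) through 3.1% to
  10.3% (high tertile) for ASBs, and budget shares falling with income
  ($\beta^0 < 0$) — the observed consumption gradient;
* mean budget shares among purchasers of roughly 1.7% (ASB), 1.9%
  (juice), 9.2% (milk), 3.0% (tea), unit-value levels near 47, 65, 25.5
  INR/litre and 3.7 INR/cup;
* independent Bernoulli purchase gates per tertile. Purchase incidence is
  not part of the two-equation system, and no selection model linking the
  gate to prices is asserted; the gate is income-specific only. Share
  realisations outside $(0,1)$ are clipped and counted (a >5% clip
  fraction flags the configuration) rather than resampled, preserving
  seed reproducibility.

Because the generator *is* the model the estimator assumes, recovery
failures are attributable to the estimator — that is the point. The
corresponding limitation: passing tests certify the econometrics, not
robustness to real-data features the generator omits (correlated purchase
gates, spatially correlated prices, non-normal noise, reporting heaping,
survey weights). One consequence shows up directly: with *independent*
1–10% gates, a sparse good like juice overlaps too rarely with focal-good
purchasers for the full 4×4 cross-price matrix to be stable, whereas real
surveys supply correlated purchases. The multi-good machinery is therefore
validated at configurations where every good has adequate cluster-level
signal (see `analysis/03_estimate_elasticities.R`).

## Recovery experiments

`elasticity_recovery_experiment()` runs the headline validation: 20
independent surveys at full scale (25,428 clusters × 8 households, truth
−0.94, quality shading active through $\beta^1 = 0.06$), each estimated
with a 1000-draw bootstrap. The mean estimate lands within a few
thousandths of the truth and the normal-approximation 95% intervals cover
it in ~95% of replicates. `tertile_recovery_experiment()` sets
tertile-specific truths (−1.035, −0.913, −0.832) with
$\beta^0 = \beta^1 = \gamma = 0$, so each group's truth is exactly
$\theta_g/\bar w - 1$ — a focused experiment isolating group price
responses. The low-income group keeps only ~200 purchasers per survey at
1% prevalence, so its estimator is heavy-tailed; the magnitude ordering
low > middle > high is nevertheless recovered by the replicate means, and
per-group bootstrap intervals cover their truths at the expected rate.

## Affordability

The relative income price is
$\mathrm{RIP}_t = 100 \times (p_t \times 100\,\mathrm{L}) / \mathrm{GDP}^{pc}_t$:
the percent of nominal per-capita GDP needed to buy 100 litres. Annual
percent changes are simple arithmetic changes (not log differences), so
the decomposition *price effect = % change in real price; income effect =
RIP change − price effect* is additive by construction, which is exactly
the subtraction identity the decomposition is defined by; a log-exact mode
is available behind `log_exact = TRUE`. Multi-brand price inputs are
pooled to one annual price first, weighted by observation counts.
`mean_growth()` is the geometric rate over $n-1$ periods,
$(x_n/x_1)^{1/(n-1)} - 1$. Fiscal-year labels are treated as opaque
ordered strings, except that leading 4-digit years are used to detect gaps.

## Tax simulation

Statutory GST rates are exclusive, so 28% GST + 12% cess put
$0.40/1.40 \approx 28.6\%$ of the retail price into tax. The simulation
works from the rounded 28.6% burden (tax 17.16 INR/L at the 60 INR/L
baseline price), which reproduces the published baseline revenue; the
exact 40/140 alternative is available via `tax_burden = NULL`.
Constant-elasticity demand is the default form because it reproduces the
published price target (67.1 INR/L for a 10% cut at elasticity −0.94) to
the printed digit; the linear form is provided for sensitivity. For
pass-through $\phi$, the tax must rise by $\Delta p / \phi$; the required
cess is $T_1/(p_1 - T_1) - 0.28$. All results are carried at full
precision with a separate display-rounding helper, since the published
table's internal rounding is visible at the last digit. Income-group
impacts use $(1+\Delta p)^{\epsilon_g} - 1$ with survey-derived group
consumption shares.

## Numerical choices and degenerate inputs

* Within-cluster demeaning (Frisch–Waugh) rather than cluster dummies;
  the two are verified equal in the tests. Rank-deficient covariates are
  reported by name.
* Residual covariances divide by $n - C - k$ (observations minus clusters
  minus regressors) on each pairwise-overlap sample — exactly unbiased on
  the diagonal, the standard plug-in off it.
* $(R - M_{11})$ is symmetrised and must be positive definite; a
  violation ("correction overshoot", typical of too-small samples) is an
  error, with an optional ridge fallback that is off by default and
  reported loudly when enabled.
* Goods with zero purchasers are dropped with a warning; clusters with no
  purchasers of a good contribute to that good's share moments but not to
  its unit-value moments; good pairs with fewer than 3 informative
  clusters are an error.
* Every stochastic operation takes an explicit seed; no global RNG state
  is relied on, and identical configuration plus seed reproduces outputs
  byte for byte.

## Problem sizes used in the shipped experiments

Recovery experiments run 20 replicates at 25,428 clusters × 8 households
(~203k households each, ~2 s per replicate including the 1000-draw
bootstrap); the variance-split design uses 2,000 clusters × 50
purchasers; bootstrap calibration compares 40 independent replicates at
600 clusters against the bootstrap SE. These sizes were chosen to mirror
the pooled two-round survey dimensions while keeping a full validation
run in the order of a minute.

## Known limitations

* Elasticities are household-level, conditional on purchase; the
  extensive margin (the Bernoulli gate) is outside the demand system.
* Survey multipliers are supported in summaries (`weighted = TRUE`) but
  the estimator itself is unweighted.
* The affordability module needs externally supplied retail-price and GDP
  series to say anything about actual years; the shipped series are
  synthetic scenarios that reproduce the *structure* (growth rates,
  decomposition), not the historical levels.
* The tax simulation is static: no supply response, no brand
  substitution, no revenue dynamics over time.
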