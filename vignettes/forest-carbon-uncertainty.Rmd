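---
title: "Methods: Monte Carlo uncertainty quantification for regional forest carbon balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo uncertainty quantification for regional forest carbon balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcarbuq)
```

# What the pipeline computes

`forcarbuq` produces region-by-year *distributions* of forest greenhouse-gas
balance and carbon stock under a grid of climate (RCP × GCM) and
harvest-intensity scenarios, by direct Monte Carlo: every uncertain input is
sampled once per simulation, held fixed where the study design says it is
shared (across regions and years), and propagated through an annual
stand--soil carbon model. The headline output is net biome exchange,

$$\mathrm{NBE} = (\mathrm{NEE} + H)\cdot \tfrac{44}{12}
  + 298\,\mathrm{N_2O} + 25\,\mathrm{CH_4},
  \qquad \mathrm{NEE} = -\mathrm{NEP},$$

in kgCO$_2$eq ha$^{-1}$ yr$^{-1}$ (negative = sink), with harvested biomass
carbon $H$ counted as an immediate emission flux (no wood-product pool).
Internally stocks and harvests are kgC ha$^{-1}$, fluxes gC m$^{-2}$; all
unit conversions live in the accounting module (`ghg_factors()`), so the
44/12 ratio is applied exactly once and to full floating precision.

# The surrogate stand model

The stand model is a *surrogate*: it preserves the contract a regional
uncertainty pipeline needs — daily weather drivers in, annual GPP,
allocation, litter, mortality and structural growth out — with the simplest
defensible process forms, not the internal physiology of a calibrated
growth model. Its components:

* **GPP** (`annual_gpp`): light-use efficiency × absorbed-light fraction ×
  $\sum_{d=1}^{365} R_d\, f_T f_D f_C f_W$, where $R_d$ is daily radiation
  (MJ m$^{-2}$) and the modifiers are all in $[0,1]$: a temperature ramp
  between `t_min` and `t_sat`, an exponential VPD decay $e^{-k_D D}$, a
  saturating CO$_2$ response $c/(c + k_C)$, and a soft water modifier
  $s/(s+w_0)$ driven by exponentially smoothed precipitation. Light
  absorption is $1-e^{-k_L\,\mathrm{BA}}$ with a floor of 0.05 so clearcut
  pixels regenerate (seedlings and ground flora keep photosynthesis alive).
  GPP is linear in the light-use efficiency by construction.
* **Allocation and growth** (`grow_stand`): a fixed autotrophic respiration
  fraction gives NPP; turnover litter is `litter_turnover` × tree carbon;
  crowding mortality activates above a Reineke density ceiling
  $N_{max} = a\,\mathrm{dbh}^{-b}$; random mortality defaults to an
  expected-value fractional loss (a Bernoulli whole-pixel mode is
  available — the expected-value default keeps small pixel samples smooth
  while preserving the flux). A fixed fraction of tree NPP is stemwood;
  basal area, diameter and height are recovered from the stem-volume
  allometry $V = \mathrm{BA}\cdot h(\mathrm{dbh})\cdot f$ by a monotone
  fixed-point iteration (six sweeps, well inside numerical convergence).
* **Ground vegetation** (`ground_vegetation_biomass`): a fertility-dependent
  ceiling approached concavely in below-canopy light, relaxed towards with
  25% annual turnover; its production is accounted as NPP so that the
  annual identity
  $\Delta(\text{tree C} + \text{ground veg C}) =
  \mathrm{NPP} - \text{litter} - \text{mortality litter} - \text{harvest}$
  holds *exactly* (to 1e-9 relative) on every step — this is
  property-tested over $10^4$ random states.

Weather far outside the generator's climatology is not clamped; the
surrogate simply evaluates its ramp/decay responses, which saturate
gracefully.

# Soils and drained organic sites

Mineral soil is a three-pool first-order chain (fast / slow / humus-like,
decay rates spanning two orders of magnitude) with cascading transfers and
an optional Q10 temperature modifier; mass balance
$\Delta(\text{total}) = \text{litter} - R_h$ is exact per step. The initial
state is spun up per simulation: the coupled stand+soil model runs over
randomly ordered repetitions of the seven historical years (weather and
realised harvest pressure), the stand resetting each cycle while soil pools
carry over, until the relative change of mean total soil carbon per cycle
is below 1e-4 (cap 300 cycles; non-convergence is flagged, not fatal). An
analytic linear-chain warm start (fixed point of the probe-cycle mean
litter) makes convergence a matter of a few cycles rather than hundreds.

Drained organic (peat) soils are static by construction: five emission
coefficients (CH$_4$ everywhere; N$_2$O and CO$_2$ split into
nutrient-rich site types 1--3 and nutrient-poor > 3) sampled once per
simulation from their published means and standard deviations, plus a
constant peat carbon stock ~ N(543 400, 18 500$^2$) kgC ha$^{-1}$. The CO$_2$
coefficient replaces the dynamic soil flux in NEP (litter passes through);
negative CO$_2$ coefficients (nutrient-poor sites) mean soil uptake and are
kept; strictly positive gases (CH$_4$, N$_2$O) are truncated at zero with
the truncation count recorded. Organic-soil emissions never feed back into
growth.

# Management

Stand-level triggers follow the structure of national silvicultural
guidelines: species-specific clearcut thresholds on mean diameter, dominant
height and age (OR-combined by default, configurable), a basal-area
thinning trigger with fractional removal. The exact numbers are shipped as
a configurable rule set (`harvest_rules()`), since they are conventions,
not estimates. Protected and poorly productive land is never cut.

Regional allocation visits eligible pixels in one pooled uniformly random
permutation (no preference between thinning- and clearcut-eligible pixels)
and executes each triggered action *in full* — actions are discrete
silvicultural events, so the marginal pixel is completed rather than
partially thinned, bounding target overshoot by one pixel's yield. When
eligible pixels are exhausted first, the remainder is an explicit
shortfall and harvesting stops. Clearcut stemwood is round wood; a
configurable fraction of residues is removed as energy wood; remaining
residues enter the litter flux. Both wood types count jointly against the
combined regional target.

Country harvest statistics (round wood 68--78, energy wood 7.2--10.2
Mm$^3$ yr$^{-1}$) describe a real national forest area, so they are
converted to an intensity via a configurable reference area (default 20.3
Mha) and scaled to the synthetic landscape area before regional allocation
by historical shares. Scenario targets for the projection years are the
historical average times 0 / 0.6 / 1.0 / 1.2 (NoHarv / LowHarv / BaseHarv /
MaxHarv); target noise is Normal with a 2% coefficient of variation,
redrawn per projection year by default (a per-simulation single draw is the
alternative reading; per-year is the default because statistical harvest
levels fluctuate annually).

# The Monte Carlo design

Per simulation $i$: one GCM uniform over five (shared by all regions), one
parameter vector resampled with replacement from each of the three pools,
one crown-height factor ~ N(1, 0.1$^2$), one emission-coefficient table,
one peat stock, and the harvest-target deviates (per year, shared across
regions). Per region: an independent area-weighted pixel sample, initial
ages ~ N($\mu$, $(0.1\mu)^2$) truncated at zero, site types resampled once
from a row-stochastic confusion model (default diagonal 0.7, neighbours
sharing the remainder, with an optional structural tilt towards fertile
classes for structurally large stands) and then held constant. All
components are sampled independently — correlations between uncertainty
sources are deliberately ignored, and segments are treated as exchangeable
(no spatial layout), since homogeneous segments are modelled as spatially
independent.

Seeding is hierarchical: master seed → per-simulation stream → per-region
sub-stream → per-(simulation, region) scenario stream. The scenario stream
is re-seeded identically for every scenario of the grid, so harvest
scenarios of the same RCP are *matched*: 2015--2021 trajectories are
bit-identical across harvest intensities, and scenario contrasts are paired
rather than independent. Weather series are deterministic per (seed, GCM,
RCP) and generated before the scenario stream is seeded, so cache state
cannot perturb reproducibility. Results are invariant to scenario order
and bitwise reproducible.

The synthetic landscape defaults to 4 regions spanning the observed
national ranges (mean basal area 17→12 m$^2$ ha$^{-1}$, mean age 50→85 y
along a south–north gradient, pine share rising and organic-soil share
0.06→0.2 northwards), with heterogeneous region sizes (0.5×–2×) and
harvest shares declining per area northwards. Segment areas are truncated
log-normal on [0.026, 540] ha with median ≈ 0.8 ha; basal area and age are
gamma with CV 0.45; species proportions are Dirichlet about the regional
mixture. Pixel sample sizes are proportional to region area (mean = the
configured `n_pixels`), so smaller regions carry more sampling
uncertainty.

# Attribution and risk

Variance attribution uses the Stewart--Love redundancy index: canonical
correlation between a feature block and the output, with the output
redundancy $\sum_k \rho_k^2 \overline{\ell_k^2}$. The default analysis is
per feature column against the scalar output (the $r^2$ special case),
with per-set maxima reported for the multi-parameter sets (growth,
photosynthesis, soil, emission coefficients, harvest deviates) — the
harvest deviates enter as the per-simulation mean standard-normal deviate
per wood type. Categorical drivers are one-hot encoded with the first level
dropped; constant columns are dropped and flagged; the NoHarv scenario is
excluded by default because it would trivially dominate. The index is
clamped to [0,1] and interpreted only relative to other values.

Risk summaries are plain empirical CDFs, $\hat P(X \le t) = \#\{x_i \le
t\}/n$, and central 95% ranges computed with linear interpolation of order
statistics (quantile type 7) for cross-implementation determinism.

# Test-scale study conditions, and what passing does not show

The default problem sizes — 4 regions × ~1000-segment populations, mean 500
pixels per region, 50 simulations, 2015--2050, one RCP × four harvest
scenarios — were chosen so a full grid runs in a few minutes on one core;
full-scale values (18 regions, 20 000 pixels, 300 simulations) remain plain
configuration. Monte Carlo checks in the test suite use draw counts between
2×10$^4$ and 10$^6$ per law, with bands set at ≥ 4 standard errors.

The synthetic generator emulates the *statistical structure* of segmented
inventory data (marginal distributions, fertility gradients, area
weighting), not real geography: there is no spatial correlation, no
climatic gradient between regions (all regions share one national weather
series per GCM × RCP), no disturbance events, no nitrogen limitation, and
the stand model is a surrogate. Passing tests therefore demonstrate the
correctness of the uncertainty-propagation machinery, the accounting
identities and the qualitative scenario orderings — not the predictive
accuracy of any national carbon-balance number.

One documented ensemble diagnostic is sensitive to this design: the
anticorrelation between region size and the NoHarv 95% range width. In
this pipeline the region-level spread is dominated by the uncertainty
components that are deliberately held fixed across regions (parameter
sets, GCM choice, crown factor, shared weather), so the pixel-sampling
component (~600 kgCO$_2$eq ha$^{-1}$ at 50 pixels, negligible above 200)
is largely buried and the size–width rank correlation is weak and can
carry either sign at test scale. The diagnostic is computed and reported
as is.

# Known limitations

* The stand and soil surrogates are structurally simple; absolute NBE
  levels are realistic in order of magnitude only.
* Harvested biomass is an immediate emission; no wood-product carbon pool.
* Static organic-soil coefficients likely understate future peat CO$_2$
  emissions under warming; no dynamic alternative is provided.
* Site-type resampling uses a configurable confusion model, not a fitted
  classification-error model.
* No parallel execution is built in; simulations are embarrassingly
  parallel and order-invariant by seeding design, so external
  parallelisation over simulation ids is safe.
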