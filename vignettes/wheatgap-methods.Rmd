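---
title: "wheatgap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheatgap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatgap)
```

`wheatgap` estimates, for a site's climate, the *genetic yield potential*
of wheat (the water-limited yield of an ideotype whose seven key traits are
jointly optimal there) and the *genetic yield gap* (that potential minus
the yield of the current well-adapted cultivar). This vignette is the
package's own account of the three models it chains together — a
stochastic weather generator, a daily crop growth simulator, and a
constrained evolutionary trait search — with the reasoning behind every
tunable number.

## 1. Synthetic weather

The analysis needs many years of daily minimum/maximum temperature,
precipitation and global radiation whose *statistics* resemble a target
climate: seasonal cycles, wet/dry-day persistence (dry spells), day-to-day
temperature autocorrelation (heat spells), and realistic inter-annual
variability. `generate_weather()` implements a WGEN-style generator:

* **Occurrence.** Wet/dry days follow a two-state first-order Markov chain
  with monthly transition probabilities $p_{wet|wet}$, $p_{wet|dry}$. The
  chain starts from its stationary distribution.
* **Amounts.** Wet-day precipitation is exponential with the monthly mean
  (a single-parameter stand-in for the usual skewed amount distributions).
* **Temperature.** A single annual harmonic is least-squares fitted
  through the twelve monthly means (evaluated at mid-month days) to give a
  smooth seasonal curve; a shared AR(1) anomaly with lag-1 autocorrelation
  0.7 and monthly standard deviation is added to both tmin and tmax. The
  shared anomaly makes `tmax >= tmin` hold by construction; the cost is
  that the diurnal range has no stochastic component, which matters little
  here because the crop model consumes the daily mean (thermal time) and
  tmax (heat damage), both of which retain full variability.
* **Radiation.** The seasonal harmonic value is multiplied by a mean-one
  log-normal factor (log-scale SD 0.22) and by 0.75 on wet days; dry days
  are brightened by the exactly compensating factor so the *expected*
  monthly radiation equals the configured mean. Without the compensation
  the wet-day cloud coupling would bias every monthly mean low.

A year is 365 days; no leap days (the bias is negligible against the
other approximations and it keeps phenology bookkeeping trivial).

Five shipped archetypes (`site_preset()`) span the European wheat belt.
Each is built from an annual target (mean temperature, precipitation,
radiation), a seasonal amplitude, and occurrence probabilities, then
rescaled so the *implied* annual values (`implied_climate()`) hit the
targets exactly; across the family the extremes sit exactly on
7.1/19.2 °C, 344/801 mm yr⁻¹ and 9.7/17.0 MJ m⁻² day⁻¹. They are
archetypes — "a cool wet maritime site", "a hot dry Mediterranean site" —
not reconstructions of particular stations, and the generator is a
climate sampler, not a calibrated reproduction of any observational
weather generator: it has no semivariate amount distributions, no
spell-length corrections, and no tmin/tmax cross-correlation structure
beyond the shared anomaly. Tests that pass against it demonstrate the
*procedure*, not fidelity to any particular station's record.

## 2. The crop model

`simulate_season()` advances one day at a time from sowing. Notation:
$T_{min}, T_{max}$ (°C), $R$ global radiation (MJ m⁻² d⁻¹), $P$
precipitation (mm). The seven optimizable traits are $A_{max}$ (potential
maximum leaf area index), $S_G$ (stay-green), $P_h$ (phyllochron, °C d per
leaf), $P_p$ (photoperiod sensitivity, 0–1), $G_f$ (grain-filling thermal
duration, °C d), $R_u$ (maximum fraction of stored soil water extractable
per day), and $W_{ss}$ (maximum senescence acceleration under water
stress).

**Thermal time and phenology.** Daily thermal time is
$\Delta tt = \max(0, (T_{min}+T_{max})/2 - T_{base})$ with $T_{base} = 0$ °C.
Before anthesis it is multiplied by the photoperiod factor
$f_p = \mathrm{clamp}\!\left(1 - P_p \frac{\max(0, d_{sat} - d)}{d_{sat}-d_{base}},\; f_{min}, 1\right)$
with day length $d$ from standard solar-declination geometry and constants
$d_{base} = 8$ h, $d_{sat} = 15$ h, $f_{min} = 0.25$: short days slow
sensitive cultivars. Anthesis occurs when accumulated modified thermal
time reaches $(N_{leaf} + 2)\,P_h$ with a fixed final leaf number
$N_{leaf} = 9$ and a two-phyllochron booting-to-flowering allowance. This
preserves the causal chain that matters for ideotype design — larger
$P_h$ or $P_p$ mean later flowering — without a full leaf-number model.
Vernalization and frost damage are out of scope (see §6).

**Canopy.** LAI rises with leaf emergence,
$L = A_{max}\min(1, tt_{mod}/(N_{leaf} P_h))$, and after anthesis declines
linearly in effective thermal time over a stay-green-scaled duration
$D_{sen} = 350\,(1+S_G)$ °C d. Each post-anthesis day contributes
$\Delta tt \cdot (1 + (W_{ss}-1)(1-s))$ to senescence, where $s$ is the
day's water-stress index: a fully stressed canopy senesces $W_{ss}$ times
faster.

**Light and biomass.** Intercepted PAR is
$I = 0.5\,R\,(1 - e^{-k L})$ with extinction coefficient $k = 0.5$, and
biomass grows by $\mathrm{RUE} \times m_{LUE} \times I \times s$ with
RUE 2.2 g MJ⁻¹ (PAR basis, mid-range for modern wheat) and
$m_{LUE} = 1.10$ for ideotypes (the assimilation gain available at current
CO₂ from an optimal Rubisco specificity), 1.0 for cultivars. There is no
further temperature limitation of RUE; temperature acts through phenology
only (an acknowledged extension point). CO₂ is a constant 364 ppm with no
response function — a single-level analysis.

**Soil water.** A single bucket of available water capacity 177 mm
(a common medium profile used identically at all sites, so soil
differences never confound climate differences), re-filled to 90 % at
each sowing. Daily: precipitation infiltrates, storage above capacity
drains, transpiration is $\min(\text{demand}, R_u \times \text{storage})$
with demand 0.45 mm per MJ of intercepted PAR (equivalent to a
transpiration efficiency of about 5 g dry matter per kg water at this
RUE), and the stress index is $s = \text{uptake}/\text{demand}$ (1 when
there is no demand). The step conserves mass exactly, which the test
suite asserts to 10⁻⁶ mm over a thousand random seasons.

**Grain number and flowering-window damage.** At anthesis the potential
grain number is 22 grains per g of anthesis biomass. Over the flowering
window (anthesis ± 4 days — "a short spell around flowering"), heat
removes $\mathrm{HSGNR}\max(0, T_{max} - \mathrm{HSGNT})$ of grain number
per day (capped at 1), and drought removes
$\mathrm{DSGNS}\max(0, \mathrm{DSGNT} - s)$ per day, capped at
$\mathrm{DSGNRMax}$. The sensitive (iS) set is
HSGNT 27 °C, HSGNR 0.05, DSGNT 0.6, DSGNS 0.3, DSGNRMax 0.9; the tolerant
(iT) set is HSGNT 32 °C, HSGNR 0.01, DSGNT 0.4, DSGNS 0.1, DSGNRMax 0.3.
These are package defaults standing in for cultivar calibrations, clearly
labelled non-authoritative and overridable.

**Grain filling and yield.** Filling lasts $G_f$ °C d (unmodified thermal
time) or until full senescence, whichever comes first. Grain mass is the
smaller of supply — post-anthesis biomass growth plus a labile reserve of
25 % of anthesis biomass released in proportion to fill progress — and
sink, grain number × 45 mg potential grain mass. Harvest index is
yield/biomass and cannot exceed 1 by construction; reduced grain *size*
under stress is represented only through this source limitation, a
deliberate simplification.

**Multi-year runs.** `simulate_multi_year()` sows once per generated
year; each season runs 365 days from the sowing day, borrowing the start
of the following year (the final year borrows the start of year one —
a cyclic wrap that is harmless because the generated climate is
stationary). The soil is re-initialized each sowing, so years are
independent samples of the climate. Yield statistics over years use the
**sample** standard deviation (divisor $n-1$, `stats::sd`) for the CV —
the convention is fixed and documented because the 10 % stability filter
must be reproducible.

## 3. Ideotype optimization

`optimize_ideotype()` maximizes mean yield over the weather series with a
multi-start $(1+\lambda)$ evolution strategy, $\lambda = 16$ candidates
per generation. Mutation is self-adaptive: each per-trait step size is
multiplied by $e^{\tau N(0,1)}$ with $\tau = 1/\sqrt{2\cdot 7}$, the trait
is perturbed by a Gaussian with the new step size, and the result is
reflected back into the trait bounds. Step sizes start at 10 % of each
trait range. A candidate whose yield CV exceeds 10 % or whose mean
harvest index exceeds 0.64 (the accepted biological upper limit) is
removed from selection; the best surviving candidate replaces the parent
only if it improves mean yield by more than 10⁻³ t ha⁻¹ (ties go to the
parent, for stability). A start ends after 20 improvement-free
generations ("no further improvement") or 200 generations; 25 starts are
scattered uniformly in the trait box except one that is the local
cultivar itself, which guarantees the optimized ideotype never falls
below the cultivar evaluated with the ideotype LUE. Default trait bounds
(a stand-in calibration table, overridable): $A_{max}$ 2.25–9, $S_G$ 0–2,
$P_h$ 70–140 °C d, $P_p$ 0–1, $G_f$ 400–900 °C d, $R_u$ 0.02–0.12 d⁻¹,
$W_{ss}$ 1–4.

Two variance-reduction choices make comparisons meaningful at desk scale:
every candidate in every start is evaluated on the *identical* weather
series (common random numbers, as implied by optimizing against one fixed
multi-year climate), and the iS and iT searches for a site share one
mutation stream, so their contrast isolates the stress parameterization
rather than search luck. An infeasible initial parent (the cultivar can
violate the CV filter at harsh sites) still seeds a start; selection
simply never moves to an infeasible candidate.

All randomness descends from one integer seed through a documented
splitting scheme (`split_seed()`, a multiplicative hash over keys such as
site, stage and start index), so adding a site or a start leaves every
other result unchanged.

## 4. Gap arithmetic and reporting

For a site, $Y_W$ is the mean rainfed yield of the cultivar
($m_{LUE} = 1$), $Y_{iW}$ the mean yield of the optimized ideotype, and
$Y_{iG} = Y_{iW} - Y_W$, also expressed as $100\,Y_{iG}/Y_{iW}$ percent of
the genetic yield potential. Negative gaps (an under-performing search)
are reported, not clipped — they are diagnostic. `aggregate_gaps()` takes
arithmetic means per mode across sites and contrasts the modes (the
difference of mean gaps, absolute and as a percent of the iS mean gap).
Percentages are computed in full precision and rounded half-up only at
the printed-precision reporting layer (`round_half_up()`), because
conventional round-half-even would turn a 48.5 into 48.

## 5. Problem sizes and numerical choices

The full study design is 100 weather years, 25 starts and up to 200
generations per start. The package treats reduced scales as first-class
(they exercise the identical code paths): the test suite uses 5–20 year
series with 2–3 starts and generation caps of 4–50, chosen so the whole
suite completes in minutes while still crossing every mechanism
(stress-damaged seasons, binding CV and HI filters, converged starts);
`scripts/acceptance.R` uses 10 years × 3 starts × cap 50. Other numerical
choices: anthesis triggers on the first day cumulative modified thermal
time reaches its threshold (no sub-daily interpolation); the flowering
window is clipped at maturity; a season that never reaches anthesis
(possible for extreme trait combinations at cold sites) returns zero
yield with its biomass and water balance intact; evaluation failures
inside the optimizer mark the candidate infeasible rather than aborting
the search; reflection (not clipping) keeps mutants in bounds without
piling probability mass on the bounds themselves.

## 6. Known limitations

* **No vernalization, no frost, no nitrogen.** Nutrient limitation is
  excluded by the optimal-management assumption. The missing cold-season
  controls matter more: with warm-winter climates nothing stops the
  optimizer from choosing very early flowering, which *evades* the
  flowering-window heat and drought mechanisms. At the hot-dry archetype
  the yield-stability filter (CV ≤ 10 %) reinforces this, driving both the
  sensitive and the tolerant ideotype to early, stress-avoiding phenology:
  the iT−iS contrast at the feasible optimum is therefore directionally
  positive but much smaller than the contrast among late-flowering
  genomes, where the two stress sets differ dramatically. Interpreting iT
  advantages estimated by this model as lower bounds is appropriate.
* **Minimal functional forms.** Linear threshold damage, a linear
  senescence multiplier, one soil bucket, no RUE temperature response, no
  separate soil evaporation. Each is the simplest form consistent with
  the mechanism it represents; each is localized in one small function
  and straightforward to replace.
* **Synthetic sites.** The archetypes span the target climate gradient
  but are not calibrated stations, so site-specific published yields are
  out of reach by design; what is reproducible is the procedure and its
  internal arithmetic, which the acceptance tests pin.
* **Ideotype yields are generous.** With optimal management, no biotic
  losses, a +10 % LUE and wide trait bounds, optimized potentials at the
  wettest sites reach the upper edge of field experience. The *gap*
  arithmetic is unaffected (both terms share the model), but absolute
  potentials should be read as model-internal ceilings.
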