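---
title: "Modelling cascading forest transitions on moisture-recycling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cascading forest transitions on moisture-recycling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raincascade)
library(dplyr)
```

## The model

`raincascade` treats a forested basin as a grid of locally bistable
vegetation cells coupled by atmospheric moisture recycling. Each cell `i`
carries a state `x_i` on the fold-bifurcation normal form,

    dx_i/dt = -x_i^3 + x_i + C_i + sum_k R_ki * w(x_k),

with `x = -1` the forest state and `x = +1` an open, degraded state. The
forest equilibrium exists only while the total forcing stays below the
critical value `c* = sqrt(4/27) ~ 0.3849`; beyond it the cell is committed
to the degraded state. Everything in the package is about building `C_i`
(the cell's own hydroclimatic forcing) and `R_ki` (the coupling it loses
when an upwind cell `k` transitions), integrating the system to its steady
state, and attributing each transition to its cause.

### Hydrological drivers

Two drivers force a cell: mean annual precipitation (MAP, the sum of
monthly precipitation over a hydrological year, October-September) and the
maximum cumulative water deficit (MCWD). MCWD runs the capped water-balance
recursion `CWD_m = min(0, CWD_{m-1} + P_m - E_m)` through the hydrological
year, starting at zero, and reports the absolute value of the deepest
deficit; it measures dry-season intensity in mm/yr. By default the deficit
resets at each hydrological-year start (the recursion is a 12-month
window); a cross-year carrying variant sits behind
`hydro_series(carry_deficit = TRUE)`. Missing months inside a year are a
hard error, never imputed. Both drivers are evaluated as 10-year running
means: single extreme years are episodes the forest is adapted to, while a
decade-scale shift is what commits a transition. A window `y..y+9` is
labelled `y+5`.

### Adaptation and thresholds

Each cell is assumed adapted to its own history: over a historical
adaptation window (65 years in the presets) we take the per-hydro-year mean
`mu` and standard deviation `Delta` of MAP and MCWD (population convention
by default, treating the window as the complete adaptation history; the
sample convention is a flag). The tipping thresholds sit one safety margin
away,

    MAP_crit  = mu_MAP  - sigma * Delta_MAP
    MCWD_crit = mu_MCWD + sigma * Delta_MCWD,

where `sigma` is the uncertain adaptive-capacity multiplier, drawn
uniformly from [0.75, 1.25] per cell (and per ensemble member). The MCWD
threshold formula mirrors the MAP one on the dry side of the mean. Cells
with a degenerate margin (`sigma * Delta = 0`) are flagged non-tippable and
clamped to forest. A robustness mode (`model_config(guard = TRUE)`) adds
hard safe boundaries: cells with decadal MAP above 1,850 mm/yr and MCWD
below 350 mm/yr are forbidden to tip (the AND combination is the default;
OR is available), and that mode is conventionally paired with lower
`sigma_bounds = c(0.5, 1)`.

### Forcing components

The windowed drivers map onto the normal form through ramps anchored at
the adapted mean (forcing 0) and at the threshold (forcing `c*`):

    C(MAP)  = c* (mu - MAP) / (mu - MAP_crit)
    C(MCWD) = c* (MCWD - mu) / (MCWD_crit - mu)

The printed reciprocal form of the MAP component (exponent -1) shares these
two anchor points but diverges at `MAP = mu` and is non-monotone across the
threshold; we therefore default to the monotone ramp and keep the literal
reciprocal behind `model_config(map_form = "literal_reciprocal")` for
comparison runs.

The two components combine as `max + (1 - max/c*) min`, algebraically the
symmetric `a + b - ab/c*`: two sub-critical stresses compound, and the
combination reaches `c*` exactly when the larger component does. Because
the expression is symmetric, the two case branches of the published
combination (keyed on which component is larger) evaluate identically; we
implement it once. Beyond `c*` the printed algebra turns non-monotone (a
second strong driver would *reduce* the combined forcing, eventually below
zero), which we regard as outside its intended operating range: the package
returns the larger component once it is at or above `c*`, keeping the
combination continuous and monotone for arbitrarily strong forcing.
`driver_mode = "map_only"` / `"mcwd_only"` run the single-driver ablations.

### Couplings

A moisture link that delivers `dMAP_ki` mm/yr from cell `k` to cell `i`
converts to a dimensionless coupling by the same yardstick as the forcing:

    R_ki,MAP  = c* dMAP_ki  / (mu_MAP,i  - MAP_crit,i)
    R_ki,MCWD = c* dMCWD_ki / (MCWD_crit,i - mu_MCWD,i)

so a link carrying a cell's entire adaptive range is exactly
tipping-equivalent. The drought-side effect `dMCWD_ki` is not uniquely
determined by an annual number; we compute it counterfactually: remove the
link's monthly flows from the target's monthly climatology, rerun the MCWD
recursion, and take the deepening. A link that only delivers moisture in
surplus months therefore has zero drought effect. (A cheap annual proxy —
the link's annual moisture times the target's deficit-month share of the
year — is available behind `link_effects(method = "annual_proxy")` for
speed comparisons; the counterfactual is the default.) The two compartments
combine with the same capped algebra as the forcing components.

In the coupling weight `w(x_k)` the source state is saturated to `[-1, 1]`
(a transitioned source removes at most its full link; a transiently
sub-forest state never injects moisture). We default to the zero-baseline
form `w(x) = (x+1)/2`: a forest source contributes nothing (its moisture is
already part of the realized climate that `C_i` is referenced to) and a
transitioned source contributes its full `R_ki` as lost stabilization. The
literal `x/2` weight, under which an all-forest network contributes a
standing stabilization of `-sum R/2`, is available as
`coupling_baseline = "literal_half_x"`.

### Deforestation

Deforestation enters the dynamics in three consistent pieces: the cleared
fraction `f_k` of a source removes `f_k (1-r)` of its outgoing moisture
permanently (a static forcing on its targets), the surviving share keeps
participating in the state-dependent coupling, and cells at least half
cleared are held at `x = +1`. At `f` of 0 or 1 with retention `r = 0` this
is exactly "remove the evapotranspiration of a transitioned cell"; the
fractional split guarantees the total link loss never exceeds `R_ki` when a
cell is both partly cleared and tipped. The retention parameter `r`
(default 0) supports the secondary-vegetation robustness mode, in which
cleared land keeps part of its evapotranspiration; no literature value is
hard-coded.

### Integration and the cascade oracle

The coupled system is integrated with fixed-step RK4 from `x = -1`
(deforested cells held at `+1`, guarded cells clamped) until the residual
norm falls below `1e-8`. The defaults are `dt = 0.01`, `t_max = 500`; for
ensemble-scale runs we use `dt = 0.2`, `t_max = 1200` — the cubic is stable
under RK4 up to `dt ~ 0.6` and the steady state is defined by the residual
tolerance, not the step size, while the larger `t_max` lets cascading
fronts (which cross the 20-cell synthetic basin in roughly 500-900 time
units of near-critical slowing) run to completion. Non-convergence at
`t_max` is warned about, never silent. A cell counts as transitioned when
its steady state exceeds 0 (the equilibria sit near -1 and +1, so the cut
is uncritical); exact equality of a forcing with `c*` does not tip (strict
inequality).

`discrete_cascade()` is a deliberately independent oracle: a fixed-point
iteration that tips any cell whose own forcing plus the couplings from
already-tipped sources strictly exceeds `c*`. It terminates in at most N
passes, is monotone in its seed set and couplings, and must agree with the
ODE steady states whenever every intermediate effective forcing keeps a
margin from `c*` (the equivalence is exercised on hundreds of random
networks in the test suite).

### Ensembles, risk and attribution

`run_ensemble()` redraws `sigma` for every member — by default
independently for every snapshot decade (one reading of "ten samples per
scenario per decade"), with `sigma_redraw = "per_member"` holding each
member's draw across decades — and reports per-cell transition risk (the
member fraction that transitioned), area-weighted transitioned-area
trajectories with their across-member standard deviation, the deforested
area, and pooled cause attribution. Transitioned-area percentages include
deforested cells (the deforested share is also reported separately, and an
alternative normalization relative to the initially forested area is
emitted alongside). Attribution labels a transitioned cell `map` or `mcwd`
if that component alone reached `c*` (the larger wins if both did),
`deforested` if it was held tipped, and `network` otherwise — the cell
tipped only because upwind transitions removed its moisture. The three-way
shares exclude deforested cells. `risk_plane()` tabulates snapshots by
basin-mean windowed MAP and MCWD and flags high risk at a transitioned area
of at least 10% (inclusive at the boundary).

## The synthetic scenario generator

The generator replaces Earth-system-model forcing and Lagrangian moisture
tracking with the minimal statistical structure the analysis relies on. It
is a first-class, tested component, and its defaults are the study
conditions of the package.

**Climate.** Monthly precipitation per cell is a deterministic seasonal
profile (baseline 2,200 mm/yr, four dry-season months at -140 mm/month,
optionally an east-west baseline gradient) modulated by interannual
anomalies and secular trends; evaporation is constant at 100 mm/month.
Interannual variability has a standard deviation of 550 mm/yr — 25% of the
baseline, so that losing one standard deviation of moisture means losing
about a quarter of a cell's MAP, and one standard deviation of MCWD is
roughly a third of its mean. Anomalies are indexed by hydrological year and
applied multiplicatively, so their absolute imprint follows the seasonal
climatology. Sixty percent of the variance sits in a basin-coherent
quasi-biennial episodic mode (alternating drought and wet episodes with
random phase): forests are adapted to these recurrent episodes — they carry
full weight in the historical standard deviation — while 10-year averaging
cancels them almost exactly, which is precisely the point of working on
decadal means. The remainder is AR(1) noise (white by default) split into a
basin-shared part (25% of its variance) and cell-local scatter, plus an
independent dry-season-only anomaly (8 mm/month) that varies drought
intensity without touching annual totals. Drying trends act on the annual
total (mm/yr per decade) and on dry-season intensity (mm/month per decade,
compensated in wet months); the preset profiles weight them spatially
("east": 1.7 at the upwind edge through zero to a mild wetting of -0.3 at
the downwind edge, as large-scale drying projections typically show). A
`recovery_start_year` reverses the accumulated trends at the same rate
(wetting scenarios), and `noise_until` mutes anomalies after a given year
so committed responses to the secular signal can be isolated.

**Moisture network.** Directed monthly links are generated on the monthly
climatology: source attractiveness is the source's evaporation times an
exponential kernel displaced one step along the prevailing wind (default
westward, e-folding 3 cells, weights below 0.1 dropped and shares
renormalized), so sources deposit preferentially downwind. Incoming mass at
each target is scaled to a per-cell recycling fraction that grows downwind
from 30% to 100% of `recycling_target` (default 0.5 — "up to half" of
precipitation forest-generated, with the downwind interior the largest
receiver and a basin mean near one third), normalized against the
best-connected cell so edge cells saturate below the target. Conservation
is structural: incoming link mass never exceeds the target's precipitation.
The transpiration/interception split (36%/22%) is carried as metadata only.

**Deforestation.** A logistic clearing front advances from a chosen edge
(east by default) while the basin-wide cleared fraction ramps linearly —
in the severe preset from 18% to 35% over 2020-2050, held constant
afterwards.

**Presets.** `weak_drying` (no trend), `moderate_drying` (-20 mm/yr and
-0.5 mm/month per decade), `strong_drying` (-45 and -1.5) and
`strong_drying_deforestation` (strong drying plus the clearing front) share
all stochastic settings, so scenarios differ only in forcing. The
magnitudes were chosen once so that the trend-free preset commits
essentially no transitions, the strong preset reaches a systemic transition
within the century, and severity ordering is strict.

**What the generator does not emulate.** Real forcing fields have rich
spatial anomaly patterns, trends that accelerate over time, and
scenario-specific moisture networks from explicit parcel tracking; the
synthetic basin is small, rectangular and statistically homogeneous apart
from the gradients described above. Passing tests therefore demonstrate the
correctness and qualitative behaviour of the machinery — conservation,
threshold algebra, cascade propagation, monotone responses, attribution
accounting — not quantitative projections for any real basin. One visible
consequence of the homogeneity is that the synthetic basin transitions
rather abruptly once the committed region becomes supercritical: with a
shared adaptation statistic and a dense kernel, cascading fronts that start
in the dried upwind third can traverse most of the domain, so
transitioned-area trajectories saturate earlier and higher than a
heterogeneous real basin would.

## Numerical choices and degenerate inputs

* RK4 steady-state tolerance `1e-8` (max-norm of the derivative); every
  reported state satisfies its cubic to `<1e-6`.
* Strict inequality at the threshold: forcing exactly `c*` does not tip.
* Kernel weights below the cutoff are dropped *before* normalization, so
  sparsification never violates conservation.
* Counterfactual link removal clamps precipitation at zero (with a
  warning) if a link nominally exceeds the target's monthly precipitation.
* Degenerate adaptation margins flag the cell non-tippable (warning);
  degenerate year ranges, negative fractions, inconsistent grids and
  malformed files raise classed input errors.
* All randomness flows from explicit integer seeds; ensembles derive
  member/decade seed streams from one master seed and are byte-reproducible.

## A worked run

```{r run, eval = FALSE}
pre <- scenario_preset("strong_drying", seed = 1)
cfg <- model_config(dt = 0.2, t_max = 1200)
res <- run_scenario(pre, nx = 20, ny = 20, config = cfg, master_seed = 1)
glance(res)        # per-decade transitioned area, MAP/MCWD, high-risk flag
res$attribution    # three-way cause split
plot_area_series(res)
plot_risk_map(res, attr(res, "grid"))
```

The problem sizes used throughout the package's own checks — a 20 x 20
basin, 10 ensemble members, 8 decade snapshots, 65 adaptation years — were
chosen as the smallest configuration on which the basin-scale phenomena
(regional cascades, episodic spikes, severity ordering) are cleanly
expressed.

## Known limitations

* The climate is exogenous: vegetation state never feeds back on the
  climate fields, only on the moisture network term (the offline design).
* Reversed forcing/hysteresis experiments are out of scope; only committed
  equilibria under monotone or relaxing forcing are analysed, and the pace
  of transitions is deliberately unresolved.
* The transpiration/interception split is bookkeeping, not dynamics.
* Attribution is threshold-based; a cell pushed over jointly by a direct
  driver and the network is credited to the direct driver.
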