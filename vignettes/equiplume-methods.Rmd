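---
title: "Methods: emission estimation and dispersion of horse allergen and odor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emission estimation and dispersion of horse allergen and odor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiplume)
```

## Scope and model chain

`equiplume` estimates airborne horse-allergen and ammonia exposure around an
equine facility in four linked stages:

1. **emission estimation** for the stable (indoor concentration ×
   ventilation flow × duct transfer), the pastures (inverse dispersion), and
   the manure heap (passive flux samplers);
2. **temporal disaggregation** of daily emission totals into hourly series
   via activity, occupancy, weather and seasonal indices;
3. **forward dispersion** with an hourly Gaussian plume to receptor grids;
4. **analysis** of receptor series: period means, source attribution,
   measured-vs-modeled compliance, and odor-survey summaries.

The dispersion core is deliberately a flat-terrain Gaussian plume. Advanced
operational models add terrain, land use and building effects; those inputs
and that machinery are out of scope here, and results in complex terrain
should be read with that limitation in mind. What the plume core must get
right — and what the test suite checks — is linearity in emission, mass
conservation, geometric consistency, and the hourly bookkeeping that the
emission indices and the inversion depend on.

## The plume kernel and its parameters

Concentration from a point release of strength $Q$ (units s$^{-1}$) at
effective height $H$, evaluated at downwind distance $x$, crosswind offset
$y$ and height $z$ under wind speed $u$:

$$
C = \frac{Q}{2\pi u \sigma_y \sigma_z}
  \exp\!\left(-\frac{y^2}{2\sigma_y^2}\right)
  \left[\exp\!\left(-\frac{(z-H)^2}{2\sigma_z^2}\right) +
        \exp\!\left(-\frac{(z+H)^2}{2\sigma_z^2}\right)\right]
$$

The image term reflects the plume at the ground, so the crosswind/vertical
integral of $C\,u$ recovers $Q$ exactly — the mass-consistency property the
suite verifies by quadrature at 100/500/1000 m for all six stability
classes.

**Spread curves.** $\sigma_y$ and $\sigma_z$ are power laws $a\,x^b$ (x in
m) per stability class, shipped as the data frame `plume_sigma_coefs`. The
coefficients approximate the classic rural Pasquill–Gifford curves at
100–1000 m, but both $a$ and $b$ were chosen jointly monotone across
classes so that a more unstable class has the larger $\sigma_z$ at *every*
distance ≥ 1 m. The classic piecewise fits violate this in the near field
(curves cross below ~20 m and some carry additive offsets that go negative),
which would break the class-ordering invariant the area-source tiling relies
on. The cost is accuracy at the extremes: the very-unstable class grows
superlinearly in reality, and a pure power law undershoots it beyond ~1 km.
$\sigma_z$ carries a mild roughness correction $(z_0/0.1)^{0.2}$; the
coefficients are data and can be replaced wholesale.

**Stability classification.** The Monin–Obukhov length $L$ is an input
(sign: negative = convective, positive = stratified). Classes are assigned
by a Golder-style boundary table linear in $(1/L, \log_{10} z_0)$, with
$z_0$ clamped to the nomogram's 0.001–0.5 m validity range. Neutral is any
$|1/L| < 10^{-4}$ m$^{-1}$, so "neutral" never needs an infinite sentinel.
The mapping is piecewise constant and monotone in $1/L$: sweeping $1/L$
never jumps from unstable to stable without passing neutral.

**Calm hours.** The kernel diverges as $u \to 0$, so hours with
$u < 0.5$ m/s are flagged calm, carry `NA` concentration, and are excluded
from period means by default (`calm = "zero"` is available for conservative
averaging). The threshold is configuration, not physics.

**Area sources.** Polygons are tiled into sub-point-sources at a pitch of
one tenth of the shortest edge, capped at 5 m. Receptors closer than one
pitch to a sub-source (including receptors inside the polygon) are evaluated
with a minimum downwind distance of one pitch and flagged `near_field` —
this bounds the $1/(\sigma_y\sigma_z)$ singularity instead of hiding it.
Halving the pitch moves receptor values by well under 1% at the default,
which the suite checks by self-convergence; superposition of two
half-polygons against the full polygon guards the tiling bookkeeping.

**Deposition.** Dry deposition uses the Chamberlain source-depletion factor
$\exp[-\sqrt{2/\pi}\,(v_d/u)\int_0^x e^{-H^2/2\sigma_z^2}/\sigma_z\,d\xi]$,
evaluated analytically for ground-level releases (where the integrand is a
pure power law) and by a graded cumulative trapezoid otherwise. Defaults
$v_d = 0.002$ m/s (PM10-like particles) and 0.02 m/s (coarse mode) are
declared configuration: no measured deposition velocity exists for this
material, only the statement that deposition matters.

## Emission models

**Stable.** The duct transfer chain is pure arithmetic:
`pm10_pass_through(5.9, 7.6)` ≈ 0.776 (77% of PM10-bound allergen leaves
with the ventilation air), and `tsp_transfer_factor(1.3, 1.7, 0.77)` ≈ 0.589
(the TSP/PM10 ratio differs between stable and duct because coarse particles
settle before reaching the duct). Emission = indoor TSP allergen ×
ventilation flow × transfer factor. The ventilation flow is a required
site input with no default. Relative uncertainties of concentration and flow
add linearly (±10% + ±15% = ±25%) — first-order propagation for a product,
which is the convention for these field budgets.

The hourly **activity index** maps each hour's class
(no activity/no horses … much activity/half-full stable) to a weight table
and normalizes every day to mean 1, so base × index conserves the daily
total. The default weights (0.1, 0.6, 1.0, 1.4, 2.2) encode the observed
ordering — afternoon grooming/saddling highest, quiet occupied nights low,
empty stable lowest — and are configuration: the diurnal pattern was
published as a figure, not numbers, so only the ordering is evidence-backed.
If measured stable TSP is available the index can instead be derived from
the background-corrected TSP signal, with negative corrections clipped to
zero (subtracting outdoor TSP can transiently exceed the indoor reading).

**Pastures.** Daily scale factors: dry + horses = 1, rain + horses = 0.18,
dry + no horses = 0.10, rain + no horses = 0 (`scaling_rule()`; the 18% and
10% come from continuous field measurements, the zero from the observation
that a wet, empty pasture does not resuspend allergen). The diurnal index is
proportional to the number of horses present, normalized so the
dry-with-horses reference day has mean 1 and then multiplied by the scale
factor — so a rain day keeps its shape at 18% amplitude rather than being
re-normalized back to 1, which would silently cancel the factor. A
horse-free dry day falls back to a flat profile at 0.10. The seasonal table
(winter minimum, summer maximum, annual mean 1) is likewise configuration
with only its ordering evidence-backed.

**Inversion.** With emissions entering linearly, the period-mean
concentration at observation $i$ is $\sum_j M_{ij} q_j$ where
`unit_response_matrix()` computes $M$ by forward runs at unit emission
density and $q$ are the densities to estimate. A source whose emission is a
`time`/`rate` table is used as the *known unit-density shape*: the fit then
estimates the base density multiplying that shape, which is exactly how a
daily-basis inversion with known diurnal indices is posed, and what makes
the noise-free round trip close to machine precision. The fit is
nonnegative least squares via an active-set clip-and-refit (negative
estimates are dropped and the remainder refitted; emission cannot be
negative); an independent NNLS implementation cross-checks it in the test
suite. The fit is done in linear concentration space — the model is exactly
linear in $q$ there, preserving the closed-form round-trip property that a
log-space fit would lose. Below-detection observations enter at half the
detection limit by default (`exclude` and `substitute_full` are available);
half-limit substitution is the conventional exposure-science default and the
choice is reported in the fit object. Windows that are entirely calm drop
out of the fit with their rows flagged.

**Manure heap.** The passive flux sampler physically integrates
concentration × wind speed × wind-direction cosine, so the software applies
*no* wind weighting — re-applying it would double-count an integration the
hardware already performed. The campaign total is the double sum
$E = \sum_m \sum_n W_m \Delta h_n (Q_{H,mn}-Q_{S,mn}) \Delta t$ over the
complete mast × height grid, with per-mast widths and per-level height
intervals (mast spacing in the field was 15–20 m, not uniform). Negative
cells (back-flux) are kept with sign. The effective sampling area is a
sampler calibration constant supplied per campaign.

## Odor analysis

Detection curves report, per distance edge, the fraction of *all*
respondents detecting at-or-beyond and at-or-within that distance;
never-detecting walkers stay in every denominator (the field percentages
were quoted against all recruited walkers). Quantiles are order statistics
on the same denominator and return an explicit unattainable signal when too
few respondents detected. The logistic model treats the first-detection
distance as a continuous variable with survival
$S(d) = \mathrm{plogis}(\mathrm{slope}\,(d_{50}-d))$: never-detectors are
censored below 0 m, instant detectors censored at the walk start, and the
two parameters are estimated by direct maximum likelihood (Nelder–Mead on
$(d_{50}, \log \mathrm{slope})$). Complete separation (all detections at one
distance) is flagged rather than fitted. `tracer_comparison()` joins the
curve with modeled ammonia and allergen profiles and flags bins where people
smell the source although modeled ammonia sits below the supplied odor
threshold; the threshold has no defensible physiological default and must be
given by the user.

## The synthetic generator

Every input table can be generated with a seed: met series (diurnal wind
cycle, AR(1) direction wander, convective-midday/stable-night Obukhov
cycle, Bernoulli rain days; a `"campaign"` preset with dry weather, wind
uniform in 1–3 m/s and ~20 °C), receptor observations (forward-model daily
means × lognormal noise, censored at the assay limit), particle-fraction
tables (mass ordering enforced, coarse-fraction allergen density ~10× the
fine fractions, duct/stable TSP:PM10 ratios centered on 1.3/1.7, densities
independent of masses so no mass–allergen correlation appears), flux
campaigns (a known total distributed over the grid with an exponential
vertical decay and inverted to tube masses), and odor surveys (logistic
survival inversion, 1-m walking steps). Generators derive fixed sub-seeds
from the one scenario seed, so a whole scenario reproduces from a single
integer. Lognormal measurement noise was chosen because concentrations are
positive and field uncertainties are quoted relatively.

What the generator does *not* emulate: terrain and building effects on the
wind field, within-pasture herd clustering (the dominant error source in
real inversions — a herd parked upwind of a receptor violates the uniform
area-emission assumption unrecoverably), natural doorway ventilation, and
multi-compound odor chemistry. Passing round-trip tests therefore
demonstrate internal consistency of the method chain, not field accuracy;
against real data the comparable chain achieved daily-mean compliance of
roughly ±20–35%, which is why `compare_measured_modeled()` reports the
fraction within both tolerances instead of asserting either as pass/fail.

## Numerical choices and problem sizes

* Quadratures: depletion integrals on 600–800-node graded grids (exact
  closed form for ground-level releases); mass-consistency checks with
  trapezoid rules on ±10σ windows.
* NNLS tolerance $10^{-10}$; rank-deficient sub-fits return zero for the
  affected coefficients rather than `NA`.
* Tie-breaks: the near-field floor clamps downwind distances to one tiling
  pitch; boundary receptors count as inside polygons.
* Degenerate inputs: zero-area polygon slivers fall back to a centroid
  sub-source carrying the full area; all-zero activity days refuse to
  normalize rather than return `NaN`.
* The shipped scenario (`scenario_gunnebo()`) uses a 17-horse stable
  (stack at 6 m), two 50 m × 50 m pastures with 8 horses each out
  09:00–17:00, a pasture emission density of 2000 U m⁻² h⁻¹ (chosen once so
  receptor levels land in the 0.3–1.3 U/m³ range observed 100–200 m from
  real facilities), and seven receptors 130–200 m east. Tests and the
  acceptance script run it at 1–30 days; the month-long run checks the
  qualitative claims (elevated-stack ground maximum strictly downwind;
  pasture share exceeding the stack share at every nearby ground receptor,
  consistent with the 0.1–2% stack contribution seen in the field).
* The headline scaling ratios (rain/dry = 18%, horse-free/occupied = 10%)
  are computed as ratios of 24-h mean concentrations from actual forward
  runs. The occupancy comparison holds occupancy constant over the 24 h for
  the with-horses series: with a peaked diurnal shape the concentration
  ratio would fold in the covariance between the shape and the hourly
  meteorology, while the field figure rests on 24-h integrated samples —
  the flat comparison isolates the factor the rule encodes.

## Known limitations

Flat terrain only; no building downwash, plume rise, wet scavenging or
chemistry. Power-law sigmas degrade outside ~50 m–2 km. The inversion
assumes spatially uniform emission within each pasture polygon. Odor is
represented only through the ammonia tracer and survey statistics — no
olfactometry. The activity, diurnal, and seasonal index tables are
qualitative configuration calibrated to observed orderings, not measured
values; anyone with site measurements should replace them.
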