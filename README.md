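# equiplume

Horse allergen and odor exposure around equine facilities: emission
estimation, Gaussian-plume dispersion, inverse emission fitting, and
odor-survey analysis.

## The problem

Riding stables are increasingly close to housing, and planners need
quantitative estimates of how far horse allergen (carried on airborne
particles, measured in U/m³ where 1 U = 1 ng of allergen standard) and
stable/manure odor travel. Direct measurement is expensive and censored by
assay detection limits (2 U/m³ for the standard ELISA, 0.2 U/m³ amplified),
so the practical route is: estimate source emissions from a handful of field
measurements, then disperse them with a model at hourly resolution.
`equiplume` implements that whole chain for the three source types of a
typical facility — the stable ventilation outlet, the pastures, and the
manure heap — plus a seeded synthetic-data generator so every stage can be
exercised and validated without field data.

## What is computed

**Stable emissions.** Indoor TSP-bound allergen concentration × ventilation
flow × a duct transfer factor. The transfer factor combines the PM10
pass-through (duct/stable allergen-per-PM10 ratio, 5.9/7.6 ≈ 77%) with the
TSP/PM10 mass ratios in duct and stable (1.3 and 1.7):
`1.3/1.7 × 77% ≈ 59%` of the stable's TSP-bound allergen leaves through the
duct. The daily total is redistributed hourly by a five-class activity index
(grooming/saddling peak in the afternoon, quiet nights). Relative
uncertainties of the concentration (±10%) and flow (±15%) add to ±25% on
the emission.

**Dispersion.** A ground-reflected Gaussian plume kernel

    C = Q / (2π u σy σz) · exp(−y²/2σy²) · [exp(−(z−H)²/2σz²) + exp(−(z+H)²/2σz²)]

with power-law spread curves σ = a·x^b per stability class (classified from
the Monin–Obukhov length via a Golder-style (1/L, z₀) table), polygonal area
sources evaluated by sub-source tiling, dry deposition via a
source-depletion factor, calm hours flagged and excluded.

**Pasture emissions by inverse dispersion.** Pasture area-emission densities
are fitted by nonnegative least squares on the linear forward model: a
unit-response matrix (period-mean concentration per unit emission density)
times the densities is matched to receptor observations. Emission series
carry occupancy/weather indices: rain days emit 18% of dry days, a
horse-free pasture 10% of an occupied one, rain + no horses nothing.

**Manure-heap ammonia.** Passive flux samplers integrate concentration ×
wind speed × direction cosine through a vertical plane; the campaign total
over a 3-mast × 3-height grid is

    E = Σₘ Σₙ Wₘ · Δhₙ · (Q_H,mn − Q_S,mn) · Δt   [g NH₃]

**Odor surveys.** Walk-toward-source surveys are summarized as detection
curves and quantiles, fitted with a logistic detection-distance model
(`d50`, slope), and compared against modeled ammonia as an odor tracer.

## Worked example

```r
library(equiplume)

tsp_transfer_factor(1.3, 1.7, pm10_pass_through(5.9, 7.6))
#> [1] 0.5941176          # 59% of TSP-bound allergen leaves via the duct

sc <- scenario_gunnebo(seed = 42, days = 7)   # synthetic 17-horse facility
fw <- run_forward(sc)
fw$period_mean |>
  dplyr::group_by(receptor) |>
  dplyr::summarise(mean_U_m3 = sum(mean_conc))
#>   receptor mean_U_m3
#> 1 site1        1.28     # receptors 130-200 m east of the facility
#> 2 site2        0.623
#> ...
#> 7 site7        0.318
```

Week-mean allergen levels at receptors 130–200 m from the facility come out
at 0.3–1.3 U/m³ — the "well below a few U/m³ beyond 100–200 m" regime that
makes allergen, not odor, the binding constraint for siting. The
`attribution` table of the same run shows the pastures contributing >95% of
the total at every receptor: the elevated stack plume touches down further
out and contributes only a few percent at ground level nearby.

```r
srv <- generate_odor_survey(102, d50 = 60, slope = 0.1, seed = 10)
tidy(fit_detection_model(srv))
#>   term  estimate
#> 1 d50     59.3          # recovered from 102 synthetic walkers
#> 2 slope    0.0938
detection_quantile(srv, 0.65)
#> [1] 65                  # 65% had detected by 65 m
```

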