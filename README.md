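# trackscape

Species- and guild-level **isoscapes** from concurrent GPS tracking and
blood-plasma stable isotope values of central-place foraging seabirds.

Marine predators can be geolocated retrospectively from the δ13C and δ15N
values of their tissues — but only against a reference map ("isoscape") of
how those values vary in space. Because blood plasma integrates roughly the
last 7 days of diet, a bird tracked by GPS and blood-sampled on recapture
provides one calibrated point: its plasma values tied to where it actually
foraged that week. `trackscape` turns tables of such birds into isoscapes.

The pipeline implements, end to end:

1. **Track processing** — foraging-trip segmentation at the colony,
   McConnell-style maximum-speed filtering (135 km h⁻¹ flying birds,
   10 km h⁻¹ penguins), regular-interval interpolation (linear, or a
   continuous-time correlated random walk — an integrated
   Ornstein–Uhlenbeck velocity model fit by maximum likelihood and smoothed
   by a Kalman/RTS pass), and colony buffering (15 km / 2 km).
2. **Behavioural annotation** — a quadrant-constrained four-component
   Gaussian-mixture EM over (speed, |turning angle|) for flying birds
   (low-speed/high-turn = foraging, "actively sitting"); a strict
   species-mean speed threshold for divers.
3. **Lipid normalization** — per-species regression of
   Δδ13C = δ13C_del − δ13C on ΔC:N = C:N_del − C:N from paired
   raw/delipidated samples, used to correct raw-only samples
   (δ13C_cor = δ13C + Δδ13C); C:N > 3.5 flags lipid-rich plasma.
4. **Mean foraging locations** — foraging time per grid cell
   (0.5° flying / 0.05° diving, or derived from mean 2-h travel distance
   rounded up to 0.05°), inside the 7-day window before blood sampling,
   collapsed to one time-integrated weighted mean location per individual.
5. **Isoscape estimation** — Pearson correlations/regressions of plasma
   values against foraging latitude, longitude or distance to coast;
   **ordinary kriging** with weighted-least-squares best-fit variograms
   (spherical/exponential/gaussian) on a convex-hull + buffer mask;
   surface differencing between species; guild-level **bootstrap
   ensembles** (k individuals per species, B replicates, cell-wise mean).
6. **Fronts and zones** — sub-tropical / sub-Antarctic / Antarctic polar
   fronts as SSH contours (0.92 / 0.03 / −0.48 m), the four water zones
   they delimit, mean ± SD of isoscapes per front band (±1°) and zone, and
   back-calculation of front isotope values from latitude regressions at
   51°S and 42°S.

A synthetic-data module (`baseline_field`, `simulate_track`,
`sample_plasma`, `add_lipid_contamination`, `ssh_field_synthetic`,
`simulate_study`) generates tracks over latitudinal isotope gradients with
full ground truth, so every stage is testable by parameter recovery
without field data.

## The model at the core

Ordinary kriging predicts the isotope value at grid location *s₀* as
Ẑ(s₀) = Σᵢ wᵢ Z(sᵢ) with weights solving

```
[ C   1 ] [ w ]   [ c0 ]
[ 1ᵀ  0 ] [ μ ] = [ 1  ]
```

where C is the sample covariance matrix implied by the fitted semivariogram
γ(h) (C(h) = nugget + psill − γ(h), the nugget treated as micro-scale
variance so data are honoured at sample points) and the unbiasedness
constraint Σwᵢ = 1 enters via the Lagrange multiplier μ. Variograms are fit
to pair-count-weighted empirical semivariances over lag bins up to 2/3 of
the maximum distance, and the candidate model with lowest weighted SSE wins.

## Worked example

```r
library(trackscape)

# a baseline field with the combined-study d13C gradient (0.21 permil/deg)
field <- baseline_field(grid_spec(0.5, c(0, 75), c(-75, -25)),
                        field_spec(0.21, -11.25), field_spec(0.12, 18.29))

# two flying species, ten tracked + blood-sampled individuals each
study <- simulate_study(c("albatrossA", "albatrossB"), 10, field, seed = 42)

run <- run_pipeline(study$tracks, study$isotopes,
                    pipeline_config(boot_B = 50,
                                    boot_k = c(flying = 7, diving = 9),
                                    seed = 42))
run
#> trackscape pipeline run
#>   individuals located: 20 (of 20 with joined data)
#>   species surfaces: 4   guild surfaces: 2

correlate(run$locations, "lat", isotope = "d13c")
#> R = 0.99, p = 6.75e-16, value = 0.19 (lat) -11.4  [n = 20]

back_calculate_front_value(correlate(run$locations, "lat",
                                     isotope = "d13c"), 51)$reported
#> [1] -21.1

summary(run$surfaces[["albatrossA.d13c"]])
#> isoscape of d13c (permil)
#>   samples: 10   defined cells: 1943 (of 4128)
#>   surface range: [-22.98, -18.50]   mean kriging SD: 0.117
#>   variogram [gaussian]: nugget = 0.004242, partial sill = 6.663, range = 27.4 deg
```

The pooled regression recovers the planted 0.21 ‰/° gradient (0.19 here,
from 20 noisy individuals); evaluating it at 51°S back-calculates the
Antarctic-polar-front plasma δ13C (−21.1 ‰); the kriged surface spans the
range of the sampled plasma values. `plot(run$surfaces[["albatrossA.d13c"]])`
draws the surface with its sample locations.

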