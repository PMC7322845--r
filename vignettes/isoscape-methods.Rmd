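---
title: "Methods: predator-level isoscapes from tracks and plasma isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predator-level isoscapes from tracks and plasma isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackscape)
```

## The estimation problem

Blood plasma of a seabird integrates the isotopic composition of its prey
over roughly the week before sampling. A GPS-tracked, blood-sampled
central-place forager therefore yields one spatially referenced isotope
observation: its δ13C and δ15N values attached to a single *time-integrated
weighted mean foraging location*. Pooling such observations across
individuals of a species (or a guild) and interpolating them by ordinary
kriging produces a predator-level isoscape: a reference surface against
which untracked animals can later be geolocated from tissue values alone.

Each stage of the pipeline, its assumptions, and the choices made where the
design was genuinely open are documented below.

## Track processing

A trip runs from the last fix on land to the first fix back on land.
"On land" is defined as lying within `land_radius_km` (default 0.5 km) of
the colony point; a desk-scale stand-in for a coastline polygon that
removes a GIS dependency. Implausible fixes are removed by a McConnell-style
forward pass: walking the trip, any fix implying a speed above `vmax`
(135 km h⁻¹ flying, 10 km h⁻¹ diving) from the last retained fix is
dropped, and the pass repeats to fixation; the first fix is anchored. The
exact filter variant is a documented choice — only the rule's speed
thresholds are fixed by the study design.

Flying-bird trips are then linearly interpolated to hourly fixes. Linear
interpolation is performed in raw lon/lat, adequate below 60° latitude at
hourly spacing (error under ~0.1 km for 30 km steps). Diving-bird fixes are
irregular (GPS is lost underwater), so they are regularized with a
continuous-time correlated random walk: per planar axis an integrated
Ornstein–Uhlenbeck velocity process with parameters (β, σ, τ) shared
between axes, estimated by maximum likelihood through the Kalman-filter
innovations (L-BFGS-B on log-parameters, bounds log β ∈ [log 10⁻³, log 50]
h⁻¹, τ ≥ 1 m) and smoothed by a fixed-interval RTS pass. Non-convergence
falls back to linear interpolation with a warning. Finally fixes within the
colony buffer (15 km flying / 2 km diving) are discarded; individuals whose
fixes all fall inside the buffer are excluded downstream.

The canonical order is segment → filter → interpolate → buffer; a
regression test documents that permuting filter and interpolation changes
the result on a planted-outlier track.

## Behavioural annotation

For flying birds, a four-component Gaussian-mixture EM is run in
standardized (speed, |turning angle|) space. Components are initialized at
the four quadrants of the per-variable medians and re-bound to quadrants
after every M-step (the two lowest speed means form the low-speed pair;
within each pair the lower |turn| mean is the low-turn component), which
keeps the four states interpretable as LL, LH, HL, HH throughout.
Foraging is the low-speed/high-turn state LH ("actively sitting").
The magnitude of the turning angle, not its sign, is the clustering
variable, following the published convention for this class of classifier.
Degenerate covariances trigger up to five seeded jittered restarts, then a
median-threshold fallback; fewer than 20 usable steps go straight to the
fallback. Standardization addresses the scale disparity between km/h and
radians; reported component means are transformed back to natural units.

For divers the rule is simpler: the threshold is the arithmetic mean speed
pooled over all steps of the *species* (not the individual), and a step
forages iff its speed is *strictly* below it. The strict inequality means a
constant-speed track yields no foraging labels at all — the degenerate case
is explicit rather than arbitrary.

## Lipid normalization

Lipids are depleted in ¹³C, so lipid-rich plasma (C:N mass ratio > 3.5)
reads artificially low in δ13C. For samples measured both raw and
delipidated, the per-pair differences

- Δδ13C = δ13C_del − δ13C
- ΔC:N = C:N_del − C:N

are regressed (OLS, Δδ13C on ΔC:N) per species, never pooled across
species. For a raw-only sample the C:N excess term is
mean(C:N_del) − C:N_raw — negative for lipid-rich samples, so with the
typically negative fitted slope the correction added back is positive.
δ15N is always taken from raw plasma and never altered.

Two algebraic forms of the correction are implemented: the **direct**
regression prediction Δδ13C = m·ΔC:N + c (the default, consistent with the
fitting procedure) and a **printed-inverse** form Δδ13C = (ΔC:N + c)/m
offered behind a configuration switch. The two forms generally disagree;
both are kept because published formulations of this correction differ, and
the package takes no position beyond defaulting to the form implied by the
described regression. The synthetic contamination generator is the exact
inverse of whichever form is selected, so the round trip is an identity to
numerical precision — this is what the round-trip tests certify.

## Mean foraging locations

Only trips ending within the 7-day window before blood sampling
contribute; trips straddling the window start are trimmed to it rather
than excluded (the window rule is ambiguous on this point; trimming uses
all data the window covers). Each foraging fix credits its nominal
sampling interval (1 h / 2 min after interpolation) to its half-open grid
cell; weights are normalized, and the location is the weight-averaged cell
*centre* (centres rather than corners carry the coordinate; grid origins
are snapped to multiples of the cell size globally so runs are
reproducible and grids from different data align). Grid cell size is
either fixed per guild (0.5° flying / 0.05° diving) or derived from the
data as the mean 2-hour along-track distance, converted at 111.19 km per
degree — one conversion constant used everywhere — and rounded *up* to the
next 0.05°.

## Variograms and kriging

The empirical semivariogram uses 12 equal-width lag bins up to 2/3 of the
maximum pairwise distance, in isotropic geographic degrees. Working in
degrees rather than a projection is a known approximation: at 47°S one
degree of longitude is ~76 km against ~111 km per degree of latitude. The
study extents are modest in this compression and the approximation is
applied uniformly to fitting and prediction, so it cancels to first order;
a projected-coordinate hook would be the first extension for work nearer
the poles.

Spherical, exponential and gaussian candidates are each fit by
pair-count-weighted least squares over (nugget, partial sill, range), and
the lowest weighted SSE wins. Numerical safeguards, each chosen once:

- the range is bounded by the observed lag span, so the sill is identified
  by the data rather than extrapolated;
- the gaussian model gets a nugget floor of 10⁻³ of the maximum empirical
  semivariance — the zero-nugget gaussian covariance is numerically
  singular;
- if spatial structure improves the weighted SSE by less than 5% over a
  flat fit, the pure-nugget model is preferred (the partial sill is
  unidentified in that regime);
- a fitted range below the first resolvable lag is folded into the nugget;
- constant-valued samples return a unit-sill convention model (every valid
  model reproduces a constant exactly);
- kriging systems with reciprocal condition below 10⁻¹⁰ get a ridge of
  10⁻⁶ of the sill on the sample diagonal before solving, and exact
  duplicate coordinates are averaged beforehand.

The nugget is attributed to micro-scale variation, so C(0) = nugget +
partial sill and predictions honour the data exactly at sample locations —
matching the default behaviour of the standard geostatistical software
stack. Kriging weights always sum to 1 (the Lagrange-multiplier
unbiasedness constraint); a brute-force dense-solve oracle in the test
suite certifies the solver to 10⁻⁸ ‰ on small configurations.

Surfaces are estimated on the convex hull of the sample locations dilated
by 0.5° (flying) or 0.05° (diving); collinear locations degrade to a
buffered segment with a message. Species surfaces with a shared cell size
can be differenced cell-aligned; disjoint masks raise an error rather than
returning an empty surface.

## Bootstrap guild ensembles

To combine species with unequal sample sizes, k individuals per species
(22 flying / 9 diving in the motivating design) are drawn *without*
replacement — the stated purpose is equalizing species contributions, which
subsampling achieves directly; with-replacement sampling is available by
flag. Each of B replicates refits its own variogram (the alternative,
freezing one variogram, was rejected since the variogram is itself
sample-dependent) and kriges **only within its own buffered convex hull**
intersected with the guild mask. Kriging far outside a replicate's data
support is extrapolation, and smooth covariance models extrapolate wildly;
confining each replicate to its hull keeps every surface inside the range
of its data. The ensemble surface is the cell-wise mean over the replicates
defining each cell (the per-cell replicate count is returned), and the
cell-wise min/max envelope is retained as a diagnostic.

## Fronts, zones and back-calculation

Fronts are fixed SSH contours — sub-tropical 0.92 m, sub-Antarctic 0.03 m,
Antarctic polar −0.48 m — extracted by scanning each longitude column for
level crossings with linear interpolation in latitude (equivalent to
marching squares for the latitude-monotone fields in scope; the longest
connected run of columns is taken if crossings are disjoint). The four
zones partition the domain from north to south; points exactly on a front
are assigned northward, a boundary convention chosen once.

"Within one degree along a front" is interpreted as a ±1° band *in
latitude* relative to the front's local latitude — following the front,
not a great-circle corridor. Front isotope values are back-calculated from
latitude regressions evaluated at 51°S (Antarctic polar) and 42°S
(sub-tropical); reported values are rounded half away from zero to one
decimal, the convention required to reproduce published tabulations from
their printed regression coefficients. Cross-species aggregation uses the
sample (n−1) standard deviation. Two published per-species entries are
known not to recompute from their printed (rounded) coefficients; they are
documented as such and excluded from the recomputation checks rather than
reverse-engineered.

## The synthetic generator

`simulate_track` is a two-state (transit/forage) first-order correlated
random walk from the colony: truncated-normal speeds, wrapped-normal
turning angles, Markov switching between states, and a homing rule so
trips start and end at the colony. Flying defaults (45 ± 8 km h⁻¹ transit,
8 ± 3 km h⁻¹ foraging, hourly fixes, up to 7 days) and diving defaults
(5 ± 1.5 / 1.2 ± 0.5 km h⁻¹, 2-min fixes, 12 h) are stated choices
matching the logger intervals and plausible movement scales of the two
guilds; no per-species speed distributions were available to calibrate
against, so these are generator conventions, not estimates.

Baseline fields are linear latitudinal gradients (defaults 0.21 ‰/° for
δ13C with intercept −11.25, 0.12 ‰/° + 18.29 for δ15N, the
combined-regression scales) with optional front steps, inshore
exponential enrichment and cell noise. Plasma is the time-weighted field
mean along the within-window *foraging* fixes — plasma integrates ingested
prey, and prey is taken while foraging — plus a trophic offset (defaults
+0.8 ‰ δ13C, +4 ‰ δ15N, mid-range of the conventional 0.5–1 ‰ and 3–5 ‰
per-trophic-level enrichments) and Gaussian noise (0.3 ‰ in the recovery
tests).

What the generator does *not* emulate: oceanographic circulation, fronts
that move or meander with real dynamics, diet switching, tissue turnover
dynamics beyond the sharp 7-day window, and spatially correlated
measurement error. Passing parameter-recovery tests therefore show that
the pipeline's stages compose correctly and recover planted gradients
under the stated noise model — not that real seabird isoscapes attain any
particular accuracy.

## Problem sizes and determinism

The recovery tests and the acceptance script use 3 species × 25
individuals (hourly fixes, ≤7-day trips), a 200-replicate bootstrap
drawing 9 per species, 600-point behavioural recovery, and ≤10-point
kriging-oracle configurations — sizes at which every quantity stabilizes
while the full suite runs in well under a minute. All randomness flows
from explicit integer seeds; identical configuration and seed reproduce
every numeric output exactly.

## Known limitations

- Geographic-degree isotropy (discussed above).
- The on-land rule is a radius, not a coastline; islands other than the
  colony are invisible to segmentation.
- The diving-bird speed threshold ignores dive-depth information entirely.
- Kriging variance is emitted but not propagated into front/zone summary
  uncertainty; the bootstrap envelope is the intended uncertainty
  diagnostic at guild level.
- Extents crossing the antimeridian are not supported.
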