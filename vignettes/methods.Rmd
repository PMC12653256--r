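---
title: "Methods: trajectory-based source attribution validated by insecticide susceptibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based source attribution validated by insecticide susceptibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoppertrace)
```

## Overview

`hoppertrace` attributes immigrant white-backed planthopper populations to
their emigration sources by two independent lines of evidence that must
agree: backward trajectories through wind fields (where *could* the insects
have come from, physically) and insecticide susceptibility profiles (which
candidate areas carry populations that are toxicologically
indistinguishable from the immigrants). This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic tests
do and do not demonstrate.

## Backward trajectory model

Planthoppers are treated as passive wind-borne particles at a single
representative flight level: aircraft catches concentrate the migrating
layer below 1000 m, so the fields are taken at a nominal 1000 m and no
vertical motion is modelled. The position ODE is

$$\frac{d\varphi}{dt} = \frac{v}{111320\ \mathrm{m/deg}}, \qquad
  \frac{d\lambda}{dt} = \frac{u}{111320 \cos\varphi},$$

a spherical-Earth small-angle metric adequate for a study domain spanning
under fifteen degrees of latitude. Integration uses the Petterssen
predictor–corrector (iterated implicit midpoint) scheme, the standard
trajectory integrator: a forward-Euler first guess followed by trapezoidal
correction iterated to 1e-10 degrees (at most 10 iterations). The default
step is 6 minutes; under uniform wind the scheme is exact to rounding, and
in smooth sheared fields forward re-integration from the computed takeoff
point returns to the landing point within 2 km (a property verified in the
test suite).

Behavioural rules bound each flight:

| Parameter | Default | Meaning |
|---|---|---|
| `takeoff_hour` | 19:00 Beijing Time | crepuscular mass takeoff at dusk |
| `altitude_m` | 1000 m | nominal flight level of the wind fields |
| `temp_floor_C` | 16.5 °C | minimum flight temperature |
| `max_duration_h` | 24 h | obligate one-way flight ceiling |
| `landing_hours` | 20:00–06:00 | simulated landing clock hours per capture night |
| `step_min` | 6 min | integration step |

A backward trajectory starts at a landing time and stops at the most recent
dusk takeoff hour. The temperature floor is enforced as a hard in-flight
constraint: a backward simulation cannot distinguish "the insect landed
here" from "the insect never flew here", so the first position colder than
16.5 °C invalidates the remainder of the path (`truncated_temp`) rather
than marking a landing. Trajectories leaving the meteorological domain are
likewise excluded (`exited_domain`) and counted in the run report.

Which landing hours were flown on a capture night is not observable from a
trap count. The default enumerates hourly landings from 20:00 of the
capture evening to 06:00 the next morning — nocturnal trap catch implies
nocturnal arrival — giving flight durations of 1–11 h back to the previous
dusk. `flight_config(full_window = TRUE)` extends enumeration to the full
physiological window (landings through 19:00 the following day, durations
up to 24 h) for sensitivity analyses. This choice trades completeness for
specificity and is deliberately exposed rather than hidden.

All timestamps are Beijing Time (UTC+8, no daylight saving); no timezone
arithmetic occurs inside the pipeline. Met fields carry a single vertical
level; multi-level archives must be pre-selected to the flight level before
loading. The long-format CSV grid (`time, lat, lon, u, v, T`) is the
primary input dialect because fixtures are hand-writable; CF-style NetCDF
is accepted when the `ncdf4` package is available. Sampling is trilinear
(bilinear in space, linear in time), which reproduces grid-node values
exactly and never exceeds the bounds of the surrounding knots.

## Valid-source filtering

Three criteria, evaluated in a fixed order so each rejection carries its
first failed reason: (1) latitude — endpoints strictly north of 25° N are
excluded because rice there is still at sowing/seedling stage in May and
cannot supply emigrants; the boundary latitude itself is retained, a
documented and configurable semantic; (2) rice area — the endpoint must
fall inside a rice-cultivation polygon of the user-supplied mask;
(3) macroptery — the containing polygon must be flagged as holding
macropterous (long-winged, migratory) adults. Point-in-polygon tests are
planar, which at 0.5° analysis resolution over this domain introduces
negligible error. The package ships no rice map: delineating cultivation is
a remote-sensing problem outside its scope, so masks are user inputs and
the tests use toy rectangles.

## Density mapping

Valid endpoints are counted on a 0.5° fishnet anchored at a configurable
origin with half-open cell membership (an endpoint exactly on an edge
belongs to the higher cell — a boundary convention fixed so counts always
sum to the number of endpoints). Counts are normalised to probabilities per
endpoint set, i.e. per destination group panel. Interpolation to a surface
uses Sibson natural-neighbor weights computed by area-stealing: the query
point is inserted into the Voronoi tessellation of the non-empty cell
centroids (via `deldir`) and each datum is weighted by the tile area the
insertion steals from it. Empty cells are not data points; queries outside
the convex hull return `NA` rather than extrapolating; a query within
1e-9° of a centroid returns that cell's value exactly. Whether the original
analysis interpolated cell centroids or raw points, and how it normalised,
is not recorded; interpolating centroid probabilities per group is this
package's documented choice. A barycentric-linear fallback
(`method = "linear"`) exists for robustness checks; both methods reproduce
a planar test surface to numerical precision.

## Probit bioassay statistics

Mortality is modelled as binomial with
$P(\text{death}) = \Phi(\alpha + \beta \log_{10} c)$. Replicates are pooled
per concentration (one fit per site × insecticide), control mortality up to
10% is removed by Abbott's correction before fitting (assays above 10%
control mortality are discarded), and the fit is weighted maximum
likelihood via IRLS with a convergence tolerance of 1e-10 within 100
iterations. Base-10 logarithms follow the classical probit-analysis
convention. LC₅₀ = 10^(−α/β). Goodness of fit is the Pearson χ² on
corrected counts with k − 2 degrees of freedom; when χ²/df exceeds 1 the
coefficient covariance is inflated by the heterogeneity factor h = χ²/df
before intervals are formed. The default interval is Fieller's exact-ratio
solution for −α/β on the log scale, back-transformed; the delta method is
available and agrees to three significant figures whenever the slope is
precisely estimated. When Fieller's g = z²·var(β)/β² ≥ 1 the interval is
unbounded: the fit object records `NA` bounds with a warning, and calling
`lc50_ci()` directly raises the condition. Complete separation (0% or 100%
corrected mortality at every dose) is a hard error — no finite LC₅₀ exists.

Monte-Carlo calibration under the reference design (5 log-spaced
concentrations spanning LC10–LC90 of the truth, 80 insects per
concentration) shows median LC₅₀ recovery within a fraction of a percent of
truth and Fieller coverage of 96.0% over 1000 replicates, consistent with
the nominal 95% given the half-of-replicates heterogeneity inflation.

## Grouping and attribution

Significance is CI overlap at α = 0.05: two populations differ when their
95% intervals are disjoint (touching intervals overlap). The compact letter
display is built by insertion–absorption over the pairwise overlap matrix,
with populations processed in ascending LC₅₀ order so lettering is
deterministic and letter "a" anchors the most susceptible class. The letter
display is always recomputed from the intervals; where a published
annotation is supplied (`letter_printed`), `cld_discrepancies()` reports
every pair whose printed verdict contradicts strict overlap. On the
packaged tables this surfaces eight such pairs — notably Xingbin's
nitenpyram interval, whose upper bound overlaps Youxian's and Babu's lower
bounds despite distinct letters — which are reported as data discrepancies
and left untouched. (The packaged tables' notes say "same row" where the
comparison runs down the column; this is treated as a typo.)

Destination groups are the joint letter signatures across both
insecticides; group-level pooled intervals are the envelope (min lower, max
upper) of member intervals. The matching rule is conjunctive by default
(`both_all`): a source matches a group only if, for both insecticides, its
CI overlaps every member site's CI. Although the filtering criterion is
sometimes phrased disjunctively ("pymetrozine or nitenpyram"), only the
conjunctive rule jointly reproduces the published match lists on the
packaged tables, so it is the default; `either_all` (disjunctive) and
`both_pooled` (envelope-based) are selectable alternatives, and every
pairwise verdict is retained in the decision matrix for audit.

## Synthetic data: what it emulates and what it does not

The generators cover all four input kinds so the whole pipeline is testable
offline: parametric wind scenarios (uniform; solid-body rotation, whose
center is a fixed point; a Gaussian southwesterly jet advecting parcels
northeast), binomial probit bioassays with known truth under the reference
design, Poisson trap series with immigration pulses (magnitude ≥ 30 clears
the 10-per-night event threshold with high probability), and rectangular
rice masks. Every generator takes one explicit seed and restores the
caller's RNG state.

The planted-source scenario wires these together with a known answer: a
uniform southwesterly flow (u = v = 8 m/s, 20 °C) carries migrants from a
rice rectangle south of 25° N to two trap sites near 26.5° N; destination
bioassays share their generating truth (LC₅₀ 30 and 1 mg/L, slope 3.4) with
a true source, while a decoy is generated at three times the LC₅₀. The
pipeline must attribute the destination group to the true source and reject
the decoy, and does so for ten consecutive seeds in the acceptance suite.

These synthetics are deliberately idealised: winds are smooth and
stationary over a night, temperature carries no diurnal cycle, trap counts
are pure Poisson, and bioassay truth is exactly probit with no between-
replicate heterogeneity. Passing tests therefore demonstrate correctness of
the machinery — integration, filtering, counting, fitting, matching — not
that real reanalysis winds or field assays satisfy these assumptions.
Cumulative field quantities (seasonal totals, event-day counts, endpoint
clusters over real winds) depend on unpublished raw data and are outside
what desk-scale simulation can reproduce.

## Problem sizes and determinism

The test suite runs 1500 probit refits for the recovery and coverage
checks, ten end-to-end pipeline runs for the planted-source check, and
week-long synthetic met fields at 1° × 3 h resolution — sizes chosen so the
whole suite completes in about a minute while keeping Monte-Carlo standard
errors (≈0.7% on coverage at 1000 replicates) well inside the asserted
bands. Identical configs and seeds produce byte-identical outputs, which
the pipeline tests assert file-by-file.

## Known limitations

- No vertical motion, turbulent dispersion or mixed-layer logic; one flight
  level only.
- Landing-hour enumeration per night is an assumption (two documented
  presets), not an observation.
- Planar geometry for point-in-polygon and fishnet assignment; no
  antimeridian wraparound.
- The Fieller/heterogeneity recipe approximates, but cannot exactly
  reproduce, intervals from proprietary bioassay software; published
  intervals therefore enter the attribution as data, and any letter
  disagreements are surfaced as discrepancies.
- CI-overlap grouping makes no multiplicity correction, matching the
  published analysis convention.
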