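---
title: "Canopy profiling from hinge-angle lidar: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy profiling from hinge-angle lidar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingescan)
```

## The measurement model

A fixed instrument sweeps a rangefinding laser through all azimuths at a
constant view zenith angle of 57.5° (an *almucantar* scan) and records one
slant range per shot; a range of 0.000 m encodes a gap — the beam left the
canopy, or no valid return came back. Under the assumptions of flat ground
and horizontally random foliage placement, three steps convert a scan into
a vertical structure profile:

1. **Geometry.** A return at slant range $d$ originates at height
   $h = d\cos 57.5^\circ$ above the instrument datum ($z = 0$ at the scan
   head). The 60 m night-time detection limit for live foliage therefore
   caps useful profiling at about 32 m.
2. **Gap probability.** For each height $z$ on a grid,
   $P_{gap}(z) = 1 - \#\{z_i < z\}/N$ over the $N$ shots, counting only
   valid returns $z_i$. $P_{gap}$ starts at 1 and is non-increasing.
3. **Inversion.** Beer–Lambert attenuation gives the cumulative plant area
   index $PAI(z) = -1.1\,\ln P_{gap}(z)$ and the plant area volume density
   $PAVD(z) = \mathrm{d}PAI/\mathrm{d}z$. Because lidar returns do not
   separate leaves from stems and branches, outputs are labelled PAI/PAVD
   rather than LAI.

### Why 1.1, and what it costs

The extinction coefficient of the Campbell ellipsoidal leaf angle
distribution,
$K(\theta, x) = \sqrt{x^2+\tan^2\theta}\,/\,(x + 1.702(x+1.12)^{-0.708})$,
depends strongly on the leaf-orientation parameter $x$ at most view angles
— but near $\theta = 57.5^\circ$ the curves for all $x$ cross:

```{r hinge}
x <- c(0.2, 0.5, 1, 2, 5)
round(1 / extinction_coefficient(57.5, x), 3)
```

The inverse coefficient $1/K(57.5^\circ, x)$ spans barely 0.08 across
erectophile to planophile canopies, against a spread of well over 1 at
$\theta = 30^\circ$. Its spherical-canopy value 1.074 rounds to the
conventional 1.1 used in the inversion. The cost of the convention is a
multiplicative factor $1.1\,K(57.5^\circ, x) \approx 1.02$–$1.07$ between
estimated PAI and true plant area: estimates are biased a few percent high
in absolute terms, and the bias cancels entirely in relative quantities
(seasonal amplitude, trend shape), which is what long-term monitoring
consumes. Validation tests therefore assert the estimate against
$1.1\,K\,L$ at Monte-Carlo precision and against the true $L$ at a looser
10% relative band.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `zenith` | 57.5 | deg | hinge angle; the LAD-insensitivity above |
| `instrument_height` | 1.5 | m | typical pole mount; only used for ground-datum reporting |
| `max_detect_range` | 60 | m | night-time live-foliage detection limit of the red-wavelength rangefinder |
| `n_shots` | 920 | — | typical configuration, 2.6 shots per degree; instrument maximum 7360 |
| height grid | 0–35 m by 0.5 m | m | covers the ~32 m ceiling; bin width balances PAVD noise against vertical detail |
| inversion `coefficient` | 1.1 | — | hinge convention; override with `hinge_inverse_coefficient(lad)` if the LAD is known |
| rain rule | 50 shots < 0.300 m | — | firmware power-saving cut-off; droplet returns cluster near 0.27 m |
| QC threshold | per instrument | m | chosen from the summed-range histogram; strictly-less-than exclusion |

Heights are reported above the instrument datum by default; pass
`datum = "ground"` to `height_from_range()` to add the mount height. All
angles are accepted in degrees at every interface and converted internally.

## What the simulator emulates — and what it does not

`simulate_scan()` draws each shot's first-interception height by exact
inverse-transform sampling from the survival function
$S(z) = \exp(-K\,L(z))$ of a piecewise-constant PAVD canopy
(`canopy_model()`), so there is no vertical discretization bias in the
synthetic truth. It then applies, in order: the detection-limit censoring
(interceptions beyond 60 m slant range return nothing and become gaps),
per-shot wind perturbation (a true hit lost with probability
`wind_gap_prob`; a true gap replaced by near-range clutter with probability
`wind_hit_prob`), range quantization (mm below 10 m, cm at or above), and
optionally a rain event: from a uniformly drawn onset shot, ranges become
droplet returns drawn uniformly on 0.260–0.290 m — a distribution invented
around the observed ~270 mm prism-face distance, configurable — and the
scan truncates exactly 50 shots later, as the firmware would.

Azimuths are a deterministic uniform grid (stepper-motor stepping), encoded
at the 0.1° precision of the rotary encoder; optional jitter is off by
default. Every public simulation entry point requires a seed and uses a
local RNG, so identical seeds give byte-identical scan files.

Deliberate simplifications: wind is i.i.d. per shot (real gusts correlate
across consecutive azimuths, which would make wind damage *harder* to
detect from the summed-range statistic than in simulation); there is no
radiometry (return intensity, reflectance, beam divergence, partial hits),
no daylight noise, and no topography. Passing the validation suite
therefore shows the *inversion and filtering chain* is correct under the
stated attenuation model — it does not certify performance on real scans,
where leaf angle distributions, clumping, and correlated weather violate
the model to an unknown degree.

## Numerical and design choices

- **Counting rule.** The gap-probability counting rule is implemented as
  $1 - \#\{\text{valid } z_i < z\}/N$. A literal reading that counts every
  record below $z$ would treat the 0.000 gap code as a ground-level return
  and destroy monotonicity of the cumulative profile; it is kept behind
  `gap_profile(..., literal = TRUE)` purely for comparison. The below-height
  comparison is strictly `<`.
- **Saturation.** If every shot is intercepted below some height,
  $P_{gap}=0$ and the log diverges. We clip to $1/(2N)$ — half the smallest
  observable non-zero proportion — and flag the profile `saturated` rather
  than returning infinity silently.
- **Conservation.** PAVD is a forward finite difference on the uniform
  grid, so `bin_width * sum(pavd)` telescopes to the top-of-canopy PAI
  exactly (asserted to 1e-9); optional moving-average smoothing is off by
  default because it redistributes area across bins.
- **Quantization.** Half-up rounding (with a 1e-9 nudge so decimal literals
  stored just below the binary half round up), idempotent by construction.
- **Footprint.** The popular radius = 2H rule of thumb for the sampled plot
  is geometrically inconsistent with the scan angle
  ($\tan 57.5^\circ \approx 1.57$, not 2). `footprint_area()` implements
  both rules — `radius_2h` as the default for comparability with published
  plot-size statements (0.985 ha ≈ 1 ha at H = 28 m), `tangent` as the
  geometrically exact one (0.61 ha) — so the discrepancy stays visible.
- **Rain runs.** "Consecutive short returns" are non-gap records in
  (0, 0.300) m; gaps break a run, since droplets produce ~0.27 m *hits*,
  not gaps. `count_gaps = TRUE` flips the convention. Both the firmware
  truncation flag and a post-hoc run-length scan on complete scans are
  honoured.
- **Threshold boundary.** Exclusion uses strictly-less-than, so a scan
  summing exactly to the threshold is retained.
- **Monthly aggregation** averages per-scan profiles (each night equal
  weight), matching how daily data are usually aggregated for display;
  pooling all shots of a month into one gap profile before inversion is
  available via `method = "pool"` (it weights nights by their valid-return
  counts and is not the default). Summary statistics are computed over
  monthly aggregates.
- **Trend.** Cubic spline (`splinefun`, method `"fmm"`, exact for cubic
  polynomials) through month-midpoint abscissae, sampled daily; runs of
  missing months longer than `max_gap_months` split the fit into pieces
  rather than inventing a bridge. Fewer than 4 months is refused.
- **Degenerate inputs.** Empty scans, non-positive ranges, azimuths outside
  [0, 360), non-uniform grids and empty PAI series all raise immediate
  errors naming the constraint.

## Validation problem sizes

The test suite validates parameter recovery at $N = 10{,}000$ shots per
scan across true plant areas 0.5–2.5; gap-count equivalence against a
brute-force per-shot recount on 200 random scans of up to 50 shots; and an
end-to-end campaign of 18 months × 3 instruments × nightly 920-shot scans
(≈1,650 scans) with a seasonal sinusoid of amplitude 10% of the mean,
nightly rain probability 0.2 and heavy-wind probability 0.25 — roughly the
exclusion rates seen in long unattended deployments. The campaign's QC
threshold is placed at 0.65 of the deterministic expected clean-scan
summed range (`expected_sum_valid_ranges()`), which cleanly separates
clean scans from windy ones losing 60% of interceptions. Recovery is
judged on Pearson correlation with the injected monthly truth and on the
relative PAI range.

## Known limitations

- No woody/leaf separation, clumping correction, or multi-zenith
  inversion: PAI is plant area, and spatial clumping biases it low
  relative to destructive truth.
- Flat-ground assumption; no slope or per-shot terrain correction.
- Shots that intercept vegetation but return no range (distant or moving
  targets) are indistinguishable from gaps and bias $P_{gap}$ high; the
  simulator folds this into `wind_gap_prob`.
- Threshold-based filtering can mistake genuine structural collapse
  (fire, pest outbreak, tree fall) for weather and exclude it; dynamic
  threshold re-estimation is out of scope here.
- The scan file format is a package-defined plain-text stand-in (the
  instruments' on-card byte format is unpublished); it preserves the
  documented precision conventions and the ~tens-of-kB size, nothing more.
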