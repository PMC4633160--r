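---
title: "colonyscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{colonyscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `colonyscreen`, the parameters
that matter, and the design decisions taken where the underlying platform
leaves the analysis under-specified.

## The screening problem

A flow sorter with electrostatic deflection can deposit one bacterial
cell per stop onto solid medium, building a dense lattice ("matrix") of
clonal colonies — hundreds per cm² — on dark charcoal agar. After
induction and substrate spraying, the plate is imaged through a set of
optical bandpass filters. Each colony then has a vector of band
intensities: a coarse emission spectrum. A library screen looks for the
rare colony whose spectrum differs from the majority — for instance a
red-shifted firefly luciferase point mutant (emission maximum ~615 nm)
inside a wild-type population (~550 nm) — and must report its lattice
address so it can be picked.

`colonyscreen` implements that whole chain in software: lattice geometry,
a calibrated synthetic-plate generator (there is no public deposited
image data for this kind of platform, so simulation with ground truth is
the only way to validate the analysis end to end), colony detection and
photometry, spectral calling with a pick map, two-colour coincidence
statistics, and a throughput model of the deposition schedule.

## Lattice geometry

`make_layout(n, a)` enumerates all factor pairs `r * c = n` and picks the
pair whose ratio `c / r` is closest to the target aspect `a` (ties toward
more columns). The canonical formats all factor exactly at `a = 1.5`:
384 = 16 x 24, 3,750 = 50 x 75, 25,350 = 130 x 195. The choice of exact
factorisation (rather than rounding up to a rectangle with unused
positions) matches how these plates are actually printed. One published
format breaks the rule — the 4,050-point multiplexer plate is 50 x 81,
ratio 1.62 — so layouts can always be constructed explicitly with
`plate_layout(rows, cols)`; `make_layout` is a convenience, not a
constraint. If no factor pair comes within 4x of the requested ratio
(large primes), the function refuses and names the nearest achievable
shapes; the cutoff is arbitrary but only affects degenerate requests.

Coordinates are 0-based `(row, col)`, row-major, origin top-left with y
increasing downward — the raster convention of the images the lattice is
mapped onto. The physical span is fencepost: `(n_cols - 1) * pitch` by
`(n_rows - 1) * pitch`. Density is reported rounded to the integer
(`~394 colonies/cm²` style) with full precision retained internally.

## The synthetic plate generator

`sample_ground_truth()` draws, independently per position:

* occupancy — empty with probability `1 - viability` (default **0.94**,
  the platform's measured deposition viability); an occupied position is
  a coincident doublet with probability `doublet_rate` (default
  **0.004**, the upper end of the platform's estimated total doublet
  rate);
* variant identity per deposited cell, from `variant_mix` (e.g. a 0.5%
  spike-in);
* per-cell brightness, log-normal with arithmetic mean **0.14** and SD
  **0.03** — the calibration measured on a 10,788-colony clonal plate.
  Intensity units are arbitrary (the upstream imager's own scale is
  instrument-specific); only relative statistics are meaningful;
* a small deposition-placement jitter (Gaussian, SD **25 µm** per axis,
  our own choice of a realistic stage accuracy, ~5% of the pitch).

Colony radius follows `r = r_ref * (d_ref / d)^alpha` (defaults
`r_ref = 6 px` at `d_ref = 44 colonies/cm²`, `alpha = 1/3`): a monotone
shrink with density, reproducing the observed trend that colony area and
per-colony protein yield fall as the matrix gets denser. The exact
published curves are not tabulated anywhere, so only the monotone trend
is modelled and tested; `alpha` is configurable and `alpha = 0` gives
constant radius.

Emission spectra are Gaussians in wavelength, unit area over 400–800 nm,
with only peak positions published (550 nm wild-type, 615 nm red
variant); the FWHM default of **70 nm** reflects the broad unimodal
shape of firefly luciferase emission. The classification contract only
depends on band integrals, so the exact line shape is not critical.
Doublets are rendered as a single disc whose band signal is the
brightness-weighted sum of both members' spectra — coincident
depositions are optically unresolvable, and the pipeline treats them
that way throughout.

Rendering paints each colony as a uniform disc (total signal =
brightness x band fraction, conserved exactly before blur and noise — a
property the tests exploit as an oracle), then applies Gaussian PSF blur
(EBImage), a flat background (default **0.01**; charcoal agar is nearly
black), Poisson shot noise at **10⁶** photons per intensity unit and
Gaussian read noise (SD **10⁻⁴**). These defaults put the peak-band
signal-to-noise ratio above 10 for an average colony, which is the
regime the screen is designed to operate in. All randomness flows from
one seeded generator in a documented draw order, so a plate is
byte-reproducible from its seed.

What the simulator does **not** emulate: substrate kinetics (light
output is steady-state; the real protocol waits ~120 s for
stabilisation), camera-specific artefacts (vignetting, fixed-pattern
noise, intensifier blooming), colony morphology beyond a disc, and
spatial growth interactions between neighbours beyond the global
density–radius law. Passing tests therefore demonstrate the analysis
logic, not robustness to every real-world imaging artefact.

## Colony quantification

Segmentation thresholds the max-projection across bands with **Otsu
computed on square-root intensities** (variance-stabilising under shot
noise, and far less sensitive to the wide brightness spread across
colonies than a linear-domain Otsu, which can swallow dim colonies), and
labels connected components (EBImage `bwlabel`). The threshold is
relative to the image's own range, so segmentation is invariant to
global linear rescaling. Components below `min_area_px` (default 4) are
noise; components larger than 1.7x the median area are flagged as
probable merged neighbours and excluded from spectral calling — the same
treatment as coincident depositions.

Photometry is the pixel sum inside a component minus area x background,
with the background the median of non-foreground pixels in the
component's bounding box expanded by 3 px (a local annulus, robust to
illumination gradients), or optionally a global median. Uniform offsets
cancel exactly.

Grid assignment fits a similarity transform (translation + scale +
small rotation, as one complex regression coefficient) from lattice
coordinates to centroids by iterated nearest-node least squares, then
snaps each colony to its nearest node within pitch/2. Conflicts keep the
nearer colony and flag the other; a median residual above pitch/4 is a
hard error ("grid fit failed") rather than a silent misassignment.
Greedy nearest-distance with conflict flags is sufficient at these
densities; a full optimal assignment would change nothing on plates
where colonies sit within a quarter pitch of their nodes.

## Spectral calling

Each colony's band vector is scaled to unit **maximum** (not unit sum):
the peak position becomes the dominant feature, which is what separates
a 550 nm from a 615 nm emitter through 50 nm windows. References are
computed from the emission model, not learned — no training data exists,
and model references keep the caller deterministic. The call is the
nearest reference in Euclidean distance; it is *confident* when the
distance is ≤ `max_distance` (default 0.6, about half the distance
between the two default references) **and** the runner-up is at least
20% farther. The margin rule is what rejects intermediate spectra such
as mixed-variant doublets, which sit near the midpoint of the two
references and must not be picked. The platform itself never published a
numeric shift-detection rule; this distance + margin formalisation is
this package's own, surfaced in the configuration. Only two of the six
filter windows are published (550–600 and 590–640 nm); the default set
completes them with 50 nm windows covering the stated 510–750 nm range
(510–560, 590–640, 630–680, 670–720, 700–750), fully configurable.

Hits — confident non-majority calls — are reported with block, row and
column on a text plate map plus a machine CSV, which is the artefact a
colony picker works from.

## Coincidence and singlet purity

In a 1:1 two-colour print, only opposite-colour doublets are detectable.
With mixing fraction `f`, a random pair is two-coloured with probability
`2 f (1 - f)`, so the estimated total doublet rate is the observed
double-positive rate divided by that factor — at 1:1, exactly twice the
observed rate (0.2% observed implies 0.4% total). The estimator is
≥ the observed rate for every `f`, and unbiased on simulated plates
(checked over 50 seeded replicates). Channel thresholds default to Otsu
per channel; colonies below both thresholds leave the denominator and
are reported separately. The 95% CI is exact binomial on the
double-positive count. No spectral bleed-through between channels is
modelled: the platform publishes no bleed characterisation, and the
green/red reporters are well separated at these filter widths.

## Deposition scheduling

The rate limit of matrix printing is the electromechanical dead time
while the plate handler moves between stops. Plate time is modelled as
`total_stops * t_stop + n_particles * t_drop`, with `t_drop = 0` by
default (in-burst deposition runs at the sort rate, negligible against
the dead time). A 9-stream multiplexer reduces the stops per row of an
81-column plate from 81 to `ceil(81 / 9) = 9`. The published bench
timings give `t_stop = 1563 s / 4050 stops ≈ 0.386 s`, predicting
`450 * 0.386 ≈ 173.7 s` for the multiplexed plate — within 3% of the
measured 169 s; the residual may include per-burst settling not
separable from the published numbers, so both values are surfaced rather
than reconciled. The published "50 y-axis and 81 x-axis translations" is
read as 81 stops per row repeated over 50 serpentine rows (not 131 total
moves): only that reading is consistent with the measured ~0.39 s/stop.
The attenuation ladder assumes deflection linear in charge:
`factor_i = (D - i * p) / D` for stream pitch `p` and full deflection
`D`, strictly decreasing; real electrostatics (charge decay, droplet
fanning) are out of scope.

## Numerical choices and degenerate inputs

* Band integrals: trapezoid at ≤ 0.5 nm steps; agreement with the
  closed-form Gaussian integral is ~10⁻⁵ absolute, far below any
  decision threshold. Bands outside the support return ~0, not an error.
* `normalize_spectrum` clamps small negative (background-subtracted)
  intensities to 0 and errors on all-zero vectors ("no signal").
* Ties in `make_layout` go to more columns; `classify_spectrum` breaks
  exact distance ties by reference order.
* Single-row/column layouts have zero fencepost span; the generator's
  density law then falls back to one pitch per degenerate dimension.
* 16-bit image IO quantises at 1/65535, well below all noise scales;
  saturated (clipped) pixels are counted and reported.

## Problem sizes in the test suite

The suite validates the spike-recovery contract on ten replicate
50 x 75 plates (0.5% spike, default optics) and the singlet-purity
calibration on twenty ~12,700-colony two-colour plates at a 0.4% total
doublet rate — sizes chosen to match the platform's published
experiments while keeping a full run in the low minutes on one core.
Larger formats (25,350 points) are exercised for geometry only.

## Known limitations

* The simulator's realism bounds what the tests can show (see above);
  real plates may need different segmentation parameters, which are all
  exposed in the run configuration.
* The density–radius exponent is a modelling choice fit to a trend, not
  to data.
* Manual-picking error rates at high density involve a human operator
  and are outside what software can reproduce.
* Kinetic (time-course) light-output analysis is not implemented; the
  per-colony photometry is steady-state.
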