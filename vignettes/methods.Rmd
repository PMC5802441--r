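---
title: "Methods: grid-based biodiversity assessment and gap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based biodiversity assessment and gap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`gapscape`, the assumptions behind them, the defaults and why they were
chosen, and the places where the design was genuinely open.

## The analysis grid and spatial join

Occurrence records are reduced to presences on a graticule grid —
an angular lattice (default 10 arc-minutes, ≈ 18 km in the subtropics)
rather than a projected one, the convention of regional biodiversity
atlases. Two conventions make the join fully deterministic:

- **Anchoring.** Cells snap to multiples of the cell size from the
  (0°, 0°) graticule origin; the bounding box of the study polygon is
  expanded outward to those multiples. The same study area therefore
  always produces the same cells, independent of record order or of any
  floating-point bbox.
- **Edge ownership.** Cells (and raster pixels) are half-open:
  `[west, east) × [south, north)`. A record exactly on a shared edge
  belongs to the east/north neighbour; every point belongs to exactly
  one cell.

The study mask is the set of cells whose rectangle intersects the study
polygon (corner containment, vertex containment, or edge crossing — an
exact test, not a sampling approximation). Presence-only data carry no
absences: cells without records are "unsampled", and the pipeline never
distinguishes unvisited cells from visited-without-success cells,
because the data model cannot.

## Pixel areas

All areas in km² are sums of per-pixel areas from the spherical
cosine-latitude approximation, `(dlat·111.32) × (dlon·111.32·cos φ)`
evaluated at the pixel-centre latitude φ. Against an ellipsoidal
computation the error is below 0.6% in the subtropical band this
package targets; in exchange the quantity is exactly reproducible with
no geodesy dependency. Areas strictly decrease with |φ|, which the test
suite asserts.

## Standardized PCA of climate space

Twelve bioclim variables (BIO1, 4, 5, 6, 7, 10, 11, 12, 13, 16, 18, 19)
are z-standardized over the study pixels and decomposed with
`stats::prcomp`. Standardization is obligatory: the variables mix °C,
dimensionless seasonality indices and mm, and an unscaled PCA would be
dominated by precipitation magnitudes. The seven remaining bioclim
variables are excluded by fixed configuration; in sparsely gauged arid
regions their interpolated surfaces show station artefacts, and a
data-driven exclusion would make runs incomparable across datasets.
Two components are retained by default (not chosen by criterion — the
downstream partition is defined on a fixed number of axes). Components
are signed so each column's largest-magnitude loading is positive,
making scores reproducible across LAPACK implementations. Eigenvalues
after standardization sum to the variable count, a conservation law the
tests assert.

## Equal-variance climatic clusters

The partition divides *climate space*, not geographic space, so a
cluster represents a fixed share of climatic variance regardless of its
geographic footprint or connectivity. Each pixel's contribution is

> c_i = s_i² / Σ s²,

its squared score over the total squared scores across the retained
components, so contributions sum to exactly one. For each component the
pixels are sorted by score and walked outward from the origin
(default 0, the standardized mean climate) separately on the positive
and negative side, accumulating contributions bin by bin; when a bin
reaches θ (default 0.10) it is closed and the accumulator restarts. The
law this yields — every closed bin holds θ plus at most one pixel's
contribution — is asserted in the tests. Choices pinned here, with the
reasoning:

- **Population normalization.** Contributions use the raw sum of
  squares, not the (n−1)-denominator eigenvalues `prcomp` reports;
  otherwise contributions would not sum to 1 and the symmetric
  four-pixel toy case (scores −1, −1, +1, +1, θ = 0.5) would not close
  its two bins exactly at the origin.
- **Per-bin reset** rather than global multiples of θ: with a global
  running sum, overshoot from one bin would be deducted from the next,
  allowing bins slightly *under* θ; resetting keeps every closed bin at
  or above θ.
- **Breakpoint placement** midway between the pixel that closed the bin
  and the next pixel outward — any value in that open interval yields
  the same partition of the data; the midpoint is symmetric and
  deterministic.
- **Half-open lower-inclusive bins** `[b_j, b_{j+1})`, with the outer
  bins extending to infinity, so out-of-range projections clamp into
  the end bins rather than failing.
- **Numbering** is the full n₁ × n₂ bin grid (not only non-empty
  combinations), left-to-right along PC1 then bottom-to-top along PC2,
  so cluster 1 is the cool/wet-to-dry corner consistently across runs.
  Empty combinations simply never occur in the label table.

Because the second component carries less variance than the first, its
side shares are smaller and it always receives at most as many bins —
the partition inherits the component ordering. The walker sits behind
its own function (`equal_variance_breakpoints()`) so an alternative
scheme (e.g. ignoring the origin) can be swapped without touching
labelling or coverage code.

Sampling coverage per cluster counts *distinct occupied pixels*
("localities") rather than raw records; duplicate records in one pixel
are one locality. This interpretation reproduces the worked three-pixel
example (2 localities of 3 pixels = 66.67%) exactly.

## Ecological profiles

- **Elevation histograms** use fixed `[k·100, (k+1)·100)` m bins; a
  record at exactly 100 m falls in the upper bin (same half-open rule
  as everywhere else). Negative elevations, rare but possible in
  depressions, fold into a single `[min, 0)` bin.
- **Climate envelopes** are the per-record (BIO1, BIO12) pairs plus the
  background pixel cloud; summaries are five-number summaries per axis.
  All records are used, not deduplicated localities — an open choice;
  duplicates at one locality legitimately weight that climate.
- **Land-cover distances** are exact Euclidean distances from each
  record's pixel centre to the nearest pixel centre of each class,
  computed with a separable parabolic-envelope distance transform per
  class (linear in pixel count) and converted to km in an equidistant
  cylindrical metric (111.32 km/degree on both axes). That projection
  distorts east–west distances away from the standard parallel; it is
  kept because metric simplicity and determinism matter more here than
  geodesic accuracy, and the same convention is applied to every class
  symmetrically. A record sitting on a class has distance zero to it;
  classes absent from the raster are reported with `n = 0` rather than
  an infinite distance.

## Gap analysis

Two range estimators per species:

- **AOO** — the set of occupied analysis pixels (duplicates collapse),
  with areas summed per pixel. The 2 × 2-block variant (IUCN's 4 km²
  convention relative to a 1 km² grid) counts a whole block when any of
  its pixels is occupied, so the block area always dominates the native
  area. The native resolution is the default for the overlay because
  very small reserves (the register's minimum is 0.04 km²) would be
  overestimated by coarse blocks.
- **EOO** — pixels whose centres lie in the minimum convex polygon of
  the records **and** whose elevation lies within the species' observed
  elevational range, **union** the species' own occupied pixels. The
  union term is deliberate: a record near a hull vertex can occupy a
  pixel whose centre falls marginally outside the hull, and occupied
  pixels are part of the range by definition; it also guarantees the
  AOO ⊆ EOO nesting that the test suite asserts. "Filtered by the
  species' average altitude" admits more than one reading; the default
  observed min–max band is the conservative one (it can only exclude
  pixels the species was never recorded at), and a mean ± k·sd band is
  available as `filter_mode = "mean-band"`. The mode used is recorded
  in every estimate. Species with fewer than three distinct
  non-collinear records have no hull; their EOO falls back to the
  occupied-pixel set, flagged `fallback_used`.

A pixel is protected iff its **centre** lies inside any protected-area
polygon — partial-overlap rules would need polygon clipping and an
arbitrary area threshold, while the centre rule is deterministic and
keeps small-reserve bias bounded at the native resolution. Percentages
are rounded half-up to 2 decimals (the convention of published
tables; base R's round() is half-even). Species are scored against the
17% and 12% targets per estimator, plus an either-estimator union count
and a zero-protection count, overall and for endemics.

## The synthetic study system

`generate_world()` emulates the *structure* of an arid-country dataset,
not any real geography: a two-massif elevation template (a
north-eastern arc and a southern coastal massif) plus seeded secondary
relief; BIO1 from a latitudinal gradient and a −6.5 °C/km lapse rate on
elevation; BIO12 from a coastal moisture gradient plus an orographic
term; the other ten bioclim surfaces as smooth transforms constructed
to satisfy the order constraints (BIO5 ≥ BIO1 ≥ BIO6,
BIO12 ≥ BIO16 ≥ 0, BIO12 ≥ BIO13 ≥ 0) at every pixel and every seed;
land cover by thresholding precipitation and elevation with smooth
categorical noise; an irregular seeded boundary polygon; and a
protected-area network of axis-aligned rectangles with log-uniform
areas spanning about five orders of magnitude (mirroring real
registers), placed without overlap inside the boundary and summing to a
requested coverage fraction (default 4%, matching the register shipped
with the package). Randomness follows one root seed with per-component
derived substreams, so worlds are bit-identical under a seed.

`generate_species()` defines each species' suitability in
(BIO1, BIO12) **climate space** — not geographic space — precisely so
that climate-envelope profiling has a recoverable truth. Niche centres
anchor at the climate of a randomly chosen pixel (montane specialists
anchor on high-elevation pixels, desert specialists on hot dry lowland
pixels, generalists get widths several times the background spread),
and occurrences are drawn pixel-wise ∝ suitability × a spatially
uneven effort surface (`effort_bias = 0` means uniform). Coordinates
jitter inside the pixel, so the occupied pixel set is known exactly;
the generator computes its own per-species AOO, protected percentage
and per-cell richness with independent arithmetic, which the pipeline
must reproduce. Attribute prevalences default to 20/101 endemic and
9/101 venomous — the proportions of a typical arid-belt reptile fauna.

What the simulator does **not** emulate: climate physics (no seasonality
coherence beyond the order constraints), spatial autocorrelation of
sampling effort with roads or settlements, taxonomic error, coordinate
uncertainty, or temporal structure. Tests passing on synthetic worlds
therefore validate the *bookkeeping* of the pipeline — joins, areas,
partitions, overlays — not the ecological realism of any inference on
real data.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run worlds of 60 × 80 to
75 × 100 pixels with 12–30 species, sizes chosen so the full suite
completes in well under a minute on one CPU while every code path
(empty clusters, MCP fallbacks, unprotected species, absent land-cover
classes) is still exercised. Score/centering identities are asserted at
1e−8 relative, projection idempotence at 1e−10, and oracle equivalences
(join, hull, breakpoints, distance transform) exactly or at 1e−9 km.
The accumulation law uses an epsilon of 1e−12 on contributions to make
ties at exact multiples of θ deterministic.

## Known limitations

- Polygon features must be simple (no self-intersection); holes are
  supported by even-odd parity but the synthetic generator never
  produces them.
- The equidistant cylindrical distance metric overestimates east–west
  distances at high latitudes; within ±30° the distortion is below 15%
  and identical across classes, so class *rankings* are robust.
- EOO is a convex outer bound; strongly disjunct ranges (e.g.
  north/south massif species) inherit the hull's bridging area, only
  partly removed by the elevation filter.
- Protection by pixel-centre containment ignores sub-pixel reserves
  entirely at coarse test resolutions; at the intended 30-arc-second
  analysis resolution the bias is bounded by one pixel per reserve
  boundary.
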