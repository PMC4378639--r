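---
title: "Quantifying lamina curvature and proliferation patterning with laminametrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lamina curvature and proliferation patterning with laminametrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminametrics)
```

## The measurement problem

A healthy *Arabidopsis* leaf blade is flat. Mutations that unbalance
cell proliferation between the medial region (near the midrib) and the
margin bend the lamina out of the plane: excess medial growth cups the
blade (positive Gaussian curvature), excess marginal growth ruffles it
(negative Gaussian curvature). Measuring pointwise Gaussian curvature on
a growing, deformable organ is impractical, so the field uses a global
scale-free statistic instead: the perimeter divided by the square root
of the surface area,

$$ \mathrm{proxy} = P / \sqrt{A}. $$

For planar shapes this is bounded below by the flat-disc value
$2\sqrt{\pi} \approx 3.545$ (the isoperimetric inequality, equality only
for the circle). Measured *intrinsically* — boundary length and surface
area on the curved lamina itself — a value *below* the planar
prediction for the same outline indicates net positive (cup-like)
curvature, because a cup encloses more area per unit rim; a value above
it indicates margin excess. `laminametrics` implements this statistic,
its elliptical-leaf null model, and the cell-level measurements that
explain *why* curvature changes: the medio-lateral shape of the mitotic
arrest front, proliferation-zone dynamics, growth kinetics, cell sizes
and counts, and reporter-image quantification. A synthetic-data module
generates every input with known ground truth so each stage is testable
end to end.

## Planar morphometry and the ellipse null model

`measure_outline()` reduces a flattened outline polygon to length
(maximal extent along the blade axis), width (maximal orthogonal
extent), perimeter, shoelace area, the leaf index (length:width), and
the proxy. The blade axis defaults to the principal axis of the
polygon's area distribution — operator-independent, and exact for the
generated shapes — but must be supplied for leaves wider than long,
where geometry alone cannot tell the proximo-distal direction (the
physical protocol orients by the petiole).

The null model asks what the proxy of a *flat* leaf with the same
length $\ell$ and width $w$ would be, treating it as an ellipse with
semi-axes $a = \ell/2$, $b = w/2$:

$$ P = 2\pi\sqrt{(a^2+b^2)/2}, \qquad A = \pi a b, $$

the quadratic-mean perimeter approximation conventional in this
literature (it overestimates the true perimeter by <1% at leaf-like
eccentricities; `ellipse_perimeter_ramanujan()` quantifies the error).
The prediction depends only on the leaf index: indices 1.4 and 0.9 both
predict ≈3.6, which is why a change in planar shape alone cannot
explain group proxies of 3.8 versus 3.2 — the difference must come from
surface curvature.

```{r}
predicted_proxy_from_length_width(1.4, 1)
curvature_proxy(36.3, 90.3)   # wild-type group means
curvature_proxy(42.7, 179.5)  # cup-shaped mutant group means
```

Physically flattening a cupped or crinkly leaf requires marginal cuts;
the measurement convention excludes the freshly cut edges and sums the
pieces. `split_outline_by_line()` and `piecewise_perimeter()` reproduce
that convention on polygons, and the suite verifies margin conservation
on random chord partitions. On meshes, `mesh_metrics()` computes the
proxy intrinsically — cut-free — which equals the cut-and-flatten value
precisely because intrinsic area and boundary length are what cutting
preserves.

## Surface meshes

`gen_surface()` triangulates the three canonical curvature carriers:
a flat disc, a spherical cap (vertices exactly on the sphere), and the
saddle $z = kxy$ over a disc, each with a single rim. Closed forms
anchor the tests: a hemisphere has $A = 2\pi R^2$, rim $2\pi R$, hence
proxy $\sqrt{2\pi} \approx 2.507 < 2\sqrt{\pi}$; the saddle's area
$2\pi((1+k^2R^2)^{3/2}-1)/(3k^2)$ and quadrature rim length put its
proxy above the flat value. Curvature is classified against
$2\sqrt{\pi}$ with a ±2% band, chosen to exceed the discretisation
error of default-resolution meshes (mesh metrics converge to the
closed forms as resolution shrinks; the suite checks the error decays).
The classification presumes a disc-like rim — planar elongation also
raises the proxy, which is exactly why the ellipse null model exists
for real leaves. Pointwise curvature estimation (angle deficits and the
like) is deliberately out of scope: the global proxy is the published
statistic, and it is known to depend on how curvature is distributed
across the surface; no correction for that is defined or attempted.

## The arrest-front profile

Within the transition zone where cells stop dividing, the fraction of
cells still expressing a mitotic reporter (a cyclin-promoter GUS
fusion) is counted in rectangular 200×100 µm fields tiled from midrib
to margin. `bin_fields()` assigns each cell to exactly one field by its
centroid; a trailing partial field is kept if it covers at least half a
field width, otherwise merged. `fraction_profile()` adds binomial
standard errors; `average_profiles()` combines replicate leaves
(per-leaf fractions averaged per bin by default, pooled counts as an
option). `classify_front()` condenses a profile into the reported
qualitative shapes by comparing the midrib-adjacent third of fields
("central" in the anatomical sense — the medial region) with the
marginal third, at a margin δ = 0.05 ≈ twice the binomial SE of a
150-cell field: concave when the margin leads, convex when the medial
region leads, with the strong-convex-with-midrib-dip label when the
peak is interior and exceeds the first field by more than δ.

The generator's front presets encode the study conditions: a linear
decline 0.25 → 0.10 (wild-type-like, mildly convex), a smooth
quadratic-flank curve 0.27 → 0.40 (peak at x = 0.35) → 0.15
(mutant-like, strongly convex with a midrib dip), and a linear rise
0.10 → 0.30 (margin-overgrowth-like, concave). The mutant peak uses
quadratic flanks with zero slope at the peak because a kinked peak
would be attenuated ~2.6 percentage points by 200-µm field averaging,
while the smooth form loses <1 point; the front is biologically a
smooth gradient, not a kink. Note the estimand of a binned profile is
the *field average* of p(x), not its endpoint values: for the linear
wild-type preset the first field's true mean is 23.5%, not 25%. Tests
therefore check recovery against the field-averaged truth at two
pooled binomial SEs, plus agreement of those field means with the
printed ~25%/~10%/~40% at binning resolution.

## Proliferation-zone dynamics

The proliferation zone is defined operationally: the distance from the
lamina base to where the reporter-positive fraction adjacent to the
midrib first falls to ~10%. `zone_length()` evaluates the fraction in a
100-µm sliding window (matching the field height; the boundary is
admittedly gradual, and the 10% threshold is the convention's, not
nature's) over a 200-µm midrib column. Across a developmental series,
`zone_slope()` fits zone length against total leaf length by OLS. The
generator presets reproduce the two reported regimes — slope
−0.37 mm/mm (shrinking zone) and +0.43 mm/mm (persistently growing
zone) — with Gaussian scatter derived by inverting
$R^2 = s^2\,\mathrm{var}(L) / (s^2\,\mathrm{var}(L) + \sigma^2)$ for
the reported $R^2$ of 0.67 and 0.76, over 20 leaves evenly spanning
1–3 mm. Intercepts (1.24 and 0.20 mm) were fixed once so the line plus
scatter stays inside the physical band $0 \le \mathrm{zone} \le L$
essentially always; out-of-band draws are clipped and flagged. At these
conditions the OLS slope has a standard error near 0.05, so the ±0.10
recovery band is a ~2-SE statement: the suite checks it as replicate
statistics (≥90% of 20 series within the band, mean bias < 0.04)
rather than staking it on a single draw.

## Growth kinetics

Width growth is logistic,
$w(t) = w_{max} / (1 + e^{-4 r_{max} (t - t_{mid}) / w_{max}})$,
parameterised directly by the peak rate $r_{max}$ because peak rates
are what the field reports (wild-type-like 0.5 mm/day; the round-leaf
mutant grows at twice that). Sampling follows the protocol: alternate
days over 20 days. `growth_rates()` uses centred finite differences
with no smoothing by default — the published peak rates come from raw
2-day sampling — and the 4-day centred stencil recovers the analytic
peak within ~1.6% (the tests allow 5% for discretisation).

## Synthetic cells and images

`gen_cell_map()` tessellates tissue with hexagons whose area equals the
target cell area, then jitters each shared lattice vertex once — the
tessellation stays space-filling with simple polygons and the mean cell
area within a few percent of target. Cells in the transition band use a
150 µm² target (mitotic cells run ~100–200 µm²), giving ~133 cells per
200×100 µm field, inside the 100–150-per-field counting convention;
mature-leaf emulations use ~6000 µm². It does not attempt pavement-cell
lobing, cell-size gradients, stomatal lineages, or serrations — so
passing tests demonstrate correct *measurement* under the assumed
statistical structure, not robustness to every histological reality.

`assign_gus()` draws each cell's reporter status as an independent
Bernoulli at its centroid's normalised midrib distance — the
measurement model behind binomial error bars — ignoring any spatial
correlation of division states between neighbours.

`render_gus_image()` rasterises the map: stained cells in indigo, dark
2-pixel walls (so adjacent stained cells stay 8-connectivity-separated),
optional additive Gaussian noise, plus an exact ground-truth mask.
`classify_pixels()` thresholds a stain discriminant (blue minus mean of
red and green) by Otsu's criterion after a 3×3 median filter —
edge-preserving, so noise-free renders are essentially unchanged — or
classifies by nearest labelled-stroke mean when training strokes are
given (multi-modal background needs one stroke per mode, e.g. tissue
and walls). `count_objects()` labels 8-connected components, splits
touching cells by one watershed round on the distance transform
(default on: under 10% noise, stained neighbours otherwise fuse across
thin walls and counts drop ~16%), and filters objects below a quarter
of the target cell area. On these renders the automated per-field
fractions match ground-truth counting within 0.05 — the
manual-versus-automated agreement the original measurements relied on,
made testable.

## Cohort summaries and statistics

`summarize_groups()` reports per-genotype mean ± SEM for all planar
metrics. The group proxy appears both as the mean of per-leaf ratios
and as mean-P over √(mean-A); the latter is the published-table
convention (36.3/√90.3 = 3.82 → 3.8) and is the comparable column.
`students_t()` exposes the pooled-variance test as the default, Welch
as an option, since the source convention says only "Student's
t-test"; no multiple-testing correction is applied, matching the raw
reported p-values. Outline cohorts generated around the wild-type
group means need boundary roughness ≈ 0.25 to reproduce the measured
group proxy 3.8 — smooth ellipses sit at the null-model value 3.65,
and the measured excess is attributed to imperfect elliptical shape;
this calibration is fixed in `default_pipeline_config()`.

## Numerical choices and degenerate inputs

Outline vertex counts round up to multiples of four so axis extremes
are sampled exactly; radial noise is damped (halved, up to 30 times)
if it would drive the radius towards zero, keeping outlines
star-shaped and hence simple. Self-intersection is checked by an
O(n²) vectorised segment test. Meshes must present exactly one
boundary loop — a cut mesh is rejected with instructions rather than
silently mis-measured. Zero-variance t-test inputs return p = 1 when
means agree and error otherwise. Empty groups, empty fields, empty
masks, non-monotone day grids, and bands outside the tissue all fail
loudly. All randomness flows through per-call seeds; every generator
is bit-reproducible given its spec.

## Problem sizes

The shipped tests and the acceptance script run at the study's own
scales: 11 and 5 replicate leaves for front profiles (~650–1500 cells
per pooled field), 20-leaf zone series, 10-leaf shape cohorts,
1000×100 px renders at 1 µm/px, and 60 replicates for the
profile-recovery property. These sizes give binomial/OLS standard
errors matching the published error bars; nothing in the methods
depends on them beyond precision.

## Known limitations

The proxy conflates planar shape with curvature (hence the null
model); the classification band assumes disc-like rims; the front
profile assumes independent Bernoulli cells; the renderer's scene is
far simpler than micrographs (no staining gradients, shading, or
stitching artefacts); and the zone-length estimator inherits the
arbitrariness of the 10% threshold — sweeping it shifts zone length
monotonically (a laxer threshold shortens the zone), so comparisons
are only meaningful at a fixed threshold.
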