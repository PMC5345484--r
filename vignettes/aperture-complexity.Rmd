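---
title: "Aperture complexity analysis for VMAT plan QA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aperture complexity analysis for VMAT plan QA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The metric and its assumptions

Volumetric-modulated arc therapy (VMAT) optimizers can meet a prescription
with anything from large, smooth apertures to small, ragged ones. The ragged
solutions are harder to deliver: dose calculation is less reliable for small
openings, and the delivered fluence becomes sensitive to multileaf collimator
(MLC) leaf-position errors and to how the planning system models the leaf
ends. This package scores that raggedness with a purely geometric plan metric

$$ M \;=\; \frac{1}{MU}\sum_{i} MU_i \,\frac{y_i}{A_i} \qquad [\mathrm{mm}^{-1}] $$

where the sum runs over control-point apertures, $MU_i$ is the monitor units
delivered through aperture $i$, $A_i$ its open area (mm²) and $y_i$ its
*side perimeter* (mm): the length of open-field boundary running parallel to
the leaf travel direction. Leaf-end edges (perpendicular to travel) are
excluded because every aperture has them regardless of modulation; only the
staircase along leaf sides grows with irregularity. For a single aperture
the metric is $y/A$; for an arc, $MU$ is the arc meterset; for a plan, the
total. Because the MU weights are normalized, $M$ is independent of
prescription dose, and because $y/A$ is a ratio of one length to an area it
is only weakly sensitive to target size.

Assumptions worth stating: the model is geometry-only (no fluence, no
rounded-leaf-end or tongue-and-groove corrections, no inter-leaf leakage);
apertures are evaluated at control points, not at midpoints of delivery
segments; and the aperture is the intersection of the MLC opening with the
jaw rectangle in the beam's-eye-view plane at isocenter.

## Geometry: area, side perimeter, and the cases the definition leaves open

Each opposed leaf pair occupies a band between consecutive cross-leaf
boundaries; its opening is an interval along the travel axis, clipped by the
x jaws, and the band itself is clipped by the y jaws. The area is
$\sum_j h_j w_j$; the side perimeter counts each open band's interval twice
(upper and lower edge) and subtracts twice the overlap wherever two
geometrically adjacent bands are both open. Disconnected openings need no
special handling.

Three conventions are deliberate package decisions, because the metric's
verbal definition does not pin them down:

* **Closed-pair gap tolerance (`min_gap`, default 0.5 mm).** Planning
  systems park "closed" pairs with a small dosimetric gap. Any interval
  shorter than `min_gap` is treated as closed; otherwise every parked pair
  under the open jaw would contribute two long phantom edges. The value is a
  physical length: scale invariance of the metric holds only if `min_gap` is
  scaled together with the geometry, which is how the property tests state
  it.
* **Jaw-created edges.** Edges parallel to leaf travel created by the
  y jaws count toward $y$; edges perpendicular to travel created by the
  x jaws are excluded. This keeps a single consistent rule — exclude
  everything perpendicular to travel — rather than special-casing jaws.
* **Closed apertures with MU.** A control point with zero open area has no
  defined $y/A$; it is excluded from both the numerator and the MU
  denominator, with a warning. The alternative (treating its complexity as
  0) would reward fully blocked segments, which is clearly wrong.

The analytic computations are verified against an independent
pixel-rasterization oracle (`rasterize_oracle()`): open-pixel counting for
area, open/closed adjacency counting in the cross-leaf direction for the
side perimeter. The oracle is exact for on-grid rectangles and converges as
the pixel shrinks; the agreement tolerance ($2 \cdot \text{pixel} \cdot
n_{pairs}$ for the perimeter) assumes every geometric feature spans at least
one pixel, so the test fixtures avoid sub-pixel slivers.

## MU allocation

DICOM stores a cumulative meterset weight per control point, not $MU_i$.
The default **midpoint rule** gives each control point half of each adjacent
delivery interval — the natural choice given that the machine interpolates
apertures continuously between control points. A **forward rule** (each
interval attributed to its starting control point) is selectable for
sensitivity checks. Both conserve the beam meterset exactly, which is the
invariant the tests fuzz.

## DICOM-RT Plan I/O

No DICOM library is available in this toolchain, so the package includes a
minimal Explicit-VR-Little-Endian serializer/parser covering what an RTPLAN
needs: string and decimal-string attributes and nested sequences (defined or
undefined lengths). Files written by `write_rtplan()` are standard part-10
objects; `read_rtplan()` rejects other transfer syntaxes with a clear error
rather than guessing. Leaf positions are stored as decimal strings with 10
significant digits (round-trip error below $10^{-10}$ relative); leaf and
jaw positions are carried forward from the last control point that specified
them, as the standard requires; opposing-bank sign conventions are
normalized so `left <= right` always holds. Plans with multiple fraction
groups use the first; setup beams are skipped with a warning; static-MLC
beams are scored (the metric is aperture-generic) but tagged, since the
validation cohort behind the default threshold was VMAT-only.

## Cohort comparison and the threshold

A scored plan is placed in context against a reference cohort CSV: a
fixed-width histogram (default bin width 0.01 mm⁻¹, chosen for readable
clinical histograms; configurable), a mid-rank percentile, and a
site-stratified summary (total / failing / above-threshold /
failing-above-threshold counts with class means ± sample SD). "Above
threshold" is strict (`M > T`) everywhere — cohort tables, confusion counts,
the workflow flag — so a plan exactly at the threshold passes; one
convention, documented, applied consistently.

The package ships the summary table of a published institutional reference
cohort (711 VMAT plans, 62 QA failures, tabulated at 0.18 mm⁻¹) and a
default review threshold of 0.18 mm⁻¹. That threshold is
**institution-specific**: it depends on the QA criteria (here a composite
4%/1 mm analysis), the dose algorithm, and the delivery machines behind the
reference cohort. The CLI prints a warning to that effect, and `vmatqa roc`
recalibrates the threshold on a local cohort by constrained ROC analysis:
both TPR and FPR are non-increasing step functions of the threshold, so the
smallest candidate threshold with FPR below the bound (default 10%)
maximizes TPR among compliant choices. Candidates are midpoints between
adjacent distinct complexities plus sentinels, so no datum ever ties the
recommended threshold. The ROC curve is empirical — no smoothing or
binormal fit — and AUC is the trapezoid over the step curve.

## What the synthetic generators do and do not emulate

`make_modulated_plan()` builds one full arc conformal to a spherical
target's circular projection, then retracts each leaf *away* from the field
center by an independent $|N(0,\sigma)|$ draw. Opening outward keeps the
target covered and makes the staircase mismatch between adjacent pairs grow
faster than the area, so mean plan complexity increases strictly with
$\sigma$ — the property the tests check over seeds. $\sigma = 0$ reproduces
the conformal plan exactly. The generator emulates controllable aperture
irregularity, not an optimizer: no dose, no OAR-driven shapes, no
dose-rate/gantry-speed constraints.

`simulate_cohort()` draws class complexities from normal distributions
truncated at 0, with defaults matching the reference cohort's "All" row
(passing $0.132 \pm 0.036$, failing $0.170 \pm 0.040$ mm⁻¹, $n = 649/62$).
Real complexity histograms are right-skewed; the truncated normal is a
deliberate stand-in adequate for exercising counting, ROC and threshold
machinery. A green test on synthetic cohorts therefore establishes that the
machinery is correct, *not* that the package reproduces any clinical
cohort's distribution — the reference per-plan data are not public, which is
also why cohort-level distributional results are out of reach for the test
suite and are anchored instead through the published summary counts.

Default synthetic geometry is a Varian Millennium-style bank (60 pairs:
central 40 of 5 mm, outer 20 of 10 mm), a common clinical configuration;
clinical plans always carry their own boundaries.

## Numerical choices and degenerate inputs

* Percent reporting rounds half away from zero (`as_percent()`), matching
  how clinical summaries print 43.5% as 44%.
* Summaries display mm⁻¹ to 3 decimals; CSV/JSON exports keep full
  precision.
* A group with a single plan in a class reports its mean with no SD; an
  empty class prints a dash.
* Degenerate threshold recommendations (TPR = 0) are flagged rather than
  hidden; `max_fpr >= 1` disables the constraint.
* Zero-MU control points appear in the gantry-angle profile but cannot
  influence $M$.
* An arc whose every control point is closed (or whose open control points
  carry no MU) has no defined complexity and errors explicitly.

## Known limitations

Rounded leaf ends, tongue-and-groove, transmission and interdigitation are
not modeled; the metric is evaluated at control points rather than averaged
over delivery segments; per-site threshold optimization is left to the user
(filter the cohort and rerun `roc`); and the DICOM layer reads only the
transfer syntax it writes, which covers files exported by major planning
systems only after transcoding to Explicit VR Little Endian.
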