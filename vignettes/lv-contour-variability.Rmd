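---
title: "Quantifying inter-observer variability of LV endocardial contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-observer variability of LV endocardial contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcontour)
```

## The problem

Left ventricular ejection fraction (LVEF) measured with Simpson's biplane
method of disks is the workhorse quantity of clinical echocardiography, and
its inter-observer variability is notoriously large. When many readers trace
the same end-diastolic (ED) and end-systolic (ES) frames of the same apical
two-chamber (2CH) and four-chamber (4CH) cine loops, their endocardial
contours spread — globally (one view worse than the other), regionally (one
wall worse than another), temporally (ED worse than ES), and at the anatomic
anchor points (mitral annuli, apex). `lvcontour` implements a geometric
pipeline that turns a pile of hand-drawn contours into exactly these
decompositions: where, and by how much, do observers disagree?

The package operates purely on contour coordinates (millimetres in the view
plane). It does not segment images, read DICOM, or select cardiac frames:
tracings arrive as ordered point lists with the two mitral-annulus anchors,
one per observer, patient, view and phase.

## The canonical contour

All comparisons happen on a *standard contour* of 99 labelled points:

1. the apex is detected as the traversal point with the largest Euclidean
   distance to the midpoint of the two mitral annuli;
2. the two annulus-to-apex arms are resampled equidistantly by arc length,
   49 intervals per arm, so that label 1 carries the septal (4CH) or
   inferior (2CH) annulus, label 99 the lateral or anterior annulus, and
   label 50 the apex.

Orientation is a convention the package fixes (label 1 = septal/inferior);
the wall identity of every label then follows from the label range alone.
Tracings drawn as a closed loop across the mitral plane are first cut: the
annulus-to-annulus chord separates the loop, the apical arc is kept, basal
points are discarded (no surviving point is moved), and the exact annulus
coordinates terminate the arc.

Interpolation along the raw polyline is linear — spline smoothing would
alter distances between observers and reference. A single arc-length
resampling pass leaves the output chord lengths unequal by
$O(\Delta s^3 \kappa^2)$, which breaks idempotence near the
high-curvature apex; `resample_arm()` therefore iterates the resampling a
few times to its fixed point (the equal-chord polyline inscribed in the
drawn contour). With that refinement, re-standardizing a standard contour
reproduces it to well below the 0.01 mm tolerance, and per-arm chord
equality holds far inside the 1 % tolerance, for contours whose apex
curvature radius is a few millimetres or more — i.e. for LV-like shapes.
Extremely sharp apices (radius ≲ 3 mm at a ~2 mm point spacing) are below
the resolution of a 99-point representation; no tolerance can fix that, only
more points could.

Degenerate inputs error early and by name: fewer than 3 points for apex
detection, coincident annuli, a zero-length arm, an apex on the mitral
chord, a zero-length long axis.

## Volumes and ejection fraction

Simpson's method stacks `n_disks` slices perpendicular to the long axis
(mid-annular point to apex). Disk $i$ of $n$ sits at fraction $(i-0.5)/n$ of
the axis — the midpoint rule, so neither the mitral plane nor the apex
contributes a degenerate end disk — and its diameter is the chord between
the two contour arms, linearly interpolated between standardized points.

* monoplane: $V = \sum_i \frac{\pi}{4} d_i^2 \, L/n$;
* biplane: $V = \sum_i \frac{\pi}{4} a_i b_i \, L/n$ with $a_i, b_i$ sampled
  at the same fractional positions along each view's own long axis and
  $L = \max(L_{4CH}, L_{2CH})$ — the standard biplane convention;
* $EF = 100\,(EDV - ESV)/EDV$.

`n_disks` defaults to 20, the conventional clinical disk count; closed-form
comparisons in the tests use 200, where the half-ellipse volume agrees with
$\frac{2}{3}\pi b^2 L$ to a few hundredths of a percent. Results depend on
the disk-count and long-axis conventions at roughly the 1 % level, which is
why both are explicit, configurable parameters.

## Reference contour and distances

The consensus ("reference") contour of one patient/view/phase is the
componentwise median of all observers' points, label by label — the centre
of the density that the superimposed contours form. A density/heat-map rule
admits several readings (kernel mode, trimmed mean, ...); the pointwise
median was chosen because it is the natural robust centre on standardized
labels, is reproducible without bandwidth choices, and converges to the
truth under zero-mean noise (a property the test suite checks by
Monte-Carlo).

Individual deviation is measured *at each label*: the Euclidean distance
between an observer's label-$\ell$ point and the reference's label-$\ell$
point, signed positive when the observer's point lies on the outward side of
the reference (outward = away from the area centroid, via the local normal
of the reference polyline). The apex label 50 is excluded from segmental
statistics — its scatter is a landmark quantity — leaving 98 distances per
tracing.

One consequence of label correspondence is worth knowing. If a contour is
offset by a constant $\delta$ along the truth's normals *and the labels are
kept*, every signed distance is exactly $\delta$. If the offset polyline is
instead re-standardized, the arc-length reparameterization shifts labels
tangentially (an offset curve accumulates extra length in proportion to
turning angle), and same-label distances inflate by roughly 10 % for
half-ellipse geometry. That is a property of point-correspondence distance,
not a bug; calibration tests that assert closed forms therefore perturb
labelled contours directly, while recovery tests that only need orderings
run the full raw-tracing route.

Segments: each view splits into 6 segments (2 walls × basal/mid/apical).
Arm labels 1–49 map to basal 1–16, mid 17–32, apical 33–49; the mirrored arm
51–99 to apical 51–67, mid 68–83, basal 84–99. 48 non-annulus intervals per
arm do not divide evenly by three, so the extra label goes to the apical
segment — a convention, fixed once. Medians and IQRs pool distances across
patients and observers *at the point level* (each standardized point counts
equally; weighting patients equally instead would be a defensible
alternative, but pooling is what the summary tables here report).

## Landmarks

Labels 1, 99 and 50 give the two annulus positions and the apex. Offsets are
taken from the per-patient componentwise-median reference position of each
landmark and pooled across patients. Scatter is summarized as the percentage
of offsets inside concentric circles of **area** 1, 4 and 9 cm² (radii 5.64,
11.28, 16.93 mm) around the reference — reading "the inner ring covers
1 cm²" as a circle area; a square reading (sides 1/2/3 cm) would shift the
percentages by a known geometric factor and is not used. The four bins
always partition to 100 %.

For the 3D apex picture, the 2CH and 4CH planes are idealized as orthogonal
planes sharing the long axis (a 90° dihedral): the 4CH plane becomes the
xz-plane, the 2CH plane the yz-plane, lateral apex offsets supply x and y,
and the along-axis position is averaged. Contours are first rigidly aligned
and scaled to a common long-axis length (`normalize_length()`), since hearts
of different size must be pooled.

## Observer statistics

Per observer the pipeline derives: the median signed distance over all their
records (their overall tracing "size"), a small/medium/large classification
at a configurable threshold (default ± 1.0 mm — no published rule exists
for this grouping, so the threshold is an explicit parameter), the median
biplane EF over patients, the EF difference from the *reference-contour* EF
(EF computed from the reference contours per patient, median over patients —
not the median of observer EFs, matching the "difference from the reference"
framing; both are computable), volume deviations from the cohort median
(per phase, in percent), and an experience category: < 5, 5–10 (closed on
both ends), > 10 years.

Group comparisons use the independent-samples Kruskal-Wallis test; regional
comparisons use the related-samples Friedman test over blocks =
(observer × patient), treatments = wall regions, with two-treatment Friedman
reductions for the named pairs (septal vs lateral, inferior vs anterior,
ED vs ES, 2CH vs 4CH, apical vs basal). Correlations are Spearman with
midranks. P-values come from the asymptotic chi-square approximations; no
multiple-testing correction is applied. The test suite verifies every rank
statistic against brute-force rank-formula oracles on toy fixtures.

## The synthetic study generator

Real multi-reader tracing sets are rarely shareable, so the package ships a
generator whose defaults emulate a study of **15 echocardiograms × 42
observers × 4 tracings**:

* **Truth geometry** per patient: half-ellipse silhouettes (long axis
  72–95 mm, basal semi-width 19–28 mm per view), ES = ED scaled in-plane by
  $s = (1 - EF/100)^{1/3}$ with truth EF drawn from a normal (mean 49 %,
  sd 15 %, truncated to 15–72 %) — the half-ellipse is chosen for its
  closed-form Simpson volume, which the oracles exploit, not for anatomical
  realism.
* **Tracing noise**: each non-landmark point is displaced along the truth's
  outward normal by a per-observer bias plus $N(0, \sigma^2)$ with
  $\sigma$ = wall base value (septal 2, inferior 2.2, lateral 3,
  anterior 3.2 mm) × level multiplier (basal 0.9, mid 1, apical 1.25) ×
  phase multiplier (ED 1, ES 0.85) × view multiplier (2CH 1.1, 4CH 1).
  The values encode the qualitative orderings the analysis should recover
  (lateral > septal, anterior > inferior, apical > basal, ED > ES,
  2CH > 4CH); they are configuration defaults, not claims about any
  particular reader population. An optional centred moving average along the
  contour (window $w$) produces spatially correlated noise and reduces the
  marginal point sd by about $\sqrt{w}$; closed-form assertions use $w = 0$.
* **Landmarks**: the annulus and apex points receive kind-specific isotropic
  2D jitter instead of the wall noise (septal/inferior 2, lateral/anterior
  3, apex 4 mm), mirroring the common observation that the medial annulus is
  the best-anchored landmark and the apex the worst.
* **Observer structure**: a per-observer outward bias (sd 1 mm, shared
  across phases and patients), an optional ED-only extra bias (couples
  contour size to EF: tracing ED generously raises EDV but not ESV, hence
  EF — the mechanism behind a "larger contours, higher EF" pattern), and an
  optional multiplicative in-plane scale bias that moves contour size while
  leaving EF exactly unchanged (both phases scale equally), which is the
  clean null for calibration studies. Experience years are assigned
  independently of tracing behaviour.
* Noise is applied along normals only; tangential jitter is deliberately
  absent so that injected $\sigma$ maps directly onto measured distances.
  The generator emits raw polylines and never reads analysis output.

What passing tests on this generator do **not** show: real tracings have
spatially correlated, image-quality-dependent errors, foreshortened apices,
and systematic shape deviations from half-ellipses; recovery of injected
orderings here demonstrates that the *pipeline* is faithful, not that any
particular clinical variance decomposition is correct.

## Problem sizes and tolerances in the test suite

Property suites run 100 random LV-like contours for the standardization
invariants; reference consistency uses 200 simulated observers at
$\sigma = 2$ mm; distance calibration uses the full study scale
(42 × 15 × 4 tracings, ~247k distances); ordering and grouping recovery run
20 seeded studies at full scale; null calibration of the omnibus tests runs
500 reduced-scale replicates (2 patients × 15 observers) against the
[0.02, 0.08] acceptance band at nominal $\alpha = 0.05$. Identity-type
tolerances are 0.01 mm per point and 1 % chord equality; both are module
constants.

## Known limitations

* Distances are same-label point-to-point, not point-to-curve; label
  correspondence is the method's backbone and also its main approximation
  (see the offset-inflation note above).
* The reference is an unsmoothed pointwise median; with very few observers
  it is noisy, and all consistency statements are asymptotic in the reader
  count.
* The biplane 3D registration assumes exactly orthogonal view planes.
* Intra-observer and scan-rescan variability are out of scope; the package
  models a single reading per observer.
* The generator's EF-size coupling scenarios are mechanisms, not estimates:
  the true joint distribution of observer bias across phases in any real
  reader population is unidentifiable from summary tables.
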