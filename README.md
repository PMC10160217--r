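# lvcontour

Geometric analysis of inter-observer variability in Simpson's-method left
ventricular (LV) ejection fraction measurement.

When many readers trace the endocardial border on the *same* predefined
end-diastolic (ED) and end-systolic (ES) frames of the same apical
two-chamber (2CH) and four-chamber (4CH) views, their contours — and hence
their volumes and ejection fractions — spread considerably. `lvcontour` is
for researchers who want to decompose that spread geometrically: by view, by
cardiac phase, by wall region and level, and at the anatomical landmarks
(mitral annuli, apex), and to relate each observer's tracing style to the
ejection fraction they obtain.

## What it computes

Every tracing (an ordered point list in mm with the two mitral-annulus
anchors) is standardized to a canonical 99-point contour: the apex — the
point farthest from the mid-annular point — gets label 50, the annuli labels
1 and 99, and each annulus-to-apex arm is resampled equidistantly by arc
length. On standardized contours the package provides:

* **Simpson volumes and EF** — method of disks, mono- and biplane:
  `V = Σ (π/4) a_i b_i L/n` over `n` disks perpendicular to the long axis;
  `EF = 100 (EDV − ESV)/EDV`.
* **Reference contours** — per patient/view/phase consensus as the pointwise
  (componentwise) median over observers.
* **Distance statistics** — per-label Euclidean distance to the reference,
  signed positive outside it; medians and IQRs per segment (2 walls × 3
  levels), wall, level, view and phase.
* **Landmark scatter** — offsets of each observer's annulus/apex positions
  from the cohort reference, binned by concentric circles of area 1, 4 and
  9 cm², plus 3D apex registration from the two orthogonal views.
* **Observer statistics** — small/medium/large contour grouping by median
  signed distance, volume over/under-estimation vs the cohort, experience
  categories, Kruskal-Wallis / Friedman / Spearman comparisons.
* **A synthetic study generator** — seeded, with wall-, level-, phase- and
  view-specific tracing noise, observer-level bias and landmark jitter, so
  the whole pipeline is testable end to end without patient data.

## Worked example

Simulate a default-scale study — 15 echocardiograms × 42 observers × 4
tracings each — and run the full analysis:

```r
library(lvcontour)

cfg   <- synth_config(seed = 42)
study <- simulate_study(cfg)
res   <- run_full_analysis(study)

res$table2
#>    region        2CH_ED        2CH_ES        4CH_ED        4CH_ES
#>       all 3.4 (2.1-5.2) 3.0 (1.8-4.5) 3.1 (1.9-4.7) 2.8 (1.7-4.2)
#>  anterior 3.7 (2.3-5.5) 3.2 (2.0-4.8)          <NA>          <NA>
#>  inferior 3.2 (1.9-4.9) 2.7 (1.7-4.2)          <NA>          <NA>
#>    septal          <NA>          <NA> 2.8 (1.7-4.3) 2.7 (1.6-4.0)
#>   lateral          <NA>          <NA> 3.4 (2.1-5.0) 3.0 (1.8-4.4)
#>    apical 3.9 (2.5-5.7) 3.4 (2.1-4.9) 3.6 (2.2-5.3) 3.3 (2.0-4.7)
#>       mid 3.8 (2.3-5.7) 3.3 (2.0-4.9) 3.3 (2.0-5.0) 3.1 (1.9-4.5)
#>     basal 2.7 (1.7-4.1) 2.4 (1.5-3.6) 2.4 (1.5-3.6) 2.3 (1.4-3.3)
```

Each cell is the median (IQR) distance in mm between individual and
reference contours, pooled over all patients and observers. The generator's
injected structure is visible exactly where it should be: 2CH spreads more
than 4CH, ED more than ES, the lateral/anterior walls more than the
septal/inferior walls, and apical segments more than basal ones. The
pairwise Friedman reductions over (observer × patient) blocks confirm the
orderings:

```r
res$regions$pairwise[, c("comparison", "statistic", "p_value")]
#>            comparison statistic       p_value
#>     septal vs lateral  60.97778  5.772271e-15
#>  inferior vs anterior 102.40635  4.522498e-24
#>              ED vs ES  79.64444  4.482285e-19
#>            2CH vs 4CH  42.69206  6.407172e-11
#>       apical vs basal 515.71429 3.622123e-114
```

Landmark scatter (here 4CH at end-systole) shows the septal annulus as the
best-anchored landmark and the apex as the loosest — percentages of
observations inside concentric circles of area 1 / 4 / 9 cm²:

```r
res$table3[res$table3$view == "4CH" & res$table3$phase == "ES", ]
#>  view phase            kind lt_1cm2 cm2_1_to_4 cm2_4_to_9 gt_9cm2   n
#>   4CH    ES            apex    73.5       25.4        1.1       0 630
#>   4CH    ES lateral_annulus    81.0       18.9        0.2       0 630
#>   4CH    ES  septal_annulus    96.0        4.0        0.0       0 630
```

Observer-level grouping (small / medium / large tracers at a ±1 mm median
signed-distance threshold) and the mean biplane EF of this run:

```r
table(res$profiles$size_group)
#>  small medium  large
#>     16      8     18
mean(res$volumes$ef_pct)
#> [1] 55.1
```

`run_full_analysis(study, out_dir = "analysis")` additionally writes the
summary tables, observer profiles, distance records, test results and a JSON
run report (with the seed and full configuration) as tidy CSV/JSON files.

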