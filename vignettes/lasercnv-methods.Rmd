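---
title: "Quantifying laser-induced CNV lesions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying laser-induced CNV lesions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasercnv)
```

## The model system

Laser photocoagulation of the mouse fundus ruptures Bruch's membrane and
triggers choroidal neovascularization (CNV), the standard in-vivo model for
the exudative form of age-related macular degeneration. In a typical study
four burns are placed per eye around the optic nerve, and seven days later
the RPE/choroid/sclera eye cup is flat-mounted, stained with Isolectin B4
(IB4), and imaged; the stained lesion area is the primary endpoint.
Optionally, fundus fluorescein angiography (FFA) frames taken 5 and 10
minutes after dye injection quantify vascular leakage.

The model is notoriously variable, and the reliability of its results
hinges on two methodological commitments that this package implements as
first-class, testable code:

1. **a constant segmentation threshold** — the lesion/background intensity
   cut is fixed once per study and applied unchanged to every image, and
2. **an explicit rule-based exclusion protocol** — burns that failed to
   rupture Bruch's membrane, lesions compromised by hemorrhage or
   excessive (choroidal) damage, fused lesions, extreme outliers, and
   lesions left standing alone in their eye are removed before statistics.

Because no raw images accompany the published group tables, every stage is
driven by a seeded synthetic-eye generator with known ground truth; the
published group statistics serve as the generator's calibration and as
fixed arithmetic checks.

## Pipeline

`run_pipeline()` chains the stages, communicating only through files so any
stage can be rerun standalone:

1. **generate** — `sample_lesion_truths()` + `render_flatmount()` /
   `render_ffa_pair()` produce per-eye image pairs and a truth table;
2. **segment** — `segment_lesions()` (constant threshold, 8-connected
   components, `min_area` filter), `assign_to_sites()`,
   `detect_bleeding()`, `detect_choroidal_damage()`;
3. **qc** — `grade_hemorrhage()`, `apply_exclusions()`,
   `tally_lesion_types()`;
4. **leakage** — `measure_leakage()` on the FFA pair within the
   segmentation labels;
5. **stats** — `summarize_group()`, `percent_relative()`,
   `compare_two()` / `compare_many()`, `build_report()`.

## Grading and exclusion rules

Hemorrhage severity is graded by the ratio of the bleed region's major
axis to the lesion diameter (LD): grade 0 below 1 LD (lesion kept),
grade 1 in [1, 2) LD (lesion excluded), grade 2 at 2 LD and above (the
entire eye excluded). Two definitions had to be fixed where the protocol
literature leaves them open:

* **Lesion diameter** is the equivalent circular diameter of the lesion
  mask, `2 * sqrt(area / pi)`. Any other choice (e.g. a caliper diameter)
  is orientation-dependent for irregular masks.
* **Boundary closure.** The verbal bands use strict "smaller"/"bigger" on
  both sides, leaving exact equality undefined. Equality is assigned to
  the *higher* grade (axis = LD is grade 1, axis = 2 LD is grade 2):
  conservative toward exclusion, and it makes the three bands a true
  partition of `[0, Inf)`.
* **Bleed size** is the major axis of the second-central-moment ellipse of
  the bleed component (EBImage moment features), matching the "major
  axis" wording; a bounding-box diagonal was rejected as
  orientation-dependent.

`apply_exclusions()` applies the rules in a fixed order: structural
exclusions (failed rupture, choroidal damage, fusion) first, then the
eye-level grade-2 rule, then lesion-level grade-1, then the 5x outlier
rule, and the sole-survivor rule last. The order is a design choice — the
protocol does not state one — made so that outlier means are computed over
structurally valid lesions only, and so that "only one lesion left"
is judged after every other rule has spoken. The engine is idempotent and
each excluded lesion carries exactly one reason (first firing rule wins).

The **outlier rule** flags a lesion larger than 5 times the mean of the
other lesions in scope. Two open points were settled as follows:

* *Scope*: protocol descriptions alternate between "the same eye" and
  "the same experimental conditions"; both are implemented
  (`outlier_scope = "eye"` is the default — within-eye comparison is
  robust to between-animal variation).
* *Leave-one-out*: the candidate lesion is excluded from the mean it is
  compared against. Including it would dilute the test — with 4 lesions
  per eye, a true 6x outlier inflates its own reference mean by more than
  a factor of 2.

Per-shot outcomes are tallied per group into counts and percentages of
total shots. Sole survivors get their own tally column (the published
tables have no such row; keeping it separate preserves the invariant that
category counts partition total shots). Mouse counts are reported as
eyes/2 because animals lost before contributing shots are not derivable
from the shot table.

## The synthetic-data generator

The generator emulates exactly the study conditions the calibration tables
describe; its defaults are therefore not tuning knobs:

* **Areas** are log-normal, moment-matched to the published group mean and
  SD (`lognormal_match()`); areas are positive and right-skewed, and the
  published dispersion/mean ratios (0.4-0.7) make a normal model
  untenable. A 10^5-draw Monte-Carlo check in the test suite confirms the
  matched moments to within 1% (mean) and 3% (SD).
* **Complication frequencies** default to the published per-shot outcome
  frequencies of the power-level study (`reference_groups("power")`).
  Published counts pool grade-1/2 bleeding; the 3:1 split toward grade 1
  reflects that eye-wide grade-2 events are the rarer, severer outcome.
* **Outlier lesions** are drawn uniformly in (5x, 8x) the group mean so
  the downstream 5x rule must fire on them.
* **Fusion** is drawn as an eye-level event with probability `2 * p_fused`
  that marks one random adjacent site pair, so the marginal per-shot
  fused frequency equals `p_fused` while fused lesions always come in
  renderable pairs. They are rendered as two discs joined by a connecting
  bar, producing one component that genuinely spans both burn sites
  without violating the layout geometry.
* **Choroidal damage** shrinks the lesion (x0.4 by default) and adds a
  near-black "hole" to the bright field, emulating the excessive-burn
  phenotype (a damaged lesion is smaller than its fellows).
* **Geometry.** Four sites at radius twice the disc diameter from the
  optic nerve at the 12/3/6/9 o'clock positions, optionally jittered; the
  layout enforces pairwise separation of at least two disc diameters.
  Defaults are a 1024 x 1024 canvas at 1.5 um/px with a 135 px
  (~200 um) disc — a realistic mouse optic-disc diameter, and large
  enough that lesions at the published area moments (including 5-8x
  outliers) cannot geometrically collide with a neighboring site. Smaller
  canvases are fine for smaller lesions; everything is configurable
  because flat-mount pixel calibration varies by microscope.
* **Rendering.** A lesion of area A is drawn as the `round(A / scale^2)`
  pixels nearest its center, so the rendered pixel count matches the true
  area to rounding precision (the 2% round-trip tolerance is then almost
  entirely segmentation, not rasterization). Bright-field intensity
  levels are well separated (background 200, bleeds 80, holes 10 on the
  8-bit scale) so the bleed band `(30, 120]` and the damage band
  `<= 30` are disjoint by construction. Gaussian pixel noise (sigma 5 by
  default) sits 14+ sigma away from every threshold, so noise alone
  cannot flip a pixel's class; `min_area` removes any residual specks.
* **Determinism.** Each eye draws from a substream derived from
  `(study seed, eye index)`; images, truths and reports are
  bit-reproducible for a fixed configuration.

What the generator does **not** emulate: vascular texture, staining
gradients, uneven illumination, flat-mount dissection artifacts (radial
cuts), or registration error between FFA frames. Passing tests therefore
demonstrate the correctness of the measurement and rule logic under the
stated geometric and photometric model — not robustness to real-world
image degradation, which a constant-threshold protocol inherits from its
imaging discipline.

## Statistics

Group results are reported as mean +/- SEM with the sample SD (n - 1);
`sem = sd / sqrt(n)` is asserted at machine precision. (Some published
tables print the dispersion and standard-error rows with their labels
interchanged — recomputing `dispersion / sqrt(n)` reproduces the printed
companion row; this package always computes both from their definitions.)
Relative lesion area is `100 * mean / reference mean`, displayed at 3
significant figures. Two groups are compared with a two-sided t test —
Welch by default, pooled Student as an option — and three or more with
classic one-way ANOVA (`stats::oneway.test`, equal-variance F). The
analysis unit is the lesion, matching the published per-lesion n; per-eye
aggregation can be performed on the emitted CSVs if eye-within-mouse
correlation is a concern (no mixed-effects modeling is attempted here).

## Numerical choices and degenerate inputs

* 8-connectivity for components (diagonal contact merges); deterministic
  row-major centroid ordering of measurements.
* A component claims a burn site if the site center lies inside it or
  within one disc radius; claiming two or more sites marks it fused;
  unclaimed sites are candidate failed ruptures.
* `sd_area = 0` degenerates to a point mass at the mean; `p_no_rupture =
  1` yields all-zero areas; empty images segment to an empty table, not
  an error; a single-lesion outlier scope warns and flags nothing.
* Degenerate statistics are errors, not NaNs: summaries need n >= 2,
  t tests need non-constant input, `percent_relative` needs a positive
  reference mean.

## Problem sizes

The test suite and the acceptance script run: a noiseless round-trip study
of 11 eyes (44 burns) for segmentation accuracy and category recovery; a
19-eye study (76 shots, approximately the published 240 mW study size) for
full-pipeline moment recovery; 2 x 10^4 burns for category-frequency
calibration; 10^5 draws for moment matching; 1000 null replicates (n = 50
per arm) for the type-I error of the two-group test and 400 replicates at
the published dietary effect size (n = 110 vs 105) for power. These sizes
were chosen so each check's Monte-Carlo error is small against its
tolerance while the whole suite runs in about a minute.

## Known limitations

* The published protocol's actual threshold value is instrument-specific
  and not printed; only the *constancy* contract is implementable, and the
  default (100/255) is calibrated to the synthetic rendering.
* Fused lesions are measured as one component; their combined area is
  reported but never enters group statistics (they are excluded).
* FFA frames are assumed registered; no alignment is attempted.
* The per-shot outcome fixture reconstructs eyes from marginal counts;
  any arrangement consistent with the counts yields the same tally, but
  it is not the (unknown) true eye-level layout of the original study.
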