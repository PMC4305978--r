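---
title: "Auditing DIA-assisted Ki67 annotation with counting-frame stereology"
author: "stereoKi67"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DIA-assisted Ki67 annotation with counting-frame stereology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

stereoKi67 supports editing-based production of reference Ki67 annotations:
a digital image analysis (DIA) system proposes marks on tumour nuclei, an
expert corrects them in a viewer, and the corrected set becomes the
criterion standard while the corrections themselves quantify the DIA's
per-component accuracy. The package assumes:

* the DIA's output is available as a **multicolor markup raster** in which
  each detected nuclear profile is painted in a class color (one dominant
  channel per class) on a neutral background — the upstream tissue
  classification and nuclear segmentation are treated as an opaque stage;
* marks are **points** (one per nuclear profile), so all counting and
  matching rules operate on point coordinates, not object boundaries;
* expert editing happens in an external viewer on the annotation XML; the
  package only consumes its output.

Coordinates throughout are 0-based integer pixels, x rightward, y downward.

### From markup mask to machine marks

`excessRGB()` computes the three excess color channels `2R−G−B`, `2G−R−B`,
`2B−R−G` in exact integer arithmetic (each in [−510, 510], summing to zero
per pixel). `thresholdClassMasks()` applies fixed thresholds to excess red
(immunostained class) and excess blue (counterstained class); a pixel
passing both goes to the larger excess, ties to positive, so the masks are
disjoint. `extractMarks()` labels 8-connected components, drops those
smaller than `minArea`, and places one mark at each centroid (mean pixel
coordinate, rounded half-up so XML round trips are lossless). The excess
green channel is computed for completeness but no class rule uses it: with
the canonical palette the two nuclear classes are red- and blue-dominant.
Touching nuclei are *not* split — segmentation quality is the upstream
system's property, and merging errors surface in the audit as detection
errors, which is the measurement this package exists to make.

### Counting frames

`generateGrid()` places rectangular frames on a lattice with one uniformly
random integer offset per grid drawn from a seeded generator (systematic
uniform random sampling). Frames that would cross the image border are
dropped, never clipped: a clipped frame would shrink the counted area
without shrinking the lattice cell and bias the sampling fraction. The
counting rule (`isCounted()`) is the classical unbiased 2D counting frame
adapted to y-down point marks: left and bottom edges forbidden, top and
right accepting, i.e. counted iff `x0 < x ≤ x0+w` and `y0 ≤ y < y0+h`.
Under this half-open convention adjacent frames of a tiling partition the
plane, so a mark is counted by at most one frame, and the expected counted
fraction of uniformly scattered points equals the frame-area fraction
exactly — both are property-tested. `autosizeGrid()` picks the spacing
`frameSize / sqrt(f)` (rounded up, floored at the frame size) for the
sampling fraction `f = min(1, targetMarks/nDetected)`, which holds the
expected number of reviewed marks near the target regardless of spot
cellularity.

### Matching and the edit taxonomy

`matchMarks()` pairs dD and cD marks by greedy nearest neighbour within a
tolerance (default 5 px), ascending distance, ties broken by index order.
Because the expert edits marks in place, unmoved marks dominate and pair at
distance zero; greedy matching is deterministic and each decision is
auditable, which we prefer over globally optimal assignment whose pairings
can change discontinuously with one coordinate. `classifyEdits()` then
assigns each mark exactly one category:

| category | meaning | edit |
|---|---|---|
| TRUE_POSITIVE / TRUE_NEGATIVE | paired, labels agree | none |
| FALSE_POSITIVE_LABEL | machine positive, expert negative | relabel |
| FALSE_NEGATIVE_LABEL | machine negative, expert positive | relabel |
| FALSE_DETECTION | machine-only mark | delete |
| UNDETECTED_BY_TISSUE_MASK | expert-added mark outside the epithelial mask | add |
| UNDETECTED_BY_NUCLEAR | expert-added mark inside the epithelial mask | add |

A relabel counts as one edit, not delete-plus-add. Expert additions are
attributed by position against the binary epithelial mask: a nucleus the
tissue classifier never saw cannot have been segmented, while a miss inside
the mask is the segmenter's. Machine-only deletions are kept as a single
category: distinguishing *which* component invented a mark would require
the vendor's internals, which the markup raster does not carry. Both mark
sets are restricted to grid-counted marks *before* matching, so effort
metrics reflect only the marks the expert actually reviewed.

### Series statistics

`summarizeEffort()` totals the per-spot tallies: percentage of edits and of
each category relative to total cD nuclei, and the manual-work savings
`1 − edits/nuclei` (floored at 0) — the reasoning being that every reviewed
mark that needed no edit is a manual placement saved; time spent looking at
the image is deliberately not modelled. `linearRegression()` is ordinary
least squares of one Ki67% series on the other with `R² = 1 − SS_res/SS_tot`
and the slope's t-test p-value (reported, not gating); spots with undefined
Ki67% (no counted nuclei) are removed pairwise with a message.
`blandAltman()` reports the mean difference and `bias ± 1.96·SD` limits of
agreement with the n−1 standard deviation.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tPos`, `tNeg` | 80 | excess units | well inside [0, 510]; any palette whose classes are channel-dominant clears it with wide margin |
| `minArea` | 20 | px | rejects speckle; the smallest plausible nuclear profile at ~0.5 µm/px is larger |
| frame size | 150×150 | px | a few dozen nuclei per frame at typical TMA cellularity |
| spacing | 2× frame | px | 25% sampling fraction; override or use `autosizeGrid()` |
| `tolerance` | 5 | px | an unmoved mark is at distance 0; 5 px absorbs rounding without capturing neighbours (nuclei are ≥ 8 px apart) |

The original acquisition's grid geometry and threshold values are not
recoverable from published material; these defaults are this package's own
and are exposed everywhere.

## The synthetic generator

`generateSpot()` emulates what the method needs and nothing more: a
circular spot (diameter 0.9 × image), an irregular epithelial region (union
of 10 random discs clipped to the spot, redrawn from the seeded stream
until it covers 40–85% of the disc so both compartments are usable),
non-overlapping axis-aligned elliptical nuclei with axes 4–8 px placed by
rejection sampling (≥ 3 px clearance; bounded attempts, then an explicit
infeasible-packing error), and Bernoulli Ki67 labels at the target rate.
The markup mask renders detected nuclei in saturated class colors on
mid-gray epithelium over a dark background. The error model injects, and
logs with coordinates, exactly the taxonomy the audit measures:

* `pMissTissue` (0.028) — nucleus placed outside the epithelial mask,
  absent from the markup;
* `pMissNuclear` (0.234) — within-mask nucleus absent from the markup;
* `rateFalseDetection` (Poisson, 51/spot at the 500-nucleus default) —
  spurious components, uniform in the tissue region, random class;
* `pLabelFlipPos` (0.008) / `pLabelFlipNeg` (0.013) — rendered in the
  wrong class color.

The defaults were fixed once to reproduce the error *composition* a
well-calibrated commercial Ki67 pipeline shows on breast-carcinoma TMA
material — a small tissue-classifier loss, a dominant segmentation loss
near a quarter of nuclei, spurious detections near 10% of true nuclei, and
rare label errors, at a 25% positivity fraction typical of invasive ductal
carcinoma. `simulateCd()` plays a flawless expert (all misses added, all
spurious marks deleted, all labels corrected), so the audit of a synthetic
dD/cD pair must equal the event log *exactly* — the package's central
oracle test, which holds per spot and in aggregate over 100 spots.

What the generator does **not** emulate: stain physics and color variation,
scanner noise, anti-aliased or out-of-focus edges, overlapping and touching
nuclei, non-elliptical profiles, spatial clustering of positivity. Passing
tests therefore demonstrate the correctness of the decoding, counting,
matching and accounting machinery under known truth — not the detection
performance of any real DIA, which is exactly the quantity the audit is
meant to measure on real material.

Because centers sit on integer pixels and ellipse pixel sets are symmetric,
a component centroid rounds back to its center, which is what makes exact
event-log agreement (rather than tolerance-based agreement) achievable.

## Numerical choices and degenerate inputs

* Centroid rounding is half-up (`floor(x+0.5)`), not banker's, so results
  are stable across platforms and XML round trips are lossless.
* Threshold ties go to the positive class; matching ties break by
  (dd index, cd index); both make the pipeline a pure function of its
  inputs.
* `ki67Percent(0, 0)` is `NA` and propagates out of regression and
  Bland–Altman by pairwise deletion with a message.
* Zero variance in the regressor is an error; zero variance in the
  response yields `R² = 0` with a warning.
* Grids reject frames larger than the spacing (overlap) or the image
  (nothing fits); empty grids cannot arise from `generateGrid()` because
  an offset in `[0, spacing)` always leaves room for index 0 unless the
  frame itself does not fit.
* `connected components` are computed on the 8-neighbour pixel graph
  (via igraph) and verified against an independent flood-fill oracle.

## Validation problem sizes

The shipped suite validates at: 100 spots × 500 nuclei (1024 px) for the
end-to-end event-log identity; 200 replicate grids × 500 points for the
sampling-fraction property; 50 randomized grids against the brute-force
double loop; 500 randomized annotation documents for lossless, byte-stable
round trips; 100 random vectors against closed-form regression and
Bland–Altman formulas at 1e-10; and the published 158-spot aggregate
tallies for the effort arithmetic (37.6% edits, 2.8/23.4/10.2/1.0/0.2% per
category, savings 0.624 ≈ two-thirds). These sizes give the oracle checks
power while keeping the full suite under a few minutes on one CPU.

## Known limitations

* One-to-one greedy matching can mis-pair when an expert deletes a mark
  and adds a different nucleus within the tolerance radius; with the 5 px
  default and ≥ 8 px nucleus spacing this cannot occur in synthetic data
  and is rare in practice.
* False-detection attribution to a specific DIA component is not possible
  from coordinates alone; all deletions share one category.
* The audit presumes the corrected file is truth; expert errors are
  invisible to it.
* Ki67% regressions on synthetic series reflect the injected error model,
  not any real DIA's accuracy; the package makes no claim about published
  per-study regression values, which depend on the original images.
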