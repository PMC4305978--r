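# stereoKi67

Image-analysis-assisted stereology for producing and auditing reference
Ki67 annotations on tissue-microarray (TMA) spots.

## The problem

Scoring the Ki67 proliferation index by digital image analysis (DIA) needs
reference data: expert-verified marks on individual tumour nuclei. Marking
hundreds of nuclei per spot by hand is the bottleneck. A practical
alternative is *editing-based* reference production: let the DIA place
initial marks, have an expert correct them, and treat the corrected set as
the criterion standard. The same correction log then doubles as a
per-component accuracy audit of the DIA pipeline — how many nuclei the
tissue classifier lost, how many the nuclear segmentation lost, how many
were invented, and how often the positive/negative call was wrong.

stereoKi67 implements that workflow for users of Ki67 immunohistochemistry
DIA (pathologists and image-analysis developers):

1. **Wizard** — decode the DIA's multicolor *markup mask* into labeled
   point marks (dD, "digital data"): compute the Excess-RGB channels
   (`2R−G−B`, `2G−R−B`, `2B−R−G`), threshold the excess-red (immunostained)
   and excess-blue (counterstained) channels, label 8-connected components,
   and place one mark at each component centroid. Overlay a systematic
   uniform random grid of **unbiased counting frames** (left and bottom
   edges forbidden; a point at `(x, y)` is counted by the frame at
   `(x0, y0, w, h)` iff `x0 < x ≤ x0+w` and `y0 ≤ y < y0+h`) and write both
   to an ImageScope-style annotation XML for expert editing.
2. **Audit** — compare the expert-corrected file (cD) with the machine file
   (dD): greedy nearest-neighbour matching, then per-mark classification
   into true positives/negatives, label corrections, false detections, and
   nuclei undetected by the tissue-mask vs the nuclear-segmentation
   component (attributed by whether the added mark lies inside the
   epithelial mask). Series-level outputs: editing-effort percentages,
   manual-work savings `1 − edits/nuclei`, OLS regression of
   `Ki67%(cD) ~ Ki67%(dD)` with `R² = 1 − SS_res/SS_tot`, and Bland–Altman
   agreement (bias ± 1.96·SD of the differences).
3. **Synth** — a fully logged synthetic spot generator (circular spot,
   irregular epithelial region, non-overlapping elliptical nuclei, markup
   mask rendered under a parametric error model) whose event log is the
   ground truth the audit is validated against.

`Ki67% = 100 · n_positive / (n_positive + n_negative)` over the
grid-counted marks of a spot.

## Worked example

```r
library(stereoKi67)

spot <- generateSpot(nNuclei = 500, trueKi67Pct = 25, imageSize = 1024,
                     errorModel = ErrorModel(seed = 7))
dd <- markupToMarks(spot@markupMask, spotId = "TMA_7_49")
dd
#> MarkSet 'TMA_7_49' (role dD): 428 marks (124 positive, 304 negative, 0 expert-added)

cd   <- simulateCd(spot, dd)                   # perfect-expert correction
grid <- generateGrid(1024, 1024, 150, 150, 300, 300, seed = 7)
grid
#> FrameGrid: 6 frames of 150x150 px, spacing 300x300, offset (297,102), image 1024x1024, seed 7

audit <- auditSpot(dd, cd, grid, spot@tissueMask)
audit
#> SpotAudit 'TMA_7_49': 133 cD nuclei, 39 edits (Ki67% dD 22.4, cD 18.8)
#>             TRUE_POSITIVE             TRUE_NEGATIVE      FALSE_POSITIVE_LABEL
#>                        21                        83                         1
#>      FALSE_NEGATIVE_LABEL           FALSE_DETECTION UNDETECTED_BY_TISSUE_MASK
#>                         1                        10                         1
#>     UNDETECTED_BY_NUCLEAR
#>                        26
```

Reading: of the 133 corrected nuclei the six counting frames reviewed, 104
machine marks were already correct, 2 needed a label flip, 27 nuclei had to
be added (1 lay outside the epithelial mask — a tissue-classifier miss —
and 26 were nuclear-segmentation misses), and 10 spurious machine marks
were deleted. The machine overestimated the spot's Ki67% (22.4 vs 18.8)
because its false detections carry a random label. `summarizeEffort()` over
a list of such audits gives the series totals, per-category percentages and
the savings fraction; `linearRegression()` / `blandAltman()` compare the
Ki67% series.

For file-based batches: `runSynth()` writes fixture bundles,
`runWizard()` turns a markup raster into a `.dd.xml`, and `runAudit()`
audits a directory of `<spot>.dd.xml` / `<spot>.cd.xml` pairs into CSVs,
a JSON summary and plots. The same flows are reachable from a shell via
`inst/scripts/stereoki67 <synth|wizard|audit>`.

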