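---
title: "Grid point-counting of tumor-stroma ratio and stromal TILs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid point-counting of tumor-stroma ratio and stromal TILs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridquant)
```

## The method

Tumor–stroma ratio (TSR) and stromal tumor-infiltrating lymphocytes (sTIL)
are prognostic parameters read from routine H&E sections of invasive breast
carcinoma: TSR at low power (conventionally ×100), sTIL at high power
(conventionally ×400), each over 10 representative fields at the invasive
edge. `gridquant` implements a point-counting estimate of both on
microphotographs that show the bright circular field of view of an eyepiece
camera.

The estimator is a square grid inscribed in the circular field. A square
inscribed in a circle of diameter $d$ has the diameter as its diagonal, so
its side is

$$a = \frac{d}{\sqrt 2},$$

and dividing it $10 \times 10$ gives 100 congruent cells of exactly 1% of
the grid area each — the geometric fact that turns cell counting into
percentages. For the conventionally quoted field diameter of 16.6 (screen
centimetres), $a = 11.738\ldots$; the value is usually quoted as 11.73 (a
truncation — we carry full precision internally and round only for display),
and the small-square side for a quoted 11.7 side is 1.17.

Each cell is labeled by predominance:

* **T** — tumor occupies more than half the cell;
* **S** — tumor stroma occupies more than half the cell;
* **L** (sTIL mode only) — an S cell whose lymphocyte content satisfies the
  lymphocyte rule: lymphocyte occupancy above the predominance threshold
  and/or at least 5 lymphocytes in the cell;
* **NA** — empty space, necrosis, artifact, or no compartment predominant.

From the tallies of one field,

$$\mathrm{TSR} = \frac{n_S}{n_T + n_S}\times 100,
\qquad
\mathrm{sTIL} = \frac{n_L}{n_S}\times 100,$$

where NA squares are excluded from the TSR denominator and T and NA squares
are excluded from the sTIL calculation entirely. **The sTIL denominator
$n_S$ counts all stroma-predominant squares including those labeled L** —
this is forced by the method's second worked example (50 L squares among 100
stroma squares give 50%, not 100%). A case aggregates its fields by
averaging the defined per-field percentages, rounding half-up to a whole
percent, clamping into the reportable range 1–99, and binning into the
four-tier score (0–25 → 1, 26–50 → 2, 51–75 → 3, 76–100 → 4).

Two observers' case scores are compared with percent agreement and
unweighted Cohen's kappa,

$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
p_e = \sum_k m_A(k)\, m_B(k),$$

interpreted on the conventional verbal bands (≤0 no agreement, 0.01–0.20
none to slight, 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80 substantial,
0.81–1.00 almost perfect).

## Design choices

Several points of the procedure are underdetermined; the package resolves
them as follows.

**Tier labels and edges.** The four tiers are emitted as scores 1–4. The
quoted ranges overlap at 75 ("51–75%" and "75–100%"); we resolve the bins on
rounded integer percents as [51, 75] and [76, 100], lower-inclusive, and an
exhaustive test asserts the bins partition 0–100 with no gaps or overlaps.

**Rounding.** Half-up arithmetic rounding (67.76 → 68, 49.5 → 50), not
banker's rounding — matching the rule's "rounded up" reading and its printed
example.

**Aggregation order.** The per-field *percentages* are averaged at full
precision and the case is rounded and scored once. Rounding field values
first would occasionally shift the second decimal of the mean (e.g.
mean(200/3, 50) = 58.33, whereas mean(66.67, 50) = 58.335 → 58.34); the
rounded case percent is unaffected in practice.

**"And/or" in the L rule.** Implemented as OR (occupancy above threshold
*or* ≥5 lymphocytes), the sensitive reading consistent with image-wide
counting conventions; `quant_config(l_rule = "and")` switches to the
conjunctive reading.

**L requires stroma predominance.** sTIL is evaluated in the tumor stroma
only: a lymphocyte-rich but tumor-predominant cell is labeled T, never L,
and in TSR mode L is never emitted.

**Ties.** The predominance threshold is strict (> 0.5); an exact 0.5/0.5
split is inconclusive → NA.

**Undefined fields.** A field whose denominator is zero (e.g. no stroma
square in sTIL mode) yields an undefined percentage; such fields are skipped
from the case mean with a warning rather than counted as 0, and a case with
no defined field is an error.

**Clamping.** Case percents of 0 and 100 are never reported (some empty
space always separates cells); they are clamped to 1 and 99 with a warning.
Raw unclamped values are retained in the report, since legitimate raw field
values of 0% occur.

**Exclusions.** Necrosis, DCIS, mucin, crush artifact and tertiary lymphoid
structures are *not* auto-detected; a per-cell exclusion mask (0-based
row/col pairs) forces NA, mirroring the manual practice.

## Imaging pipeline: assumptions and tunables

All thresholds live in `quant_config()` and are echoed into every report.

* **Field-of-view fit.** Luminance is Otsu-thresholded, the largest bright
  connected component is hole-filled, and a circle is least-squares fitted
  (Kasa's algebraic fit) to its boundary. This assumes the near-binary
  separability of a vignetted eyepiece photo; a Hough transform is not
  needed. A manual `circle = c(cx, cy, d)` override and a `no_vignette`
  mode (largest centered inscribed circle, for full-frame digital fields)
  bypass detection.
* **Stain separation.** Beer–Lambert optical densities are deconvolved with
  the standard published hematoxylin/eosin vectors
  (H = (0.650, 0.704, 0.286), E = (0.072, 0.990, 0.105), normalized);
  mobile-camera white balance varies, so the vectors are config-overridable.
  Pixels with luminance above `white_threshold` (default 0.85) are
  background.
* **Nuclear blobs.** Pixels with hematoxylin concentration above
  `nuclear_threshold` (default 0.30) form blobs; blobs with equivalent
  diameter inside `lymph_diameter` (default 3–9 px) and circularity
  ≥ `lymph_circularity` (default 0.40) are lymphocytes (mononuclear cells —
  plasma cells are not distinguished); larger blobs are tumor nuclei,
  morphologically closed (disc of `tumor_close_size` = 5 px) into nests.
  These sizes are in pixels and assume grid cells of roughly 20–30 px; they
  must be rescaled for other magnifications — there is no pixel-level ground
  truth for "predominantly displaying", so these are engineering defaults,
  flagged as such.
* **Compartments.** Stroma is any stained, non-background, non-tumor pixel
  (lymphocyte nuclei live inside the stroma compartment); cell fractions use
  pixel-center-in-rectangle membership over the half-open cell rectangles,
  so shared edges are never double-counted. Per-cell lymphocyte counts
  assign each detected blob to the unique cell containing its centroid.

## The synthetic generator

`generate_field()` emulates the study material: a bright disk
(default diameter 336 px in a 384 px image) on a dark surround; per cell,
the dominant class paints a centered sub-rectangle covering
`dominant_fraction` (default 0.9) of the cell — tumor as a solid
hematoxylin-dense nest, stroma as sinusoidal eosin fiber texture with 0–2
sparse small nuclei, L cells as stroma plus `lymph_per_cell` (default 8)
well-separated 5 px hematoxylin disks, NA cells left near-white — plus
Gaussian RGB noise (`noise_sd` default 0.01). Colors are synthesized from
the *same* stain vectors the analysis defaults use, and lymphocyte disks are
drawn inside the detector's default diameter band: the generator and the
detector are deliberately coupled through the public defaults, so changing
either makes tests fail loudly rather than silently degrade. All sampling is
seeded through `withr::local_seed()`; outputs are byte-identical under a
fixed seed and no global RNG state leaks.

Default choices worth stating: 10 fields per case (the method's
convention); per-field NA counts of 0–4 and ±3-point jitter of the per-field
percentage around the case target (routine fields contain a few empty or
inconclusive squares and fields vary around the case mean); for sTIL cases a
tumor component of 10–25 squares (fields are selected so stroma is bounded
by tumor); 8 lymphocytes per L cell, safely above the ≥5 rule so generated
cells are clear-cut.

What it does **not** emulate: real nuclear morphology and chromatin texture,
overlapping and touching nuclei, stain variation within a slide, uneven
illumination, vignette blur, focus gradients, necrosis/mucin textures, and
tissue that straddles cell boundaries ambiguously. Passing tests therefore
demonstrate that the geometry, the counting rules and the plumbing are
correct and that the imaging heuristics work on separable material — not
that the default thresholds are clinically adequate on real slides.

`generate_observer_scores()` simulates two raters (B copies A with
probability $q$, else re-samples uniformly from the other categories), which
gives closed forms $p_o = q$ and
$m_B(k) = q\,p_k + (1-q)\frac{1-p_k}{K-1}$ used by `designed_kappa()`;
simulated kappas are tested against this analytic value.

## Numerical and degenerate-input behavior

* Grid invariants ($a/d = 1/\sqrt2$, corners on the circle, area
  conservation, congruent cells) hold to machine precision and are tested
  over 1,000 random diameters.
* Kappa is computed from category proportions; when both raters are constant
  and identical, $p_e = 1$ makes kappa 0/0 — perfect agreement — and 1 is
  returned with a classed warning. A normal-approximation standard error and
  interval are offered as a conventional large-sample extra; no significance
  test is attempted. Weighted (linear/quadratic) kappa is available behind a
  flag but plain unweighted kappa is the default and the reference.
* The kappa gap between 0 and 0.01 in the verbal scale is resolved into
  "none to slight"; band edges are inclusive of their printed endpoints.
* Detection failure (no bright region, or a fitted diameter below
  `min_fov_fraction` of the short image side) is a classed error, as are
  malformed CSVs (with row numbers), infeasible generator specs, and label
  shape mismatches.

## Problem sizes used by the test suite

The suite checks the per-cell label accuracy (≥95%) on 500 cells across 5
default-size fields, kappa–oracle equivalence on 200 random rating pairs,
simulated-rater recovery at 500 cases, and end-to-end recovery of 20
ten-field synthetic cases (case percent within 3 points, tier score exact in
at least 18 of 20) at the generator defaults — sizes chosen to exercise the
pipeline thoroughly while keeping a full run in a few minutes.

## Limitations

* Pixel-unit thresholds tie the imaging defaults to the synthetic scale
  (~24 px cells); real material at other magnifications needs re-tuned
  `lymph_diameter`, `tumor_close_size` and stain vectors.
* The grid is axis-aligned; rotation/perspective correction and whole-slide
  pyramidal formats are out of scope, as are field selection at the invasive
  edge and automatic recognition of exclusion regions.
* Published inter-observer statistics for this method come from paired
  ratings that are not publicly available per case, so the package validates
  its agreement module against analytic and oracle values rather than
  reproducing study-level kappas.
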