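---
title: "The Hepatocyte Likeness Index: model, calibration and screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hepatocyte Likeness Index: model, calibration and screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring model

`hlindex` scores how closely a cell population resembles freshly isolated
adult human hepatocytes, the physiological gold standard for hepatic
identity. Every cell is passed through three acceptance gates, strictly in
order:

1. **nuclear morphology** — nuclear area and nuclear width;
2. **cell morphology** — cell area, cell width and symmetry;
3. **albumin expression** — background-subtracted mean fluorescence
   intensity (MFI) of the albumin stain, thresholded at a calibrated
   cutoff.

A cell passing all three is *hepatocyte positive*; the Hepatocyte Likeness
Index (HLI) of a population is the fraction of positive cells. By
construction, a healthy adult-hepatocyte population scores close to 1, a
non-hepatocyte control (fibroblasts) close to 0, and iPSC-derived
hepatocytes (i-Heps) in between — which makes the HLI a usable read-out
for plate-based screens of extracellular niche factors that push i-Heps
toward the adult phenotype.

Morphological features come from the second-central-moment ellipse of each
segmented mask: *width* is the minor-axis length and *symmetry* the
minor/major axis ratio (bounded in (0, 1], 1 for a circle). Neither
quantity has a single canonical definition in high-content analysis; the
moment ellipse was chosen because it is rotation invariant, robust to
boundary noise, and reproduces the expected orderings (elongated
fibroblasts least symmetric, adult hepatocytes most). Areas are pixel
counts scaled by the squared pixel size and reported in µm².

## Calibrating the reference profile

Morphology gates are robust acceptance intervals fit on the reference
population: median ± 3 MADN per feature (MADN = 1.4826 × MAD, the
normal-consistent robust SD), giving ≈ 99.7% per-feature acceptance for a
Gaussian feature and ≈ 98–99% jointly across the five gated features.

One complication is biological: roughly 30% of adult hepatocyte nuclei are
polyploid, with about twice the mononucleate area, so the reference
nuclear-area and nuclear-width distributions are strongly bimodal. A
single robust interval centred on the dominant mode would reject most
polyploid nuclei — cells that are unambiguously bona fide hepatocytes —
and cap the reference HLI near 0.7 instead of 1. The package therefore
fits *ploidy-aware* nuclear gates: polyploidy is first called on the
reference itself (`call_polyploidy()`, below), median ± 3 MADN intervals
are computed per ploidy class, and the gate is the hull of the two class
intervals. Cell-morphology features are unimodal and use the plain
interval. `ploidy_aware = FALSE` restores single-interval gates.

The albumin cutoff is calibrated by ROC analysis of reference versus
negative-control MFIs (`calibrate_albumin_cutoff()`): the empirical curve
is traced over all distinct observed intensities, the area under it is
computed by the trapezoid rule (numerically identical to the scaled
Mann–Whitney U statistic, which the tests exploit as an oracle), and the
cutoff maximizes Youden's J = TPR − FPR. The "optimum cutoff" is not
otherwise defined in the field's practice; Youden's J is the standard
choice. Ties are broken toward the higher threshold, so under perfect
separation the cutoff lands at the dimmest reference cell — the most
conservative threshold that still accepts the whole reference.

Gate intervals are closed (boundary values pass), a deterministic
tie-break. With `short_circuit = TRUE` (default) a cell is not evaluated
past its first failing stage, so per-stage attrition counts are
interpretable; an all-stages mode is available for coverage analyses.

## Polyploidy calling

Nuclei are called polyploid when their area exceeds 1.5 × the mononucleate
modal area, the midpoint discriminator between the 1× and 2× modes under
the generator's binucleate/tetraploid model. The mode is estimated from
the table's own nuclear-area histogram with Freedman–Diaconis bins, which
the polyploid shoulder does not displace. Area (rather than integrated DNA
intensity or multinucleation counting) is a modelling convention; it is
the simplest observable that an area-doubling model makes fully
identifiable.

## The synthetic data generator

No microscope data ship with the package; a ground-truthed generator
stands in for them. Five presets emulate the populations used to build and
validate the index, encoding the reported qualitative contrasts — the
printed sources give directions, not magnitudes, so the magnitudes below
are generator conventions chosen once for clear separation:

| preset       | cell area (µm²) | aspect      | nuclear area (µm²) | polyploid | albumin (AU) |
|--------------|-----------------|-------------|--------------------|-----------|--------------|
| `adult_hep`  | 1600 ± 300      | 0.85 ± 0.08 | 110 ± 20           | 30%       | 2000 ± 300   |
| `fetal_hep`  | 900 ± 250       | 0.65 ± 0.12 | 80 ± 15            | 3%        | 1200 ± 350   |
| `ihep`       | 1300 ± 500      | 0.85 ± 0.08 | 150 ± 45           | 5%        | 600 ± 400    |
| `fibroblast` | 1500 ± 400      | 0.25 ± 0.08 | 105 ± 20           | 0%        | 120 ± 60     |
| `huvec_gfp`  | 1000 ± 300      | 0.55 ± 0.12 | 95 ± 20            | 0%        | 130 ± 60     |

i-Heps match adult symmetry but have larger, more variable nuclei and
deliberately large variance in cell size and albumin — their albumin
distribution straddles the calibrated cutoff, which is what makes their
baseline HLI low (~0.1) and leaves headroom for niche factors to raise it.
Fibroblast albumin is at background level (the floor of 30 AU models
residual antibody binding and keeps every rendered cell detectable on a
noise-free field). HUVECs carry a nuclear GFP label used by
`exclude_gfp()` in co-culture scenarios. All presets share a nuclear
aspect of 0.90 ± 0.04 and a nuclear-stain intensity of 800 ± 100 AU.
Polyploid nuclei are drawn at exactly twice the mononucleate mean area
with the mononucleate SD.

Cells are non-overlapping ellipses placed by dart throwing (uniform
candidate centres, rejection on overlap, ≤ 1000 retries per cell, border
margin of one semi-major axis), keeping the segmentation ground truth
unambiguous. Each nucleus is placed inside its parent cell with bounded
retries. Rendering paints nuclei into the nuclear-stain channel, whole
cells into the albumin channel and GFP nuclei into the GFP channel over a
uniform 50 AU background, then applies optional Poisson shot noise,
additive Gaussian read noise (default SD 5% of mean foreground), and
integer digitization (a 16-bit camera model, which also makes TIFF round
trips lossless). Defaults are 0.65 µm/pixel and 1024 × 1024 fields,
typical of 10–20× high-content optics. All sampling is driven by the
spec's single seed; identical (spec, seed) give bit-identical images.

What the generator does *not* emulate: optics (no point-spread function,
no vignetting), confluent monolayers (cells never touch), texture within
cells (uniform stains), 3D structure, and any correlation between
morphology and marker expression within a population (features are drawn
independently). Passing tests therefore demonstrate the correctness of
the measurement and decision logic under controlled conditions, not
segmentation performance on dense real tissue.

## Segmentation

Nuclei: Otsu threshold of the offset-log-transformed, lightly smoothed
(σ = 1 px) nuclear channel — the median offset keeps noise-clamped zero
pixels from forming a spurious histogram mode, and a robust floor
(median + 3 MADN of the smoothed image) stops Otsu from splitting the
background cluster when foreground is sparse — then hole filling,
distance-transform watershed
(tolerance 1 px) to split touching nuclei, removal of objects outside
20–600 µm² or touching the border, and renumbering in centroid scan
order. Cells: seeded propagation from the nuclei across the log-Otsu
foreground of the albumin/cytoplasm channel, so each cell contains exactly
one seed and nucleus-free foreground stays background; border-touching
cells are removed with their nuclei (morphometry on clipped cells is
biased).

Thresholding in the log domain matters when per-cell stain intensity
spans orders of magnitude: a linear-domain global threshold drops dimly
stained cells entirely, while in log intensity both dim and bright cells
sit well above background. The residual limitation is cells whose albumin
is essentially at background (possible in the fibroblast preset): their
boundaries are recovered imperfectly, although they are still detected
through their nuclei and counted. This mirrors practice — albumin staining
substitutes for a dedicated cytoplasm stain only in albumin-expressing
cells — and is harmless for the index, because such cells fail the gates
on whichever features are measured.

Background for MFI subtraction is the median intensity outside all cells,
requiring at least 1% background pixels.

## Screen analysis

`score_plate()` computes one HLI per well and aggregates replicate wells
per condition as mean ± SD, excluding wells with fewer than 20 cells
(HLI on tiny denominators is unstable). A condition is a **hit** when its
mean HLI strictly exceeds 0.2 *and* strictly exceeds the collagen-1
control mean (the conjunction prevents a drifted control from inflating
hit counts; a pure absolute rule is available as `rule = "absolute"`).
The threshold applies to the per-condition mean, not individual wells.
`confirm_hits()` keeps a first-round hit only if it satisfies the hit rule
in every second-round screen (e.g. repeats in additional iPSC lines).

Plate-scale simulations (`simulate_screen()`) generate per-well cell
tables directly from ground truth rather than rendering hundreds of
fields: features are computed analytically from the sampled ellipses and
intensities. The test suite cross-checks that image-derived and
truth-derived tables agree, so the fast path measures the same
distributions the imaging path would. Implanted efficacious conditions
draw half their cells from the adult preset, yielding condition means
near 0.5 against a baseline near 0.1 — comfortably separated at the 0.2
line.

## Problem sizes and numerical choices

The packaged analyses use n = 500 cells per population for profile
calibration and HLI endpoints (measured through full rendering and
segmentation, split across ~10–13 fields per population), n = 2000 for
polyploidy recovery (nuclear channel only), and a 58-condition screen
with 3 replicate wells of 120 cells per condition at the feature level.
At these sizes the binomial uncertainty of an HLI is below ±0.03 and the
99% CI of a recovered polyploid fraction is ±2.6 percentage points,
narrow enough for the endpoint checks to be meaningful.

Other conventions: pixel coordinates are (row, column) with pixel centres
at half-integers; degenerate zero-variance features collapse to a
point gate and are flagged in the calibration metadata; an AUC below 0.6
during calibration raises a warning (the negatives do not separate from
the reference); blank or constant images segment to empty label maps
rather than erroring; the feature-importance ranking uses permutation
importance (mean increase in held-out Brier score over ≥10 shuffles)
around a probability random forest — the probability-based loss credits
redundant informative features that a hard-accuracy loss would mask —
scoring a ranking of features without reproducing any proprietary
classifier.

## Known limitations

* Preset magnitudes are conventions; only their orderings are grounded in
  the published characterization. Absolute HLI values on real images
  depend on staining and optics and require recalibration per platform.
* The generator's independence of features within a population means
  gate-attrition correlations in real data (e.g. large dim i-Heps) are
  not represented; the reported i-Hep baseline HLI is a design point, not
  a biological estimate.
* Albumin-negative cells are segmented via their nuclei with approximate
  boundaries; quantitative cytoplasmic MFI for such cells is noisy
  (their classification is not).
* Tissue-section scoring (in-situ HLI) is out of scope; the pipeline
  assumes dissociated, plated cells.
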