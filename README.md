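# hlindex

Image-based scoring of hepatocyte identity for high-content screening.

Hepatocytes differentiated from induced pluripotent stem cells (i-Heps)
remain functionally immature compared with primary cells, and choosing
culture conditions that close this gap requires an objective, scalable
read-out of "how hepatocyte-like" a population is. `hlindex` implements
the **Hepatocyte Likeness Index (HLI)**: every cell in a multi-channel
fluorescence field is segmented, measured, and passed through three
sequential acceptance gates — nuclear morphology, then cell morphology,
then albumin immunofluorescence intensity — calibrated on freshly
isolated adult human hepatocytes, the physiological gold standard. The
index of a population is

```
HLI = (# hepatocyte-positive cells) / (# cells analysed)  ∈ [0, 1]
```

so healthy adult hepatocytes score ≈ 1, fibroblasts ≈ 0, and i-Heps in
between. On top of the per-population score the package provides the
plate-level screen analysis used to find niche factors that mature
i-Heps: per-well HLI, replicate aggregation, hit calling at
`mean HLI > 0.2` *and above the collagen-1 control*, and two-round hit
confirmation.

The package is aimed at quantitative biologists running (or simulating)
high-content screens of stem-cell-derived hepatocytes. Because microscope
data cannot ship with the package, a first-class synthetic generator
produces ground-truthed multi-channel fields for five characterized
populations (adult and fetal hepatocytes, i-Heps, fibroblasts,
GFP-labelled HUVECs) and their mixtures, so the entire pipeline —
segmentation, morphometry, ROC calibration of the albumin cutoff,
gating, screening — is testable end to end.

## The method in brief

* **Segmentation** — nuclei by Otsu thresholding (log intensity, light
  Gaussian smoothing) plus distance-transform watershed; cells by
  nucleus-seeded propagation over the albumin/cytoplasm foreground;
  border-touching objects removed.
* **Morphometry** — per cell: nuclear/cell area (µm²), nuclear/cell
  width (minor axis of the second-moment ellipse), symmetry
  (minor/major axis ratio), background-subtracted mean fluorescence
  intensity (MFI) per channel; nuclear polyploidy called at
  area > 1.5 × the mononucleate modal area.
* **Calibration** — morphology gates are median ± 3 MADN intervals on
  the reference (nuclear gates are ploidy-aware, accepting both the 1×
  and 2× nuclear modes); the albumin cutoff maximizes Youden's J on the
  empirical ROC curve of reference vs negative-control MFIs.
* **Screening** — per-condition mean ± SD over replicate wells; hits
  must exceed both the 0.2 threshold and the control mean; confirmation
  requires reproducing the hit rule in every second-round screen.

## Worked example

```r
library(hlindex)

# calibrate on the gold standard vs fibroblast negatives
ref <- simulate_population_table(
  make_population_spec("adult_hep", n_cells = 500, seed = 11), via = "truth")
neg <- simulate_population_table(
  make_population_spec("fibroblast", n_cells = 500, seed = 12), via = "truth")
profile <- fit_reference_profile(ref, neg)
print(profile)
#> <reference_profile> median +/- 3 MADN, ploidy-aware nuclear gates
#>   nuclear_area  [51.2, 273]
#>   nuclear_width [8.18, 18]
#>   cell_area     [702, 2.49e+03]
#>   cell_width    [28.2, 54.3]
#>   symmetry      [0.616, 1.08]
#>   albumin cutoff 1145 AU (ROC AUC 1.0000; n_ref = 500, n_neg = 500)

# score an i-Hep population against the profile
ihep <- simulate_population_table(
  make_population_spec("ihep", n_cells = 500, seed = 13), via = "truth")
compute_hli(apply_gates(ihep, profile))
#> <hli_result> HLI = 0.088 (44 / 500 positive); attrition nuclear/cell/albumin = 32/75/349

# a 58-condition niche-factor screen with 8 implanted efficacious conditions
sim <- simulate_screen(seed = 7)
score_screen(sim, profile)
#> <screen_result> round1 - round 1 - 177 wells, 59 conditions
#>   control (collagen-1): mean HLI 0.067 +/- 0.008 over 3 wells
#>   hits (> 0.2 ): factor-05, factor-08, factor-12, factor-22, factor-31,
#>                  factor-38, factor-44, factor-56
```

Reading the output: the profile's gates are the acceptance intervals a
cell must satisfy; the albumin cutoff (1145 AU) is the dimmest intensity
that still separates the reference from the negatives. The i-Hep
population scores HLI = 0.088 — only 44 of 500 cells pass all gates,
most failing at the albumin stage (attrition 349), i.e. morphologically
plausible but under-expressing albumin. The screen recovers exactly the
eight implanted efficacious conditions, all of whose per-condition mean
HLIs clear both the 0.2 line and the collagen-1 control (0.067 ± 0.008).

`via = "truth"` computes features analytically from the generated ground
truth (fast path for plate-scale work); `via = "image"` renders
fluorescence fields and runs the full segmentation pipeline — the test
suite verifies both routes agree.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hli", package = "hlindex"))')
Rscript $CLI synth --preset adult_hep --n 50 --seed 7 --out field.tif
Rscript $CLI features field.tif --out cells.csv
```

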