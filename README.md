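# lobulaR

Object-based analysis of brightfield immunohistochemistry (IHC) whole-slide
images: automatic detection of normal mammary gland **lobules** and the
coherent **tumor mass** at low resolution, quantification of ER/PR **nuclear
positivity** per lobule at full resolution, and spatial analysis of
positivity as a function of **distance from the tumor border**.

## The problem

Estrogen/progesterone receptor (ER/PR) status is scored on IHC-stained
breast-cancer sections, where DAB (brown) marks receptor-positive nuclei and
hematoxylin (blue) counterstains negative ones. Conventional scoring ignores
*where* positive cells sit relative to the tumor. This package implements a
two-resolution, object-based workflow that makes the spatial dimension
measurable:

1. **Working view.** The slide (0.56 µm/px at 20×) is downsampled to 10%
   (5.6 µm/px) by nearest-neighbour resampling.
2. **Texture layer.** The key feature is *stddev-n*: per pixel, the RMS
   deviation to its 8 neighbours, computed on the blue channel. Lobules —
   rings of epithelial nuclei around tubule lumens — appear as bright blobs
   (per-segment mean 15–36) against smooth stroma; for segmentation the
   layer is median-filtered (3×3) and Gaussian-smoothed (11×11).
3. **Multiresolution segmentation.** Bottom-up region merging over the
   tissue mask with merge cost
   `sum_c w_c * Δ(area × sd_c) + shape term`, channels (R, G, B, texture)
   weighted (1, 1, 1, 2). One merge tree is cut at thresholds `scale²` for
   scales 100, 80, 60, 40, 20, giving five strictly nested levels.
4. **Lobule classification.** A segment is a lobule candidate iff
   mean stddev-n ∈ [15, 36], area ∈ [2000, 14000] px²
   (0.0627–0.439 mm²), roundness ≤ 1.3, difference of means to the
   surroundings ≥ 5, and border contrast (Michelson) ≥ 0.4. Candidates are
   refined through the hierarchy via sub-segment rules and a final
   adjacent-merge pass.
5. **Tumor detection.** Seeds = non-lobule segments whose mean texture lies
   within ±0.1 of the population median; the mass grows by accretion
   (texture within Δ=2 of the running region mean, shared border ≥ 20% of
   the candidate's border), then holes are closed and components smaller
   than 1/3 of the largest are dropped.
6. **Nuclei at full resolution.** Per lobule, hue-saturation-density (HSD)
   colour deconvolution separates DAB and hematoxylin optical densities;
   nuclear regions (density > 0.2 and dominant) are split by watershed,
   merged nuclei are cut at concave dents > 30°, borders smoothed, and the
   positive fraction `n_pos / (n_pos + n_neg)` computed.
7. **Spatial analysis.** Lobule centroid-to-tumor-border distances are
   binned adjacent (< 0.5 mm) / intermediate (0.5–2 mm) / distant (> 2 mm);
   per-category means and an OLS regression of positivity on distance are
   reported.

Roundness is defined as `(r_enclosing − r_inscribed) / sqrt(area/π)` — 0 for
a perfect disk.

Because clinical WSIs are not distributable, the package ships a calibrated
**synthetic slide generator** (`generate_slide()`) that renders lobules,
stroma, and a tumor mass from a Beer–Lambert stain model with full ground
truth, so the entire pipeline is testable end to end.

## Worked example

```r
library(lobulaR)
slide  <- generate_slide(synth_config(seed = 1))   # 5600 x 10400 px virtual WSI
result <- run_pipeline(slide)                      # ~1.5 min on one CPU
print(result)
```

Output (the generator planted 12 lobules with positive fractions 5/10/15%
by distance band):

```
<pipeline_result>
  status: ok
  lobules: 12
  tumor px: 150660
category       mean pos.  lobules
adjacent            5.0%        4
intermediate       10.0%        4
distant            15.2%        4
  regression: 4.96 %/mm (intercept 3.52%)
```

All 12 planted lobules are recovered, the per-category positivity means
reproduce the planted 5/10/15% gradient, and the regression slope is
positive — positivity rises with distance from the tumor, the spatial trend
the workflow is designed to expose.

Per-lobule measurements live in `result$measurements`:

```
  lobule_id distance_mm     category n_pos n_neg      ratio
1         1   0.2671944     adjacent    45   983 0.04377432
2         2   0.4623154     adjacent    67  1108 0.05702128
...
```

Real images are analysed the same way (`run_pipeline("slide.tif", ...)`);
uncompressed TIFF and PNM are supported, with the pixel size read from the
TIFF resolution tags or given explicitly.

## Command line

```sh
inst/cli/lobular synth  --outdir fixtures --seed 7
inst/cli/lobular run    --image slide.tif --outdir out --pixel-size 0.56
inst/cli/lobular review --measurements out/lobule_measurements.csv \
                        --labels labels.csv --outdir out
inst/cli/lobular report --measurements out/lobule_measurements.csv
```

## Scope notes

Proprietary scanner formats (svs/JPEG2000), stain normalisation, H-score /
Allred intensity scoring, and formal hypothesis testing are out of scope.
See `vignettes/methods.Rmd` for the model, every tunable parameter, the
synthetic world's calibration, and known limitations.
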