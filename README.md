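# stainsight

Quantification of simple (basic-dye) staining of cells imaged on a
magnetically driven, compartmentalized microfluidic chip. Cells are captured
on antibody-coated superparamagnetic beads, pulled through fixation, staining
and washing compartments by external magnets, and inspected in the last
compartment with a bright-field microscope or a phone camera. `stainsight`
implements the image analysis for that readout — and, because no public image
data accompanies this kind of assay, a seedable synthetic image generator
with exact ground truth against which every stage is calibrated and tested.

The package is for researchers building or evaluating low-cost colorimetric
cell-staining readouts who need a reproducible, scriptable analysis of
bright-field images of stained cells, beads and conjugate clusters.

## The statistics at the core

Bright-field chip images show dark objects on a light background (mean
intensity ≈ 225 per 8-bit band). For an object with interior band means
`I_c` and background means `B_c`, the stain signal is the per-band
**difference from background**

    d_c = B_c − I_c ,   c ∈ {R, G, B}

Each object class has a characteristic deficit triple (bundled defaults):
beads (125, 120, 140), unstained cells (15, 15, 30), and cells stained with
trypan blue (50, 40, 40), safranin (25, 135, 100), methylene blue
(100, 100, 45) or crystal violet (100, 115, 30). The *dominant* band — the
dye's own hue — stays brightest (smallest deficit). A two-stage threshold
rule (stage 1: minimum deficit; stage 2: per-band intervals plus nearest
profile in deficit space) classifies each segmented object.

Cell number in a compartment image is estimated by the **area ratio**

    N̂ = (total conjugate area) / (mean single-cell area)

and chip performance by the **transport efficiency** between the first and
last compartments,

    E = 100 × N̂_last / N̂_first ,   loss = 100 − E .

Density classes bin counts as high (> 50,000), medium (30,000–50,000),
low (< 30,000) and ultra-low (< 1,000 by default).

## Worked example

```r
library(stainsight)

## a microscope field with 20 trypan-blue cells and 8 beads, then the
## analysis chain: background -> segmentation -> differences -> classes
sc   <- render_scene(scene_spec(counts = c(TB = 20, bead = 8), seed = 42))
bg   <- estimate_background(sc$image)
objs <- segment_objects(sc$image, bg)
d    <- band_differences(objs, bg)
cls  <- classify_objects(d)
summarize_differences(d, cls)$per_class[, 1:5]
#>   class  n mean_r mean_g mean_b
#> 1  bead  8    125  119.9    140
#> 2    TB 20     50   40.0     40

## a simulated first/last compartment pair (95 -> 77 cells, 19% loss)
rep <- run_pipeline(default_pipeline_config(seed = 42))
rep$compartments$last$report
#> Compartment 'last': 92 regions, conjugate area 5407 px, mean cell area 69.1 px
#>   estimated count 78.3 (density: ultra_low)
rep$efficiency
#> $efficiency_pct
#> [1] 81.24369
```

The class means recover the bundled deficit profiles from noisy pixels; the
area-ratio counter reads ≈ 78 cells in a last compartment truly holding 77,
and the first-to-last efficiency of 81.2% sits just above the 80% transport
performance the chip is expected to keep at ≤ 20% conjugate loss.

## Command line

A thin wrapper over the same functions ships in `inst/cli/stainsight.R`:

```sh
Rscript inst/cli/stainsight.R simulate --seed 3 --out sim/
Rscript inst/cli/stainsight.R segment sim/first.png --out first.csv
Rscript inst/cli/stainsight.R classify first.csv
Rscript inst/cli/stainsight.R quantify --first first.csv --last last.csv
```

Status messages go to stderr; machine-readable JSON/CSV to stdout or files.

## Limitations

The generator draws cells and beads as uniform-deficit disks under Gaussian
noise; it does not model shading, chromatic aberration, focus or
illumination gradients. See the methods vignette
(`vignettes/stainsight-methods.Rmd`) for the model, parameter choices and
what synthetic-data results do and do not establish about real images.
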