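# nucseg

Nucleus instance segmentation for cervical cytology (Pap smear) images,
using contour properties rather than learned models.

In a Pap-smear image every nucleus is a dark, compact, near-elliptical
blob inside brighter cytoplasm — but so, at first glance, are stain
artifacts, neutrophils and overlap shadows. `nucseg` detects nuclei with
a four-stage deterministic pipeline and tells those impostors apart by
shape:

1. **Adaptive thresholding** of the blurred grayscale image (green
   channel for RGB input): pixel *p* is foreground iff
   *I(p) < mean<sub>w×w</sub>(p) − C*;
2. **Kirsch compass-gradient subtraction**: the maximum of eight 3×3
   directional responses is thresholded into an edge map and
   set-subtracted from the mask, erasing ragged noise while only
   shrinking convex nuclei;
3. **Contour filtering** by size, solidity (contour area / convex hull
   area) and inertia ratio (minor / major equivalent-ellipse axis);
4. **Nucleus recovery**: each survivor re-grows by admitting neighbour
   pixels within `Irange` of its running mean intensity, stopping when no
   candidate qualifies, size exceeds `MaxSize`, or solidity drops
   below 0.75.

The package also implements the object-level evaluation protocol
(per-nucleus Dice with a 0.6 true-positive gate, precision / recall / F1,
Aggregated Jaccard Index), a grid-search tuner for the seven tunable
parameters, a seeded synthetic fixture generator, and a four-subcommand
CLI (`inst/scripts/nucseg`: `segment`, `evaluate`, `tune`, `synth`).

Intended users: image-analysis researchers and pipeline builders who need
a transparent, tunable, dependency-light nucleus detector or a reference
implementation of the Dice-gated object-matching / AJI evaluation
protocol.

## Worked example

```r
library(nucseg)

# a synthetic 256x256 cytology scene: dark elliptical nuclei in brighter
# cytoplasm, plus bar/crescent artifacts and speckles; gt labels nuclei
fx <- generateCytology(syntheticSpec(seed = 7))

params <- nucleusParams(wsize = 25, C = 35, Irange = 20,
                        minSolidity = 0.8, minSize = 10, maxSize = 150,
                        minInertia = 0.25)
mask <- segmentImage(fx$image, params)
attr(mask, "stageCounts")
#>          thresholded afterEdgeSubtraction          afterFilter
#>                   12                   24                    6
#>            recovered
#>                    6

evaluateMasks(fx$gt, mask)
#> NucleusEvaluation (1 image)
#>   TP = 5, FP = 1, FN = 0
#>   precision = 0.833  recall = 1.000  F1 = 0.909
#>   AJI = 0.926
```

Reading the numbers: thresholding found 12 connected dark components;
edge subtraction split/trimmed them into 24 candidates; the shape filter
kept 6; recovery produced 6 instances. All 5 ground-truth nuclei were
matched at Dice ≥ 0.6 (recall 1.0) with one false positive
(precision 0.833), and the Aggregated Jaccard Index of 0.926 says the
matched pixel overlap is near-perfect. On a tuned parameter set (below)
the false-positive rate drops further.

Parameters are tuned, not guessed:

```r
train <- lapply(0:9, function(s) generateCytology(syntheticSpec(seed = s)))
gs <- gridSearch(lapply(train, `[[`, "image"), lapply(train, `[[`, "gt"),
                 parameterGrid(wsize = c(25, 35), C = c(35, 45),
                               Irange = c(20, 30), MinSolid = 0.8,
                               MinSize = 10, MaxSize = 150,
                               MinInertia = 0.25),
                 metric = "f1",
                 params = nucleusParams(minSize = 10, maxSize = 150))
gs$params   # the winning combination; gs$results holds the full audit table
```

## Layout

- `R/` — pipeline stages (`preprocess`, `kirsch`, `regions`, `features`,
  `recovery`), evaluation, tuning, synthetic generator, I/O, S4 classes
  (`NucleusParams`, `NucleusEvaluation`).
- `tests/testthat/` — unit, property and oracle-equivalence tests plus
  the end-to-end acceptance suite (`test-acceptance.R`).
- `vignettes/nucseg-methods.Rmd` — the model, parameter semantics, design
  decisions and limitations.
- `inst/scripts/nucseg` — command-line interface.
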