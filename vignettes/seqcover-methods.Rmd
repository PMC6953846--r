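---
title: "Sequential binary land-cover mapping: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential binary land-cover mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeqCover)
options(SeqCover.logLevel = "quiet")
```

## The procedure and its assumptions

SeqCover maps a 10-class legend one class at a time. The pipeline assumes
co-registered, north-up inputs in a single projected CRS at a common pixel
size (30 m by default); reprojection and resampling are out of scope. Pixel
coordinates are 0-based `(row, col)` internally with pixel-center
georeferencing, so a pixel is "inside" a buffer or polygon exactly when its
center is.

**Compositing.** Each scene's QA band is a bit field; any set bit among
{cloud, shadow, fill} removes the pixel from every band. The dialect is
configurable; the default synthetic dialect is bit 0 = cloud, bit 1 =
shadow, bit 2 = fill, and a Landsat-Collection-style mapping can be supplied
in YAML. The composite is the per-band, per-pixel median of the remaining
observations; with an even count we take the mean of the two middle values
(the standard convention, matching common cloud-platform semantics). Pixels
with zero valid observations are *gaps*: they propagate as `NA` through
indices and classification and surface as "unclassified" in the final map
rather than aborting the run, since residual no-data areas are a normal
feature of cloud-prone composites. The thermal-proxy band B10 is composited
identically to the reflectance bands; index formulas that mix it with
reflectance (NDII, NDBaI) are computed exactly as configured on whatever
scale the input provides, so thresholds on those layers are
scaling-dependent — this is documented behaviour, not a defect.

**Masking.** Phase-I rules are strict inequalities (`>`/`<`), exactly as
threshold tables conventionally print them; equality fails the rule. Rules
within a class combine by logical AND, which makes Phase-I output
independent of rule order and monotone: adding a rule can only shrink the
candidate set. `suggestThreshold()` derives a zero-omission rule from
sampled signatures: the comparator points toward the target's side of the
layer distribution and the cut sits just beyond the most extreme target
sample, so 100% of target samples are retained (the design goal is to avoid
omission at the masking stage and let the classifier handle commission).
Phase-II constraints rasterize ancillary geometry on the working grid by
the pixel-center test; area-fraction membership was considered and rejected
as needless complexity at 30 m.

**Classification.** Each class trains a binary random forest (Class vs
Other) with 100 trees and `floor(sqrt(p))` predictors per split. "Other"
training pixels are the non-target training pixels restricted to the
current candidate mask; if fewer than `minTrainPerLabel` (10) remain, the
unrestricted non-target set is used so the binary problem stays well-posed.
Predicted class pixels are verified against knowledge rules (water and
mangroves on slopes above `slopeCapDeg` revert to the pool; slope comes
from Horn's 3×3 method on the native grid), then removed from the pool.
The pool is strictly non-increasing across iterations, and at the end every
non-gap pixel carries exactly one code (a class or unclassified) — both are
asserted in the test suite.

**Class order.** The default order is water → mangroves/wetlands →
artificial surfaces → barren land → ecosystem complex (Liberia) → woody
crops → flooded forests (Gabon, from SAR) → tree-covered dense → open →
mixed vegetation (Liberia) → grasslands. Ordering is itself a modelling
choice and is configurable; mapping the spectrally distinctive and
spatially constrained classes first removes most pixels that would
otherwise confuse the tree-cover iterations, at the price of possible
ordering-dependent commission.

**SAR flooded forests.** Detection requires both elevated HH amplitude and
low-lying terrain (`floodDemCapM`). The season rule is: detected in both
seasons → permanent; detected only in the rainy season → seasonal. A
dry-only detection has no definition under that rule; we treat it as not
flooded — the conservative completion of the truth table — and count it as
an anomaly. When no fixed amplitude threshold is configured the split is an
Otsu between-class-variance maximum computed within the DEM-constrained
region; a constant-amplitude region is a hard error instructing the user to
fix a threshold. On conflicts with already-mapped classes (typically open
water), the earlier class wins, mirroring the sequential classifier's
mask-propagation semantics.

**Accuracy.** The stratified design draws 50 pixels per map class without
replacement (equal weight per class; the optional area-weighted estimators
of good-practice protocols are deliberately out of the default path). The
error matrix is indexed reference × map. Overall accuracy is trace/n;
user's accuracy is the diagonal over the map-column total, producer's over
the reference-row total; the binary-class (Portmanteau) accuracy of a class
is the overall accuracy of the 2-class collapse (class vs rest) — for a
2-class matrix it coincides with overall accuracy, an identity the tests
exploit. Confidence intervals default to Wilson score intervals, which have
better coverage than Wald at stratum sizes near 50; Wald is available for
comparison. A zero marginal makes a statistic undefined (`NA`), never 0.
Stored values are unrounded; printing rounds overall accuracy to the
nearest integer percent and per-class figures to one decimal.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `trees` | 100 | trees | ensemble size of each binary forest |
| `mtry` | √p | predictors | random subset per split |
| `nPerClassValidation` | 50 | pixels | equal-weight stratified design |
| `settlementBufferM` | 2000 | m | **calibration knob**: no canonical radius exists for constraining artificial surfaces around settlement points; 2 km covers town footprints at 30 m without swallowing barren land |
| `shoreBufferM` | 1000 | m | sand/intertidal complex is a shoreline feature |
| `demCapM` | 95 | m | mangrove elevation cap |
| `floodDemCapM` | 60 | m | flood-prone lowland cap for SAR detection |
| `slopeCapDeg` | 10 | degrees | water/wetland verification; flat-terrain knowledge stated qualitatively, the number is ours |
| `minTrainPerLabel` | 10 | pixels | floor below which the binary problem is ill-posed |
| `denomEps` | 1e-10 | — | zero-denominator guard for index formulas |

## What the synthetic generator emulates — and what it does not

`generateLandscape()` lays out all legend classes with geometry consistent
with their semantics: ocean strip and shoreline, a sand/intertidal band and
mangrove patch near shore at low elevation, settlements with
artificial-surface disks, concession polygons containing woody-crop
patches, a river whose low-DEM corridor hosts the Gabon flood strips, and a
dense-forest background. The DEM rises inland at 0.8 m per pixel, keeping
slopes mild everywhere so slope verification is exercised only by the
dedicated cliff fixtures. `generateScenes()` draws per-pixel reflectance as
class mean + seasonal offset + independent Gaussian band noise truncated to
[0, 1] (the simplest model that exercises threshold robustness), paints
clouds as bright random disks with QA cloud bits and paired dark shadow
disks. The default library's class means are chosen so that every default
Phase-I rule holds for its target class and fails for at least one other
class, and so that classes the forest must separate spectrally sit at least
5 noise SDs apart (SD 0.012); classes that are spectrally near-identical on
purpose (woody crops vs natural tree cover, flooded vs dense forest) are
separated by ancillary constraints or SAR, exactly the mechanism the real
workflow relies on.

The generator does **not** emulate: mixed pixels and class gradients,
spatially correlated or non-Gaussian noise, cirrus/haze (QA-driven masking
is what is under test, not cloud detection), topographic shading, SAR
speckle statistics, or temporal land-cover change within the compositing
window. Passing tests therefore demonstrate the correctness of the
pipeline's logic and its behaviour under the stated statistical
assumptions — not classification skill on real imagery, where signatures
overlap and reference labels carry interpretation error.

## Numerical choices and degenerate inputs

Even-count medians average the middle two values; all-masked pixels become
gaps, not errors. Index denominators below `denomEps` in magnitude give
`NA`, not ±Inf. Empty candidate masks skip the class with a warning rather
than failing the run. Training sets missing a label, or below the per-label
floor, are hard errors. An overlap between class rasters (which mask
propagation makes impossible in normal operation) is an invariant breach
and a hard error. File round trips print doubles with 17 significant
digits, so write-then-read is bit-exact.

## Problem sizes

The test suite runs unit fixtures at 2–100 pixels a side and two shared
end-to-end runs at 200 × 200 (the size at which all ten classes fit
comfortably with hundreds of pixels each); the acceptance script uses the
same 200 × 200 scenes with 500 training pixels per class. These sizes give
stable accuracy estimates while keeping a full run in seconds.

## Known limitations

Raster I/O uses ESRI ASCII grids plus a JSON sidecar and vectors use
GeoJSON — standard, GIS-readable text formats chosen over binary
GeoTIFF/Shapefile; CRS strings are compared verbatim, never transformed.
Country-scale rasters would need tiled processing that this desk-scale
implementation deliberately omits. The Gabon profile's forest-extent
Phase-II constraint depends on an ancillary forest-cover layer; the
synthetic stand-in is a whole-grid polygon, so that rule is exercised as
plumbing, not as a discriminating constraint. Threshold defaults for the
two country profiles are encoded as printed constants of the workflow they
reproduce; on other landscapes they are starting points for
`suggestThreshold()`, not universal truths.
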