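---
title: "Segmenting ventilated airspaces in hyperpolarized-gas lung MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting ventilated airspaces in hyperpolarized-gas lung MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliovent)
```

## The problem

Hyperpolarized noble-gas MRI (most commonly ³He) images the spatial
distribution of an inhaled gas bolus: wherever gas reaches, the image is
bright; obstructed regions — *ventilation defects*, the radiological hallmark
of asthma and other obstructive diseases — appear as signal voids. Turning
such images into a number, the **ventilated lung volume** (VLV), requires
three decisions: what counts as background noise, what counts as negligible
ventilation, and how to exclude the trachea and main-stem bronchi, which
carry the densest gas of all but take no part in gas exchange (anatomic dead
space). `heliovent` implements a semiautomatic pipeline making those three
decisions explicitly, stage by stage, plus a synthetic phantom generator so
every stage is testable without clinical data.

Typical acquisitions are coronal multi-slice stacks: 256 × 256 pixels in
plane at ≈1.8 mm resolution, 8–14 slices of 13 mm thickness, acquired at
breath-hold. All coordinates in the package are 1-based `(row, col)` with
row 1 superior, slices ordered anterior → posterior.

## Stage 1: statistical noise subtraction

Background noise in magnitude MR images is Rayleigh distributed, not
Gaussian (a Gaussian assumption underestimates the noise power badly). The
package samples an automated 25 × 50-pixel box at the bottom centre of each
slice — a region outside the lung field — bins the intensities into
unit-width integer bins normalized to a probability mass function $h(f)$,
and fits the three-parameter *adjusted Rayleigh* curve

$$r(f) = \frac{(\alpha f + \delta)\,
        e^{-(\alpha f + \delta)^2 / 2\sigma^2}}{\sigma^2}$$

by least squares (`fit_adjusted_rayleigh()`, Levenberg–Marquardt, initialized
at the histogram mode with $\alpha_0 = 1$, $\delta_0 = 0$). The shift
$\delta$ absorbs horizontal offsets of the empirical curve; $\alpha$ rescales
the intensity axis. The optimal threshold is the integer $\tau$ minimizing

$$\varepsilon_\tau = \sum_{f=0}^{\tau-1} g(f) + \sum_{f=\tau}^{F} r(f),
  \qquad g(f) = r(f) - h(f),$$

with ties broken toward the smallest $\tau$ and the upper sum truncated at
$F$, the larger of the histogram maximum and the point where the cumulative
fitted curve exceeds $1 - 10^{-6}$. Pixels at or above $\tau$ form the
initial binary mask. Fitting, sampling and thresholding are all **per
slice**: every slice has its own box, fit and $\tau$.

Three numerical properties of this stage deserve to be stated plainly,
because they are consequences of the definitions rather than implementation
choices:

* **With $g$ signed (the default), $\varepsilon_\tau$ is monotone
  non-increasing**: $\varepsilon_{\tau+1} - \varepsilon_\tau = -h(\tau) \le
  0$, so the optimum sits one intensity level above the largest sampled
  background value. The threshold therefore adapts to the full extent of the
  observed noise, and the fitted curve matters only through the truncation
  point. A `clamp_g` option (clamping $g$ at zero) is provided but off by
  default; it does not change the argmin.
* **The model family is scale-degenerate**: $r(f;\sigma/c, \alpha/c,
  \delta/c) = c\,r(f;\sigma,\alpha,\delta)$, so a fit to a normalized
  histogram identifies only the ratios $\sigma/\alpha$ and $\delta/\alpha$
  plus the amplitude. At $\alpha = 1, \delta = 0$ the curve is the plain
  Rayleigh density and $\sigma$ itself is identifiable; parameter-recovery
  tests therefore report $\hat\sigma/\hat\alpha$.
* **Shifting every intensity by a constant shifts $\tau$ by the same
  constant** and leaves the mask unchanged.

Degenerate inputs (histograms with fewer than three populated bins) are
rejected; optimizer non-convergence raises an error carrying the last
iterate.

## Stage 2: fuzzy C-means ventilation clustering

The intensities inside the union of the per-slice initial masks are
partitioned into $C = 4$ fuzzy clusters on the 1-D intensity axis with
distances $D_{ik} = |x_k - c_i|$, memberships

$$u_{ik} = \Big[\sum_{j=1}^{C} (D_{ik}/D_{jk})^{2/(m-1)}\Big]^{-1}$$

and centre updates $c_i = \sum_k u_{ik}^m x_k \,/\, \sum_k u_{ik}^m$,
iterated until the largest membership change drops below $\varepsilon =
10^{-5}$ (at most 100 sweeps). These are the classical alternating updates
that minimize the fuzzy within-cluster sum of squares $J_m = \sum_{i,k}
u_{ik}^m D_{ik}^2$; the package records that squared-distance objective per
iteration (it is guaranteed non-increasing) and reports it as the
`objective_trace`. The fuzziness exponent defaults to $m = 2$. A pixel
coinciding with a centre receives a singleton membership, where the formula
is undefined. Initial centres are drawn uniformly from the observed
intensity range under a user seed; collapsed duplicate centres are re-drawn
(at most five times). After convergence the centres are sorted ascending and
named **negligible < low < intermediate < high** ventilation; pixels whose
argmax class is *negligible* are returned to the background
(`refine_mask()`), which is the stage's entire effect on the mask.

Two open design choices were resolved as follows. Clustering runs on the
**masked pixels of the whole volume**, not per slice and not on the whole
image: restricting to the initial mask makes the negligible class a
statement about weakly ventilated lung rather than about background, and
pooling slices gives every class enough support on thin anterior/posterior
slices. A hard **K-means backend** (`backend = "kmeans"`) is selectable;
both algorithms share the same cost function, and on well-separated data the
argmax labels coincide.

## Stage 3: semiautomatic airway removal

For each slice in which the trachea or main-stem bronchi are visible the
user supplies a `seed_spec`: one seed pixel inside the airway lumen and a
bounding box confining the search (JSON sidecar, schema in
`read_seed_specs()`). Airway extraction is then Adams–Bischof seeded region
growing on the grayscale slice: repeatedly admit the frontier pixel with the
smallest deviation $\delta(z) = |g(z) - \mathrm{mean}(A)|$ from the region's
running mean, updating the mean after each admission, until the smallest
deviation exceeds a stopping bound. No stopping rule is inherent to the
method, so the package uses an adaptive default
$\max(0.2\,\mathrm{mean}(A),\ 2\hat\sigma)$ — the airway lumen is nearly
homogeneous in signal, so a generous homogeneity bound relative to the
running mean and the slice's fitted noise scale suffices — with a fixed
`stop_delta` available for full control. Growth is 4-connected
(conservative against diagonal leaks); labelling and area filters are
8-connected; both are configurable. Frontier ties break by `(row, col)`
lexicographic order, making the stage deterministic.

The grown component containing the seed is kept, fragments of fewer than 50
pixels are dropped, and the isolated airway is subtracted from the refined
mask. A templated morphological cleanup then targets weakly connected
residue (the larger airways extending from the main stem): binary erosion by
a disk, connected-component labelling with the same 50-pixel area filter,
and binary dilation by the same disk. Erosion and dilation act only inside a
template box centred at the mask centroid with half-extents $W/4$
horizontally and $H/2$ vertically ($W$, $H$ the mask's maximum width and
height on that slice), which concentrates the morphology near the
mediastinum and spares the concave lung base. Two subtleties:

* The box is rounded to the **enclosed** integer box (a centred 100 × 100
  square yields a 50 × 100 box; a single-pixel mask a 1 × 1 box).
* Dilation is applied to the template-interior content only; dilating the
  spliced raster would let un-eroded out-of-box pixels spill across the box
  edge and break the guarantee that the cleanup never adds pixels beyond the
  input mask.

The disk radius defaults to 2 px (≈3.6 mm at 1.8 mm/pixel); the phantom
fixtures behave identically for radii 1–3. Slices without a seed spec pass
through the cleanup only, so the final mask is always a pixelwise subset of
the refined mask, which is a subset of the initial mask.

Erosion and dilation follow the strict Minkowski definitions
($A \ominus B = \{c \mid B_c \subseteq A\}$, $A \oplus B = \{c = a + b\}$)
with out-of-raster pixels counting as background; the test suite pins this
against a literal set-shift oracle on small rasters.

## Quantification

`compute_vlv()` multiplies the ventilated pixel count by the voxel volume
`in_plane_mm² × (slice_thickness_mm + slice_gap_mm)` (42.12 mm³ at the 1.8 /
13 / 0 defaults). Agreement between two segmentations uses the Dice
coefficient $2|A \cap B| / (|A| + |B|)$ (defined as 1 when both masks are
empty, where the formula is 0/0), Bland–Altman limits of agreement
$\bar d \pm 1.96\,s_d$ with the $n-1$ standard deviation, Pearson
correlation with OLS regression of VLV on the spirometric measure, and
paired/pooled two-sample t tests (a paired test on identical vectors is
reported as degenerate with $p = 1$ by convention). Sample standard
deviations use the $n-1$ denominator throughout. The bundled
`study_spirometry()` / `study_vlv()` tables carry the ten-subject evaluation
cohort from which the package's summary statistics and VLV–spirometry
correlations are recomputed.

One documentation note: the acquisition protocol states 13 mm slices while
the accompanying discussion of the same data mentions 13.13 mm compiled
slices; the package default is 13.0 mm and the value is overridable
everywhere geometry enters.

## What the phantom emulates — and what it does not

`generate_phantom()` builds a coronal stack matching the acquisition
geometry: two ellipsoidal lungs whose cross-section waxes and wanes anterior
→ posterior, four concentric intensity classes inside each lung (high
ventilation at the core, a negligible-ventilation rim), a bright tracheal
tube with bronchial stubs on the middle slices (disjoint from the lungs, as
the mediastinum separates them), optional zero-signal defect pockets, and
background drawn from the adjusted Rayleigh model by inverse transform
$f = \max(0, (\sigma\sqrt{-2\ln U} - \delta)/\alpha)$. Signal regions get
additive Gaussian jitter (the noise model concerns background only);
intensities are clipped at zero. The lung proportions keep the lung base
clear of the bottom-centre sampling box, mirroring the acquisition premise
that the box samples pure background. Everything is bit-reproducible from
the seed.

The presets used by the end-to-end tests fix the study conditions once:

| preset | class levels | noise σ | jitter SD | defects |
|---|---|---|---|---|
| easy | 30, 80, 140, 200 | 5 | 4 | none |
| realistic | 55, 100, 150, 210 | 10 | 7 | 3 of radius 4–6 px |
| hard | 40, 70, 100, 140 | 18 | 12 | 6 of radius 4–6 px |

all at 10 slices of 256², chosen so that *easy* separates the classes
cleanly, *realistic* places the negligible class near the noise threshold
with defects present, and *hard* overlaps classes with the noise floor. The
test suite requires Dice ≥ 0.98 against ground truth on *easy* (with ≥ 99%
of airway pixels removed) and ≥ 0.95 on *realistic*; *hard* must only
complete, and its Dice is reported without a band.

A passing phantom suite shows that the pipeline's stages compose correctly
under the stated noise model and geometry. It does **not** show robustness
to what the phantom lacks: coil-sensitivity bias fields, Rician signal
statistics, partial-volume boundaries at real anatomy, motion, or
between-subject lung-size variation (for which thoracic-cavity
normalization from ¹H scans would be the natural extension, out of scope
here). A Rician-signal option and spatially varying noise are likewise not
modelled.

## Problem sizes and runtime choices

The default test suite runs the full-size (10 × 256²) easy and realistic
fixtures once each in the acceptance tests and smaller 6 × 128² phantoms in
the per-module tests; property batteries use 1250-sample histograms (the
real box size), 20-seed parameter-recovery loops, 50-seed clustering runs on
240-point samples, and 32² rasters for the morphology oracles. These sizes
keep the whole suite under a minute on one CPU while exercising every
code path at the acquisition's native scale at least once.

## Known limitations

* DICOM series ingest is not implemented; convert to NIfTI first.
* The signed error term makes the noise threshold equal to one plus the
  largest sampled background intensity; if signal leaks into the sampling
  box (atypical lung positioning), the threshold becomes aggressive. Inspect
  per-slice `noise_fits` when in doubt.
* Region growing is slice-by-slice 2-D by design; no 3-D airway tree
  extraction.
* The negligible/low class boundary is driven purely by intensity; no
  spatial regularization.
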