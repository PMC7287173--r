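---
title: "Methods: two-stage epidermis and hair-follicle segmentation in skin OCT"
author: "octskinseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage epidermis and hair-follicle segmentation in skin OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octskinseg)
```

# The problem

Optical coherence tomography renders skin as depth-versus-lateral-position
B-scans in which the epidermis appears as a bright band between the skin
surface and the dermo-epidermal junction (DEJ). Hair follicles
(pilosebaceous units) are downward invaginations of the epidermis into the
dermis; delineating them together with the epidermis matters for
quantifying epidermal thickness and for follicle-related disorders such as
folliculitis, acne and basal cell carcinoma. `octskinseg` labels every
pixel of a B-scan with one of three classes — 0 (above the surface),
1 (epidermis together with follicular structures), 2 (dermis) — in two
stages: a convolutional network proposes a labeling, and a
signal-processing chain refines the follicular contours that the network
leaves ragged.

# Stage 1: encoder-decoder network

Each encoder block applies a convolution with 64 rectangular 7 x 3 kernels
and same-size zero padding, batch normalization, ReLU, and 2 x 2 max
pooling whose argmax indices are recorded. Each decoder block unpools with
the matched encoder's indices (doubling resolution and restoring maxima to
their original positions), concatenates the matched encoder's output
feature map, and applies convolution + batch normalization + ReLU. The
head is a 1 x 1 convolution to the three class channels followed by a
per-pixel softmax. The default depth is four blocks; since 526 is not
divisible by 2^4, inputs are padded by bottom/right symmetric reflection
to the next multiple of 2^nBlocks and cropped back after the decoder, so
the output always matches the input size.

Training minimizes the Soft-Dice loss

$$\zeta_{dice} = 1 - \frac{2\sum_{x,l} p_l(x)\, g_l(x)}
{\sum_{x,l} p_l^2(x) + \sum_{x,l} g_l^2(x)},$$

with \(p_l\) the softmax probabilities and \(g_l\) the one-hot ground
truth; the sum runs jointly over pixels and classes (one global ratio; a
per-class-averaged variant sits behind `dicePerClass`). The quantity is 0
at perfect hard overlap and 1 for disjoint hard maps, so it is minimized
as written; two identically-zero maps return 0 by convention. Optimization
is plain SGD with momentum 0.97, batch size 4, initial learning rate
0.001 dropped by one order of magnitude every 20 epochs, 60 epochs, with
`ceiling(n/batch)` iterations per epoch (2,730 training patches give 683).
The checkpoint minimizing validation loss is kept. Weights are
He-initialized from the config seed; the conv biases are retained for
architectural symmetry even though batch normalization cancels them.

Images are first rescaled to a common working dimension, by default
526 x 975 (bilinear for intensities, nearest-neighbor for masks so labels
stay categorical). Training uses non-overlapping full-height patches of
width 75 (13 per image); augmentation applies one random geometric
transform per draw — horizontal flip, integer translation up to 5 px,
rotation up to 10 degrees — identically to patch and mask with
nearest-neighbor sampling. Inference splits a full image into two
526 x 512 slices (offsets 0 and width - 512); how the 49 overlapping
columns are merged is unspecified upstream, and this package averages the
probability maps there, which keeps them normalized.

Evaluation is patient-wise: K external folds (one per patient), and
within each external fold an internal leave-one-fold-out validation,
giving K(K-1) models; the test patient's probability map is the arithmetic
mean of its K-1 models' maps, then an argmax with ties broken toward the
lowest class index. For K = 2 a strict internal leave-one-out would leave
an empty training set, so the single remaining patient both trains and
validates that fold's model — a documented degenerate case used only in
smoke-scale runs.

# Stage 2: signal-processing refinement

Per column, the surface is the shallowest class-1 row and the DEJ the
deepest; columns without class-1 pixels are filled by linear
interpolation (nearest value at the edges). The DEJ baseline is a
Savitzky-Golay fit of order d = 1 with a 449-sample window — each output
sample is the value, at that sample's position, of the least-squares line
over its window. The first and last M = 224 samples use the shifted rows
of the projection matrix \(B = S(S^TS)^{-1}S^T\), i.e. the fit of the
first/last full window evaluated at the boundary positions; this is the
reading of the transient formulas that reproduces polynomials of degree
<= d exactly everywhere, and it coincides with `signal::sgolayfilt`. For
masks narrower than 449 columns the window shrinks to the largest odd
length that fits.

The raw baseline tracks the mean of flat DEJ plus invaginations, so it is
corrected by a scalar shift. Read in height-up coordinates the correction
subtracts `max(s_dej) - max(bl)`; in row coordinates this aligns the
shallowest baseline point with the shallowest DEJ point
(`blc = bl - (min(bl) - min(s_dej))`), placing the baseline against the
non-follicular DEJ so the full invaginations fall below it. The literal
row-coordinate reading of the same formula would instead shift the
baseline toward the deepest invagination; it is kept behind
`baselineMode = "literal_rows"` but is not the default, because it
contradicts the purpose of the correction. Since the corrected baseline
still passes a few pixels above the flat DEJ in the immediate
neighborhood of an invagination, the outermost 1-2 px tails of a smooth
follicle shoulder may remain above it; consequences for thickness
measurement are sub-pixel and noted below.

Candidate follicles are the 8-connected components of class-1 pixels
strictly below the corrected baseline. Area opening removes components
smaller than `alpha = 0.3 * max(A_c)` — a relative threshold, so a single
component always survives and an all-equal set is untouched; it is
idempotent and never adds components. Each surviving component's boundary
is traced along pixel edges (so an 8-pixel-wide square block has
perimeter exactly 32) and resampled to N points equispaced in arc length,
N the smallest power of two at or above the raw vertex count; at pinch
vertices of diagonally-touching pixels the tracer prefers the left turn,
keeping one loop per component. The contour enters the complex plane as
`s[n] = x[n] + i y[n]`, its DFT gives the Fourier descriptors, and the
smoothed contour is the inverse DFT over the retained low-frequency bins:
k = 0 first, then pairs (k, N-k) by increasing k until P bins are kept
(for even P the last pair keeps only its lower k). The default is a fixed
P = 4; a frequency-cutoff mode derives `P = max(1, round(fc * N))` per
contour instead. The printed reconstruction formula upstream runs its
exponent over P while dividing by N; this package implements the standard
truncated inverse DFT (exponent over N), which is exact at P = N and is a
projection (idempotent). Note the two upstream P-fixing statements are
mutually inconsistent (`fc * N` with N around 57 gives 0.4, not 4); the
fixed P = 4 follows the final stated choice. Smoothed contours are
rasterized by even-odd point-in-polygon on pixel centers, and the final
class-1 region is the union of the class-1 pixels at or above the
corrected baseline with the filled contours; class 0 above the surface,
class 2 elsewhere.

# Evaluation suite

Dice `2|A∩B|/(|A|+|B|)` and Jaccard `|A∩B|/|A∪B|` are computed per layer
on the binary masks, with the both-empty case defined as 1 (vacuous
agreement); they satisfy J = D/(2-D). Follicle counting runs the full
baseline chain and counts surviving components; the relative success rate
is `RSR = 1 - |F_GT - F_P| / F_GT` (undefined and rejected at F_GT = 0).
Epidermal thickness is the mean of `dej - surface` (boundary-to-boundary
row difference) over valid columns not intersecting any surviving
follicle component, scaled by the axial pixel pitch; no pitch is stated
for the study device, so the package requires it as configuration and
defaults to 1.0, reporting pixel units. RMSE and MAE compare per-image
thickness series and are aggregated per patient over that patient's
images, with unweighted means across patients at cohort level. Values are
rounded only at rendering, never in computation.

# The phantom generator

Real training data are not required for any test: `generatePhantom()`
builds a B-scan with exact ground truth — a dark air/gel region above a
bright entrance surface at mean row 120, an epidermis band, Gaussian
invaginations of the DEJ (one per follicle, centers kept at least
4 half-widths apart by construction), exponential attenuation with depth
below the surface, and multiplicative gamma speckle of unit mean. Chosen
once as the study conditions: working dimension 526 x 975; declared axial
pitch 1.0 um/px, so the default 75 px epidermis sits mid-range of the
healthy-cheek thicknesses (49-92 um) the method targets; follicle depth
40 px with half-width (sigma) 18 px; attenuation 0.004/px; speckle
relative sd 0.3 (fully developed speckle smoothed by scanner
post-processing); surface undulation 2 px at ~150 px wavelength.
`generateCohort()` jitters per-patient thickness (±15%), follicle count
(±1) and depth (±10%) deterministically from one seed, mirroring a
several-subject study with a fixed number of B-scans per subject.

The phantom emulates layer geometry, speckle statistics and attenuation,
not wave-optical image formation: no shadowing under hairs, no refraction
at the gel interface, no sebaceous-gland substructure, and layer
brightness is piecewise constant. Passing phantom tests therefore
demonstrates the correctness of the pipeline's mechanics — geometry
recovery, counting, thickness — not clinical-grade accuracy on real
scans, which depends on training the full 72-model ensemble on real data.
One structural consequence worth knowing: with a wavy surface and zero
follicles, the relative area opening always keeps the largest wavy
residual below the baseline, so a count of exactly 0 is only guaranteed
on flat-surface phantoms; the end-to-end count-recovery tests accordingly
use noise-free flat-surface phantoms (the construction-guaranteed
regime), while the noisy, wavy defaults exercise the network path.

# Numerical choices and problem sizes

Tolerances: probability maps must sum to 1 within 1e-5; the SG filter is
held to 1e-8 relative agreement with explicit per-window least squares;
Fourier round trips to 1e-9. Ties: argmax prefers the lowest class;
max pooling prefers the first position in (top-left, bottom-left,
top-right, bottom-right) order. Degenerate inputs are rejected with the
violated constraint named (empty masks, non-divisible patch widths,
coverage gaps, F_GT = 0). All randomness flows from explicit integer
seeds; sub-seeds are derived with fixed multipliers below 2^31.

The shipped tests run the architecture at reduced width where the full
recipe is not the point: unit and smoke tests use 64 x 96 phantoms,
2 blocks and 6-8 filters, 2-10 epochs — sizes chosen so the whole suite
documents behavior in well under a minute of training while exercising
every code path (padding, pooling parity, ensembling, the full
post-processing chain); the geometry-sensitive acceptance checks
(counting, thickness, SG, Fourier) run at the full 526 x 975 working
dimension. Training the full 9-patient, 72-model ensemble at 64 filters
is supported by the same code path via `runPipeline()` but is a
compute-scale undertaking, and the headline real-data scores (epidermis
Dice ~0.83 after refinement) are expectations for that setting, not
something the phantom suite asserts.

# Known limitations

Single 2-D B-scans only (no C-scan continuity across frames); no shadow
or dispersion compensation preprocessing; the follicle region is bounded
above by the corrected baseline (columns where a follicle's faint
shoulder stays above it are attributed to the epidermis); per-patient
follicle counts aggregate per-image counts, so a follicle visible in
several B-scans counts once per B-scan; and the network is trained from
scratch per fold — no transfer learning.
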