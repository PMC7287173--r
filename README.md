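# octskinseg

Segmentation of the epidermis together with hair-follicle (pilosebaceous)
structures in cross-sectional optical coherence tomography (OCT) B-scans
of skin, with the full evaluation suite and a synthetic phantom generator.

OCT shows skin as depth-versus-lateral-position images in which the
epidermis is the band between the skin surface and the dermo-epidermal
junction (DEJ); hair follicles are downward invaginations of that band
into the dermis. Delineating both at once supports epidermal-thickness
quantification and the monitoring of follicle-related disorders
(folliculitis, acne, lupus erythematosus, basal cell carcinoma). The
package is for image-analysis researchers and OCT methodologists who need
a fully automatic, reproducible 3-class labeling (upper bound /
epidermis+follicles / dermis) plus its metrics.

## Method

**Stage 1 — encoder-decoder network.** Blocks of conv(64 kernels, 7x3,
zero padding) → batch norm → ReLU → 2x2 max pool with recorded pooling
indices; decoder blocks unpool with the matched indices, concatenate the
matched encoder features, and convolve again; a 1x1 convolution and
softmax give per-pixel class probabilities. Training minimizes the
Soft-Dice loss

    zeta = 1 - 2 * sum_xl p_l(x) g_l(x) / (sum_xl p_l(x)^2 + sum_xl g_l(x)^2)

with SGD (momentum 0.97, batch 4, lr 0.001 dropped tenfold every 20
epochs, 60 epochs), on 526x75 patches under patient-wise external K-fold
cross-validation with internal leave-one-fold-out validation (K(K-1)
models). Test images are predicted as two overlapping 526x512 slices,
ensemble-averaged over the K-1 fold models, then argmaxed.

**Stage 2 — refinement.** The per-column DEJ signal s_dej(x) is smoothed
by a Savitzky-Golay filter (order d = 1, window 449, exact least-squares
transients) to a baseline bl(x), corrected by the scalar shift that
aligns its shallowest point with the shallowest DEJ point. Epidermis
pixels below the corrected baseline form 8-connected candidate follicles;
an area opening with alpha = 0.3 * max(A_c) removes spurious components;
each surviving contour is resampled to N (power of two) equispaced
points, transformed to Fourier descriptors S[k] = sum_n s[n] e^(-i2πkn/N),
truncated to the P = 4 lowest-frequency descriptors, and reconstructed as
a smooth closed contour. The final mask unions the upper epidermis with
the filled smoothed follicles.

**Evaluation.** Per-layer Dice and Jaccard; follicle counts with the
relative success rate RSR = 1 - |F_GT - F_P| / F_GT; epidermal thickness
(mean surface-to-DEJ distance over non-follicular columns, in µm); RMSE
and MAE of thickness; per-patient and cohort aggregation.

A phantom module generates OCT-like B-scans (layered geometry, Gaussian
follicular invaginations, depth attenuation, multiplicative gamma
speckle) with exact ground truth, so every stage is testable without the
original dataset.

## Worked example

```r
library(octskinseg)

spec <- PhantomSpec(nFollicles = 3L, seed = 42L)   # 526 x 975 B-scan phantom
ph <- generatePhantom(spec)
ph$mask
#> LabelMask 526x975; pixels per class 0/1/2: 116110/79526/317214

res <- postprocessMask(ph$mask)    # baseline chain + Fourier smoothing
length(res$follicles)
#> [1] 3
openingThreshold(res$follicles)    # alpha = 0.3 * max component area
#> [1] 311.4
epidermalThickness(res$profile, res$follicles, axialPixelUm = 1.0)
#> [1] 75.63
rsr(3, length(res$follicles))
#> [1] 1
diceCoefficient(ph$mask, res$mask, layer = 1L)
#> [1] 0.9937
```

The three planted invaginations are recovered (RSR 1.00); the thickness
estimate (75.63 px·µm) sits within a pixel of the phantom's 75 px
epidermis once the follicle columns are excluded; and refining an
already-smooth mask changes under 1% of its epidermis pixels
(Dice 0.9937).

Training end to end (simulate → folds → train → ensemble predict →
postprocess → evaluate) runs through one config:

```r
cfg <- defaultRunConfig()
cfg$outDir <- "run"; cfg$seed <- 1L
runPipeline(cfg)     # writes masks, logs, metric CSVs, cohort JSON
```

A thin command-line wrapper with `simulate` / `train` / `postprocess` /
`evaluate` / `run-all` subcommands is installed at
`inst/cli/octskinseg.R`.

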