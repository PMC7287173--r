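#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' OCTImage: a single B-scan
#'
#' A 2-D intensity raster of a skin OCT B-scan. Rows index depth with row 1
#' the shallowest position; columns index lateral position. Intensities are
#' real-valued in \[0, 1\] after normalization.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot axialPixelUm positive axial pixel pitch in micrometres per pixel,
#'   or `NA_real_` when unknown.
#' @slot sourceId character identifier of the image origin.
#'
#' @seealso [OCTImage()], [LabelMask-class]
#' @export
setClass("OCTImage",
  representation(pixels = "matrix", axialPixelUm = "numeric",
                 sourceId = "character"))

setValidity("OCTImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  if (length(dim(object@pixels)) != 2L) return("pixels must be a matrix")
  if (any(!is.finite(object@pixels))) return("pixels must be finite")
  if (length(object@axialPixelUm) != 1L)
    return("axialPixelUm must be a single value")
  if (!is.na(object@axialPixelUm) && object@axialPixelUm <= 0)
    return("axialPixelUm must be positive")
  TRUE
})

#' Construct an OCTImage
#'
#' @param pixels numeric matrix, rows = depth (row 1 shallowest),
#'   columns = lateral position.
#' @param axialPixelUm axial pixel pitch (micrometres per pixel); `NA` when
#'   unknown, in which case depth measures are reported in pixel units.
#' @param sourceId identifier carried through the pipeline.
#' @return An [OCTImage-class] object.
#' @examples
#' img <- OCTImage(matrix(runif(50), 10, 5))
#' dim(pixels(img))
#' @export
OCTImage <- function(pixels, axialPixelUm = NA_real_, sourceId = "") {
  new("OCTImage", pixels = pixels, axialPixelUm = as.numeric(axialPixelUm),
      sourceId = sourceId)
}

#' LabelMask: per-pixel class map
#'
#' Integer raster over the three tissue classes: 0 = upper bound (above the
#' skin surface), 1 = epidermis together with follicular structures,
#' 2 = dermis.
#'
#' @slot labels integer matrix with values in \{0, 1, 2\}.
#' @export
setClass("LabelMask", representation(labels = "matrix"))

setValidity("LabelMask", function(object) {
  l <- object@labels
  if (length(dim(l)) != 2L) return("labels must be a matrix")
  if (!all(l %in% 0:2)) return("labels must take values in {0, 1, 2}")
  TRUE
})

#' Construct a LabelMask
#'
#' @param labels matrix with values in \{0, 1, 2\}.
#' @return A [LabelMask-class] object.
#' @export
LabelMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMask", labels = labels)
}

#' ProbabilityMap: per-pixel class probabilities
#'
#' A rows x cols x classes array; each pixel's class vector is non-negative
#' and sums to one (tolerance 1e-5).
#'
#' @slot probs 3-D numeric array.
#' @export
setClass("ProbabilityMap", representation(probs = "array"))

setValidity("ProbabilityMap", function(object) {
  p <- object@probs
  if (length(dim(p)) != 3L) return("probs must be a 3-D array")
  if (any(p < -1e-8)) return("probabilities must be non-negative")
  s <- rowSums(matrix(p, ncol = dim(p)[3L]))
  if (any(abs(s - 1) > 1e-5))
    return("per-pixel class probabilities must sum to 1 (tol 1e-5)")
  TRUE
})

#' Construct a ProbabilityMap
#' @param probs rows x cols x classes array of per-pixel probabilities.
#' @return A [ProbabilityMap-class] object.
#' @export
ProbabilityMap <- function(probs) new("ProbabilityMap", probs = probs)

#' BoundaryProfile: per-column boundary depth signals
#'
#' Holds, for each image column, the skin-surface row, the dermo-epidermal
#' junction (DEJ) row, the Savitzky-Golay baseline of the DEJ, and the
#' corrected baseline. Rows are depth coordinates (row 1 shallowest), so
#' `surface <= dej` wherever the epidermis class is present.
#'
#' @slot surface numeric vector, per-column surface row.
#' @slot dej numeric vector, per-column DEJ row.
#' @slot bl numeric vector or NULL, Savitzky-Golay baseline.
#' @slot blc numeric vector or NULL, corrected baseline.
#' @slot valid logical vector, TRUE for columns where the epidermis class
#'   was actually observed (others are filled by interpolation).
#' @export
setClass("BoundaryProfile",
  representation(surface = "numeric", dej = "numeric",
                 bl = "numericOrNULL", blc = "numericOrNULL",
                 valid = "logical"))

setValidity("BoundaryProfile", function(object) {
  n <- length(object@surface)
  if (length(object@dej) != n || length(object@valid) != n)
    return("surface, dej and valid must have equal length")
  if (any(object@valid & object@surface > object@dej))
    return("surface must be at or above dej on valid columns")
  for (s in c("bl", "blc")) {
    v <- slot(object, s)
    if (!is.null(v) && length(v) != n)
      return(sprintf("%s must have one value per column", s))
  }
  TRUE
})

#' Construct a BoundaryProfile
#' @param surface,dej per-column boundary rows.
#' @param valid logical flags for columns with observed epidermis pixels.
#' @param bl,blc optional baseline and corrected baseline.
#' @return A [BoundaryProfile-class] object.
#' @export
BoundaryProfile <- function(surface, dej, valid = rep(TRUE, length(surface)),
                            bl = NULL, blc = NULL) {
  new("BoundaryProfile", surface = as.numeric(surface), dej = as.numeric(dej),
      bl = bl, blc = blc, valid = valid)
}

#' FollicleSet: detected follicular components
#'
#' Connected components of epidermis-class pixels lying below the corrected
#' DEJ baseline, together with their traced contours, Fourier descriptors
#' and smoothed contours as they move through the refinement stages.
#'
#' Each element of `components` is a list with elements `pixels` (two-column
#' matrix of row/col coordinates), `area`, and optionally `contour` (complex
#' closed contour, x + iy with x = column, y = row), `descriptors` (its DFT),
#' `smoothed` (truncated-descriptor reconstruction) and `retainedP`.
#'
#' @slot components list of per-component records.
#' @slot alpha numeric area-opening threshold actually applied (0 when the
#'   set is empty or opening has not run).
#' @slot fc numeric frequency cutoff used for descriptor truncation
#'   (`NA` in fixed-P mode).
#' @export
setClass("FollicleSet",
  representation(components = "list", alpha = "numeric", fc = "numeric"))

setValidity("FollicleSet", function(object) {
  ok <- vapply(object@components, function(co) {
    is.list(co) && !is.null(co$pixels) && !is.null(co$area)
  }, logical(1))
  if (length(ok) && !all(ok))
    return("each component needs at least pixels and area")
  TRUE
})

#' Construct a FollicleSet
#' @param components list of component records (see [FollicleSet-class]).
#' @param alpha applied area-opening threshold.
#' @param fc frequency cutoff used in descriptor truncation, `NA` if unused.
#' @return A [FollicleSet-class] object.
#' @export
FollicleSet <- function(components = list(), alpha = 0, fc = NA_real_) {
  new("FollicleSet", components = components, alpha = alpha, fc = fc)
}

#' PhantomSpec: parameters of a synthetic B-scan
#'
#' Describes the layered geometry and noise of a synthetic OCT-like B-scan:
#' a dark air/gel region above a bright entrance surface, an epidermis band,
#' Gaussian-shaped follicular invaginations of the DEJ into the dermis,
#' depth-dependent attenuation and multiplicative speckle.
#'
#' @slot heightPx,widthPx image dimensions in pixels.
#' @slot axialPixelUm axial pixel pitch (micrometres per pixel).
#' @slot surfaceDepthPx mean row of the skin surface.
#' @slot epidermisThicknessPx epidermis band thickness in pixels.
#' @slot nFollicles number of follicular invaginations.
#' @slot follicleDepthPx invagination depth below the DEJ in pixels.
#' @slot follicleHalfwidthPx Gaussian half-width (sigma) of each follicle.
#' @slot speckleLevel relative standard deviation of the multiplicative
#'   gamma speckle (0 disables noise).
#' @slot attenuationPerPx attenuation coefficient per pixel of depth below
#'   the surface.
#' @slot surfaceWavinessAmpPx amplitude of the sinusoidal surface
#'   undulation (0 gives a flat surface).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(heightPx = "integer", widthPx = "integer",
                 axialPixelUm = "numeric", surfaceDepthPx = "numeric",
                 epidermisThicknessPx = "numeric", nFollicles = "integer",
                 follicleDepthPx = "numeric", follicleHalfwidthPx = "numeric",
                 speckleLevel = "numeric", attenuationPerPx = "numeric",
                 surfaceWavinessAmpPx = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  pos <- c(heightPx = object@heightPx, widthPx = object@widthPx,
           axialPixelUm = object@axialPixelUm,
           surfaceDepthPx = object@surfaceDepthPx,
           epidermisThicknessPx = object@epidermisThicknessPx,
           follicleDepthPx = object@follicleDepthPx,
           follicleHalfwidthPx = object@follicleHalfwidthPx)
  bad <- names(pos)[pos <= 0]
  if (length(bad))
    return(sprintf("field(s) %s must be positive", paste(bad, collapse = ", ")))
  nonneg <- c(nFollicles = object@nFollicles, speckleLevel = object@speckleLevel,
              attenuationPerPx = object@attenuationPerPx,
              surfaceWavinessAmpPx = object@surfaceWavinessAmpPx)
  bad <- names(nonneg)[nonneg < 0]
  if (length(bad))
    return(sprintf("field(s) %s must be non-negative", paste(bad, collapse = ", ")))
  if (object@surfaceDepthPx + object@epidermisThicknessPx +
      object@follicleDepthPx >= object@heightPx)
    return(paste("invariant violated: surfaceDepthPx + epidermisThicknessPx +",
                 "follicleDepthPx must be < heightPx"))
  if (object@nFollicles > 0) {
    need <- object@nFollicles * 4 * object@follicleHalfwidthPx +
      4 * object@follicleHalfwidthPx
    if (need > object@widthPx)
      return(paste("invariant violated: follicle centers cannot keep a",
                   "4 * follicleHalfwidthPx separation within widthPx"))
  }
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate a cheek B-scan at the common working dimension
#' 526 x 975: surface near row 120, an epidermis band of 75 px (75 um at
#' the declared 1 um/px axial pitch, mid-range of healthy cheek epidermal
#' thickness), three follicles invaginating 40 px below the DEJ, mild
#' surface undulation, depth attenuation and fully developed speckle.
#'
#' @param heightPx,widthPx image dimensions (pixels).
#' @param axialPixelUm axial pixel pitch in micrometres per pixel.
#' @param surfaceDepthPx mean surface row.
#' @param epidermisThicknessPx epidermis thickness (pixels).
#' @param nFollicles number of follicular invaginations.
#' @param follicleDepthPx invagination depth below the DEJ (pixels).
#' @param follicleHalfwidthPx Gaussian sigma of each invagination (pixels).
#' @param speckleLevel relative sd of multiplicative speckle; 0 = noise-free.
#' @param attenuationPerPx attenuation per pixel of depth below the surface.
#' @param surfaceWavinessAmpPx amplitude of the surface undulation (pixels).
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(nFollicles = 2L, seed = 7L)
#' @export
PhantomSpec <- function(heightPx = 526L, widthPx = 975L, axialPixelUm = 1.0,
                        surfaceDepthPx = 120, epidermisThicknessPx = 75,
                        nFollicles = 3L, follicleDepthPx = 40,
                        follicleHalfwidthPx = 18, speckleLevel = 0.3,
                        attenuationPerPx = 0.004, surfaceWavinessAmpPx = 2,
                        seed = 1L) {
  new("PhantomSpec", heightPx = as.integer(heightPx),
      widthPx = as.integer(widthPx), axialPixelUm = axialPixelUm,
      surfaceDepthPx = surfaceDepthPx,
      epidermisThicknessPx = epidermisThicknessPx,
      nFollicles = as.integer(nFollicles), follicleDepthPx = follicleDepthPx,
      follicleHalfwidthPx = follicleHalfwidthPx, speckleLevel = speckleLevel,
      attenuationPerPx = attenuationPerPx,
      surfaceWavinessAmpPx = surfaceWavinessAmpPx, seed = as.integer(seed))
}

#' NetworkConfig: architecture and optimization settings
#'
#' @slot nClasses number of output classes (3).
#' @slot nBlocks encoder (= decoder) depth.
#' @slot kernelShape conv kernel rows x cols, both odd.
#' @slot filtersPerConv feature maps per convolution.
#' @slot batchSize minibatch size.
#' @slot momentum SGD momentum.
#' @slot initialLr initial learning rate.
#' @slot lrDropFactor multiplicative factor applied to the learning rate.
#' @slot lrDropEveryEpochs epochs between learning-rate drops.
#' @slot epochs training epochs.
#' @slot augment logical, apply random geometric augmentation in training.
#' @slot dicePerClass logical, average the Soft-Dice ratio per class rather
#'   than forming one global ratio.
#' @slot seed integer RNG seed for initialization and shuffling.
#' @export
setClass("NetworkConfig",
  representation(nClasses = "integer", nBlocks = "integer",
                 kernelShape = "integer", filtersPerConv = "integer",
                 batchSize = "integer", momentum = "numeric",
                 initialLr = "numeric", lrDropFactor = "numeric",
                 lrDropEveryEpochs = "integer", epochs = "integer",
                 augment = "logical", dicePerClass = "logical",
                 seed = "integer"))

setValidity("NetworkConfig", function(object) {
  if (length(object@kernelShape) != 2L || any(object@kernelShape %% 2L == 0L))
    return("kernelShape must be two odd integers (same-size zero padding)")
  if (object@nBlocks < 1L) return("nBlocks must be >= 1")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@batchSize < 1L || object@epochs < 0L)
    return("batchSize must be >= 1 and epochs >= 0")
  TRUE
})

#' Construct a NetworkConfig
#'
#' Defaults are the reference training recipe: 64 rectangular 7 x 3 kernels
#' with same-size zero padding, batch size 4, SGD with momentum 0.97,
#' initial learning rate 0.001 dropped by one order of magnitude every 20
#' epochs, 60 epochs, Soft-Dice loss as a single global ratio.
#'
#' @param nClasses,nBlocks,kernelShape,filtersPerConv,batchSize,momentum,initialLr,lrDropFactor,lrDropEveryEpochs,epochs,augment,dicePerClass,seed
#'   see [NetworkConfig-class].
#' @return A [NetworkConfig-class] object.
#' @export
NetworkConfig <- function(nClasses = 3L, nBlocks = 4L, kernelShape = c(7L, 3L),
                          filtersPerConv = 64L, batchSize = 4L,
                          momentum = 0.97, initialLr = 0.001,
                          lrDropFactor = 0.1, lrDropEveryEpochs = 20L,
                          epochs = 60L, augment = TRUE, dicePerClass = FALSE,
                          seed = 1L) {
  new("NetworkConfig", nClasses = as.integer(nClasses),
      nBlocks = as.integer(nBlocks), kernelShape = as.integer(kernelShape),
      filtersPerConv = as.integer(filtersPerConv),
      batchSize = as.integer(batchSize), momentum = momentum,
      initialLr = initialLr, lrDropFactor = lrDropFactor,
      lrDropEveryEpochs = as.integer(lrDropEveryEpochs),
      epochs = as.integer(epochs), augment = augment,
      dicePerClass = dicePerClass, seed = as.integer(seed))
}

#' ModelState: a (possibly trained) network
#'
#' @slot params list of layer parameters (conv weights/biases, batch-norm
#'   scale/shift and running statistics) for encoder, decoder and head.
#' @slot config the [NetworkConfig-class] used to build the network.
#' @slot history data.frame with one row per epoch
#'   (epoch, trainLoss, valLoss, lr); zero rows for an untrained network.
#' @slot bestEpoch epoch whose checkpoint is stored in `params`
#'   (the epoch minimizing validation loss); 0 if untrained.
#' @export
setClass("ModelState",
  representation(params = "list", config = "NetworkConfig",
                 history = "data.frame", bestEpoch = "integer"))

setValidity("ModelState", function(object) {
  h <- object@history
  if (nrow(h) > 0) {
    if (!all(c("epoch", "trainLoss", "valLoss", "lr") %in% names(h)))
      return("history needs columns epoch, trainLoss, valLoss, lr")
    if (object@bestEpoch > 0 &&
        abs(h$valLoss[object@bestEpoch] - min(h$valLoss)) > 1e-12)
      return("selected checkpoint must minimize validation loss")
  }
  TRUE
})

#' FoldPlan: patient-wise external/internal cross-validation plan
#'
#' For K patients: K external folds, each holding one patient out for
#' testing; within each external fold, K-1 models are trained, each using a
#' different remaining patient as the internal validation fold.
#'
#' @slot patients character vector of patient ids (the K folds).
#' @slot assignments list over external folds; each element is a list with
#'   `test` (patient id) and `models` (list of lists with `val` and `train`
#'   patient ids).
#' @export
setClass("FoldPlan",
  representation(patients = "character", assignments = "list"))

setValidity("FoldPlan", function(object) {
  K <- length(object@patients)
  if (length(object@assignments) != K)
    return("one external fold per patient is required")
  for (a in object@assignments) {
    if (length(a$models) != K - 1L)
      return("each external fold needs K-1 internal (train, val) models")
    for (m in a$models) {
      if (a$test %in% c(m$train, m$val))
        return("test patient must not appear in train or validation")
    }
  }
  TRUE
})

#' OCTCohort: a set of B-scans addressable by patient
#'
#' @slot records list of per-image records, each with `patientId`,
#'   `image` ([OCTImage-class]), `mask` ([LabelMask-class]) and optionally
#'   `profile` ([BoundaryProfile-class] ground truth).
#' @export
setClass("OCTCohort", representation(records = "list"))

setValidity("OCTCohort", function(object) {
  ok <- vapply(object@records, function(r)
    !is.null(r$patientId) && !is.null(r$image), logical(1))
  if (length(ok) && !all(ok)) return("each record needs patientId and image")
  TRUE
})

#' Construct an OCTCohort
#' @param records list of records (see [OCTCohort-class]).
#' @return An [OCTCohort-class] object.
#' @export
OCTCohort <- function(records = list()) new("OCTCohort", records = records)
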