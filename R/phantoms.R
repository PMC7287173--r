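# Synthetic OCT-like B-scans with exact ground truth.
#
# The phantom emulates the structure of a cheek B-scan: a dark air/gel
# region above a bright entrance surface, an epidermis band, Gaussian
# follicular invaginations of the DEJ into the dermis, exponential depth
# attenuation below the surface and multiplicative gamma speckle.

# deterministic sub-seed derivation; stays below 2^31
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

# lateral follicle centers with guaranteed >= 4*halfwidth separation:
# evenly spaced slots with bounded deterministic jitter
.follicleCenters <- function(width, n, halfwidth) {
  if (n == 0L) return(numeric(0))
  margin <- 2 * halfwidth
  usable <- width - 2 * margin
  slot <- usable / n
  jitter <- max(0, (slot - 4 * halfwidth) / 2)
  centers <- margin + slot * (seq_len(n) - 0.5) +
    stats::runif(n, -jitter, jitter)
  sort(centers)
}

#' Generate a synthetic B-scan with ground truth
#'
#' Builds an OCT-like image, its exact 3-class label mask and the true
#' per-column boundary profile from a [PhantomSpec-class]. The surface is a
#' (possibly wavy) smooth curve, the DEJ is the surface shifted by the
#' epidermis thickness plus one Gaussian-shaped downward bump per follicle,
#' and the epidermis class is exactly the band between the two curves.
#' Intensity is piecewise layer brightness, attenuated exponentially with
#' depth below the surface, times multiplicative gamma speckle with unit
#' mean, drawn with the spec's seed (bit-identical on repeated calls).
#'
#' @param spec a valid [PhantomSpec-class].
#' @return A list with elements `image` ([OCTImage-class]),
#'   `mask` ([LabelMask-class]) and `profile` ([BoundaryProfile-class], the
#'   true surface and DEJ rows per column).
#' @examples
#' ph <- generatePhantom(PhantomSpec(heightPx = 120L, widthPx = 150L,
#'   surfaceDepthPx = 25, epidermisThicknessPx = 30, nFollicles = 1L,
#'   follicleDepthPx = 20, follicleHalfwidthPx = 10))
#' ph$mask
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  h <- spec@heightPx; w <- spec@widthPx
  set.seed(spec@seed)

  x <- seq_len(w)
  # surface undulation: sinusoid with ~150 px wavelength and random phase
  if (spec@surfaceWavinessAmpPx > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    wav <- spec@surfaceWavinessAmpPx * sin(2 * pi * x / 150 + phase)
  } else wav <- numeric(w)
  surface <- spec@surfaceDepthPx + wav

  bump <- numeric(w)
  centers <- .follicleCenters(w, spec@nFollicles, spec@follicleHalfwidthPx)
  for (cx in centers)
    bump <- bump + spec@follicleDepthPx *
      exp(-(x - cx)^2 / (2 * spec@follicleHalfwidthPx^2))
  dej <- surface + spec@epidermisThicknessPx + bump

  surfRow <- pmax(1, pmin(h, round(surface)))
  dejRow <- pmax(1, pmin(h, round(dej)))

  rows <- matrix(seq_len(h), h, w)
  surfM <- matrix(surfRow, h, w, byrow = TRUE)
  dejM <- matrix(dejRow, h, w, byrow = TRUE)
  lab <- matrix(2L, h, w)
  lab[rows < surfM] <- 0L
  lab[rows >= surfM & rows <= dejM] <- 1L

  bright <- c(0.05, 0.85, 0.55)  # air/gel, epidermis, dermis
  img <- matrix(bright[lab + 1L], h, w)
  depthBelow <- pmax(0, rows - surfM)
  img <- img * exp(-spec@attenuationPerPx * depthBelow)
  if (spec@speckleLevel > 0) {
    shape <- 1 / spec@speckleLevel^2
    img <- img * matrix(stats::rgamma(h * w, shape = shape, rate = shape), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  list(image = OCTImage(img, axialPixelUm = spec@axialPixelUm,
                        sourceId = sprintf("phantom-seed%d", spec@seed)),
       mask = LabelMask(lab),
       profile = BoundaryProfile(surface = as.numeric(surfRow),
                                 dej = as.numeric(dejRow)))
}

#' Generate a multi-patient phantom cohort
#'
#' Emulates a study layout of several subjects contributing a fixed number
#' of B-scans each. Per-patient anatomy (epidermis thickness, follicle
#' count and depth) is jittered deterministically from the seed, and every
#' image of a patient gets a fresh speckle/waviness realization.
#'
#' @param nPatients number of patients (>= 2 so cross-validation folds
#'   exist).
#' @param imagesPerPatient B-scans per patient.
#' @param baseSpec [PhantomSpec-class] whose fields are the cohort means.
#' @param seed integer seed controlling all jitter.
#' @return An [OCTCohort-class]; records carry `patientId` of the form
#'   `"P01"`, the image, mask and true boundary profile.
#' @examples
#' co <- generateCohort(2L, 1L, PhantomSpec(heightPx = 100L, widthPx = 150L,
#'   surfaceDepthPx = 20, epidermisThicknessPx = 25, nFollicles = 1L,
#'   follicleDepthPx = 15, follicleHalfwidthPx = 9))
#' length(co)
#' @export
generateCohort <- function(nPatients, imagesPerPatient, baseSpec = PhantomSpec(),
                           seed = 1L) {
  if (nPatients < 2L)
    stop("nPatients must be >= 2 so that patient-wise folds exist")
  records <- list()
  for (p in seq_len(nPatients)) {
    set.seed(.deriveSeed(seed, p))
    thick <- baseSpec@epidermisThicknessPx * stats::runif(1, 0.85, 1.15)
    nf <- max(0L, baseSpec@nFollicles + sample(c(-1L, 0L, 1L), 1))
    fd <- baseSpec@follicleDepthPx * stats::runif(1, 0.9, 1.1)
    pid <- sprintf("P%02d", p)
    for (i in seq_len(imagesPerPatient)) {
      spec <- PhantomSpec(heightPx = baseSpec@heightPx,
                          widthPx = baseSpec@widthPx,
                          axialPixelUm = baseSpec@axialPixelUm,
                          surfaceDepthPx = baseSpec@surfaceDepthPx,
                          epidermisThicknessPx = thick,
                          nFollicles = nf, follicleDepthPx = fd,
                          follicleHalfwidthPx = baseSpec@follicleHalfwidthPx,
                          speckleLevel = baseSpec@speckleLevel,
                          attenuationPerPx = baseSpec@attenuationPerPx,
                          surfaceWavinessAmpPx = baseSpec@surfaceWavinessAmpPx,
                          seed = .deriveSeed(seed, p * 1000L + i))
      ph <- generatePhantom(spec)
      ph$image@sourceId <- sprintf("%s-img%02d", pid, i)
      records[[length(records) + 1L]] <-
        list(patientId = pid, image = ph$image, mask = ph$mask,
             profile = ph$profile)
    }
  }
  OCTCohort(records)
}

#' Write a cohort to disk
#'
#' Images are written as 16-bit grayscale TIFF (or 8-bit PNG), masks as
#' single-channel 8-bit PNG with raw values \{0, 1, 2\}, plus a manifest CSV
#' with columns `patient_id`, `image_path`, `mask_path`.
#'
#' @param cohort an [OCTCohort-class].
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"` for the intensity images.
#' @return Invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohortRecords(cohort)
  manifest <- data.frame(patient_id = character(0), image_path = character(0),
                         mask_path = character(0))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    stem <- sprintf("%s_%03d", r$patientId, k)
    ipath <- file.path(dir, paste0(stem, if (format == "tiff") ".tif" else ".png"))
    mpath <- file.path(dir, paste0(stem, "_mask.png"))
    writeOCTImage(r$image, ipath)
    writeLabelMask(r$mask, mpath)
    manifest[nrow(manifest) + 1L, ] <- c(r$patientId, ipath, mpath)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest
#'
#' @param manifestPath path to a manifest CSV as written by [writeCohort()]
#'   (columns `patient_id`, `image_path`, `mask_path`).
#' @param axialPixelUm axial pixel pitch to attach to the images.
#' @return An [OCTCohort-class].
#' @export
readCohort <- function(manifestPath, axialPixelUm = NA_real_) {
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  base <- dirname(manifestPath)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  records <- lapply(seq_len(nrow(man)), function(k) {
    list(patientId = man$patient_id[k],
         image = readOCTImage(resolve(man$image_path[k]),
                              axialPixelUm = axialPixelUm,
                              sourceId = basename(man$image_path[k])),
         mask = readLabelMask(resolve(man$mask_path[k])))
  })
  OCTCohort(records)
}
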