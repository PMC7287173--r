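# Image input/output, rescaling to the common working dimension, patch
# extraction for training and slice split/recombination for tiled inference.

#' Read a grayscale B-scan from PNG or TIFF
#'
#' @param path image file (.png, .tif/.tiff). Multi-channel input is
#'   averaged to one channel; intensities are returned in \[0, 1\].
#' @param axialPixelUm axial pixel pitch to attach (micrometres/pixel).
#' @param sourceId identifier; defaults to the file name.
#' @return An [OCTImage-class].
#' @export
readOCTImage <- function(path, axialPixelUm = NA_real_,
                         sourceId = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  OCTImage(a, axialPixelUm = axialPixelUm, sourceId = sourceId)
}

#' Write a B-scan as PNG or TIFF
#'
#' Intensities are clipped to \[0, 1\] and stored as 8-bit grayscale PNG or
#' 16-bit grayscale TIFF depending on the file extension.
#'
#' @param image an [OCTImage-class].
#' @param path destination path (.png, .tif/.tiff).
#' @return Invisibly, `path`.
#' @export
writeOCTImage <- function(image, path) {
  m <- pmin(pmax(pixels(image), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a 3-class label mask from a single-channel PNG
#'
#' Masks are stored with raw 8-bit values \{0, 1, 2\} (appearing black when
#' viewed); values are recovered exactly.
#'
#' @param path PNG file.
#' @return A [LabelMask-class].
#' @export
readLabelMask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  LabelMask(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)))
}

#' Write a 3-class label mask as a single-channel PNG
#'
#' @param mask a [LabelMask-class].
#' @param path destination PNG path.
#' @return Invisibly, `path`.
#' @export
writeLabelMask <- function(mask, path) {
  png::writePNG(labels2d(mask) / 255, path)
  invisible(path)
}

#' Rescale an image (and optionally its mask) to the common dimension
#'
#' All B-scans of a study are brought to one working dimension (the
#' dataset-wide minimum, by default 526 x 975) before training. Intensities
#' are resampled bilinearly; masks use nearest-neighbor resampling so that
#' labels remain categorical and no new label can appear.
#'
#' @param image an [OCTImage-class].
#' @param mask an optional [LabelMask-class] paired with the image.
#' @param target integer vector `c(rows, cols)`.
#' @return A list with `image` and (if given) `mask`, both at `target`
#'   size. Inputs already at `target` are returned unchanged.
#' @examples
#' img <- OCTImage(matrix(runif(601 * 90), 601, 90))
#' out <- rescaleToCommon(img, target = c(526, 90))
#' dim(pixels(out$image))
#' @export
rescaleToCommon <- function(image, mask = NULL, target = c(526L, 975L)) {
  stopifnot(length(target) == 2L, all(target > 0))
  m <- pixels(image)
  if (length(m) == 0L) stop("empty image cannot be rescaled")
  if (all(dim(m) == target)) {
    return(list(image = image, mask = mask))
  }
  # EBImage indexes the first array dimension as x; bilinear resampling is
  # separable, so feeding rows as x is safe.
  im <- EBImage::resize(EBImage::as.Image(m), w = target[1], h = target[2],
                        filter = "bilinear")
  outImg <- OCTImage(pmin(pmax(as.matrix(EBImage::imageData(im)), 0), 1),
                     axialPixelUm = axialPixelUm(image) * nrow(m) / target[1],
                     sourceId = sourceId(image))
  outMask <- NULL
  if (!is.null(mask)) {
    lm <- EBImage::resize(EBImage::as.Image(labels2d(mask) + 0),
                          w = target[1], h = target[2], filter = "none")
    outMask <- LabelMask(matrix(as.integer(round(EBImage::imageData(lm))),
                                target[1], target[2]))
  }
  list(image = outImg, mask = outMask)
}

#' Extract non-overlapping full-height training patches
#'
#' Tiles the image left to right into patches of the full image height and
#' a fixed width (by default 975 / 13 = 75 columns), pairing each image
#' patch with its mask patch.
#'
#' @param image an [OCTImage-class].
#' @param mask a [LabelMask-class] of the same size.
#' @param patchWidth patch width in columns; must divide the image width.
#' @return Ordered list of `list(image =, mask =)` patch pairs, one per
#'   tile, left to right.
#' @export
extractPatches <- function(image, mask, patchWidth = 75L) {
  m <- pixels(image); l <- labels2d(mask)
  stopifnot(all(dim(m) == dim(l)))
  w <- ncol(m)
  if (w %% patchWidth != 0L)
    stop(sprintf("image width %d is not divisible by patch width %d (residue %d)",
                 w, patchWidth, w %% patchWidth))
  n <- w %/% patchWidth
  lapply(seq_len(n), function(k) {
    cols <- ((k - 1L) * patchWidth + 1L):(k * patchWidth)
    list(image = OCTImage(m[, cols, drop = FALSE],
                          axialPixelUm = axialPixelUm(image),
                          sourceId = sprintf("%s#%02d", sourceId(image), k)),
         mask = LabelMask(l[, cols, drop = FALSE]))
  })
}

#' Split an image into two overlapping slices for inference
#'
#' Full images are predicted as two fixed-width slices: columns
#' `[1, sliceWidth]` and `[width - sliceWidth + 1, width]`. When the image
#' width equals the slice width a single slice at offset 0 is returned.
#'
#' @param image an [OCTImage-class].
#' @param sliceWidth slice width; the image width must lie in
#'   `[sliceWidth, 2 * sliceWidth]`.
#' @return List of `list(image =, offset =)` with 0-based column offsets.
#' @examples
#' img <- OCTImage(matrix(runif(20 * 975), 20, 975))
#' s <- splitForInference(img, 512L)
#' vapply(s, `[[`, integer(1), "offset")  # 0 and 463
#' @export
splitForInference <- function(image, sliceWidth = 512L) {
  m <- pixels(image)
  w <- ncol(m)
  if (w < sliceWidth)
    stop(sprintf("image width %d smaller than slice width %d", w, sliceWidth))
  if (w > 2L * sliceWidth)
    stop(sprintf("image width %d exceeds 2 x slice width %d; two slices cannot cover it",
                 w, 2L * sliceWidth))
  mk <- function(off) list(
    image = OCTImage(m[, (off + 1L):(off + sliceWidth), drop = FALSE],
                     axialPixelUm = axialPixelUm(image),
                     sourceId = sprintf("%s@%d", sourceId(image), off)),
    offset = as.integer(off))
  if (w == sliceWidth) return(list(mk(0L)))
  list(mk(0L), mk(w - sliceWidth))
}

#' Recombine per-slice probability maps into a full-width map
#'
#' Columns covered by more than one slice receive the arithmetic mean of
#' the contributing probability maps, so per-pixel class probabilities
#' still sum to one.
#'
#' @param sliceMaps list of `list(probs =, offset =)` where `probs` is a
#'   [ProbabilityMap-class] (or raw array) and `offset` the 0-based column
#'   offset from [splitForInference()].
#' @param fullWidth width of the recombined map.
#' @return A [ProbabilityMap-class] of the full width.
#' @export
recombineSlices <- function(sliceMaps, fullWidth) {
  stopifnot(length(sliceMaps) >= 1L)
  first <- sliceMaps[[1L]]$probs
  p1 <- if (is(first, "ProbabilityMap")) probs(first) else first
  h <- dim(p1)[1L]; nc <- dim(p1)[3L]
  acc <- array(0, c(h, fullWidth, nc))
  cnt <- matrix(0, h, fullWidth)
  for (sm in sliceMaps) {
    p <- if (is(sm$probs, "ProbabilityMap")) probs(sm$probs) else sm$probs
    cols <- (sm$offset + 1L):(sm$offset + dim(p)[2L])
    if (max(cols) > fullWidth)
      stop("slice extends beyond fullWidth")
    acc[, cols, ] <- acc[, cols, ] + p
    cnt[, cols] <- cnt[, cols] + 1
  }
  if (any(cnt == 0)) {
    gap <- range(which(colSums(cnt) == 0))
    stop(sprintf("coverage gap: columns %d-%d are not covered by any slice",
                 gap[1], gap[2]))
  }
  for (l in seq_len(nc)) acc[, , l] <- acc[, , l] / cnt
  ProbabilityMap(acc)
}
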