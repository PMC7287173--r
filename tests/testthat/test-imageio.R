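test_that("rescaling reaches the common working dimension and keeps labels categorical", {
  set.seed(1)
  img <- OCTImage(matrix(runif(601 * 975), 601, 975), axialPixelUm = 1)
  l <- matrix(2L, 601, 975); l[1:100, ] <- 0L; l[101:200, ] <- 1L
  out <- rescaleToCommon(img, LabelMask(l), target = c(526L, 975L))
  expect_identical(dim(pixels(out$image)), c(526L, 975L))
  expect_identical(dim(labels2d(out$mask)), c(526L, 975L))
  expect_true(all(labels2d(out$mask) %in% 0:2))
  # axial pitch rescales with the depth axis
  expect_equal(axialPixelUm(out$image), 601 / 526)

  # identity case: returned unchanged
  sm <- OCTImage(matrix(runif(40 * 30), 40, 30))
  idl <- LabelMask(matrix(0L, 40, 30))
  same <- rescaleToCommon(sm, idl, target = c(40L, 30L))
  expect_identical(pixels(same$image), pixels(sm))
  expect_identical(labels2d(same$mask), labels2d(idl))

  # nearest-neighbor cannot invent labels
  l2 <- matrix(sample(c(0L, 2L), 50 * 60, TRUE), 50, 60)
  out2 <- rescaleToCommon(OCTImage(matrix(runif(50 * 60), 50, 60)),
                          LabelMask(l2), target = c(30L, 45L))
  expect_true(all(labels2d(out2$mask) %in% c(0L, 2L)))
})

test_that("patch extraction tiles the image exactly and validates widths", {
  set.seed(2)
  img <- OCTImage(matrix(runif(60 * 975), 60, 975))
  mask <- LabelMask(matrix(sample(0:2, 60 * 975, TRUE), 60, 975))
  patches <- extractPatches(img, mask, patchWidth = 75L)
  expect_length(patches, 13L)
  expect_identical(dim(pixels(patches[[1]]$image)), c(60L, 75L))
  # lateral concatenation reconstructs the originals exactly
  expect_identical(do.call(cbind, lapply(patches, function(p) pixels(p$image))),
                   pixels(img))
  expect_identical(do.call(cbind, lapply(patches, function(p) labels2d(p$mask))),
                   labels2d(mask))
  # full-width patch is the input
  one <- extractPatches(img, mask, patchWidth = 975L)
  expect_length(one, 1L)
  expect_identical(pixels(one[[1]]$image), pixels(img))
  expect_error(extractPatches(img, mask, patchWidth = 74L), "residue")
})

test_that("inference splitting yields the stated offsets and overlap", {
  img <- OCTImage(matrix(runif(20 * 975), 20, 975))
  s <- splitForInference(img, sliceWidth = 512L)
  expect_length(s, 2L)
  expect_identical(vapply(s, `[[`, integer(1), "offset"), c(0L, 463L))
  expect_identical(ncol(pixels(s[[1]]$image)), 512L)
  # overlap = 512 - 463 = 49 columns
  expect_identical(512L - 463L, 49L)

  # disjoint halves at width exactly 2 x sliceWidth
  img2 <- OCTImage(matrix(runif(10 * 64), 10, 64))
  s2 <- splitForInference(img2, 32L)
  expect_identical(vapply(s2, `[[`, integer(1), "offset"), c(0L, 32L))
  # degenerate width == sliceWidth: one slice at offset 0
  s3 <- splitForInference(img2, 64L)
  expect_length(s3, 1L)
  expect_identical(s3[[1]]$offset, 0L)
  expect_error(splitForInference(img2, 20L), "exceeds")
})

test_that("slice recombination averages overlaps and round-trips", {
  h <- 6L; w <- 10L
  mk <- function(v) {
    p <- array(0, c(h, 7L, 3L)); p[, , 1] <- v[1]; p[, , 2] <- v[2]
    p[, , 3] <- v[3]; p
  }
  out <- recombineSlices(list(list(probs = mk(c(1, 0, 0)), offset = 0L),
                              list(probs = mk(c(0, 1, 0)), offset = 3L)), w)
  p <- probs(out)
  expect_equal(p[1, 5, ], c(0.5, 0.5, 0))   # overlap column: mean
  expect_equal(p[1, 1, ], c(1, 0, 0))
  expect_equal(p[1, 10, ], c(0, 1, 0))
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-12))

  # split -> recombine of a column-constant map restores it
  set.seed(3)
  base <- matrix(runif(3 * w), 3L, w)  # one class-profile per column
  base <- sweep(base, 2, colSums(base), "/")
  full <- array(0, c(h, w, 3L))
  for (l in 1:3) full[, , l] <- matrix(base[l, ], h, w, byrow = TRUE)
  img <- OCTImage(matrix(0, h, w))
  sl <- splitForInference(img, 7L)
  maps <- lapply(sl, function(s)
    list(probs = full[, (s$offset + 1L):(s$offset + 7L), , drop = FALSE],
         offset = s$offset))
  expect_equal(probs(recombineSlices(maps, w)), full)

  expect_error(recombineSlices(list(list(probs = mk(c(1, 0, 0)), offset = 0L)),
                               10L), "gap")
})

test_that("images and masks survive PNG round trips", {
  dir <- withr::local_tempdir()
  set.seed(4)
  img <- OCTImage(matrix(runif(30 * 40), 30, 40))
  p <- file.path(dir, "img.png")
  writeOCTImage(img, p)
  back <- readOCTImage(p)
  expect_lt(max(abs(pixels(back) - pixels(img))), 1 / 254)
  mask <- LabelMask(matrix(sample(0:2, 30 * 40, TRUE), 30, 40))
  mp <- file.path(dir, "mask.png")
  writeLabelMask(mask, mp)
  expect_identical(labels2d(readLabelMask(mp)), labels2d(mask))
})
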