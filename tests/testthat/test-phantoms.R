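test_that("phantom generation is deterministic and well-formed", {
  spec <- tinyPhantomSpec(nFollicles = 2L, speckleLevel = 0.3, seed = 11L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(labels2d(a$mask), labels2d(b$mask))

  l <- labels2d(a$mask)
  expect_true(all(l %in% 0:2))
  expect_identical(dim(l), dim(pixels(a$image)))
  expect_true(all(pixels(a$image) >= 0 & pixels(a$image) <= 1))

  # epidermis class vertically contiguous per column: one surface crossing,
  # one DEJ crossing
  for (cc in seq_len(ncol(l))) {
    r <- which(l[, cc] == 1L)
    expect_true(length(r) > 0 && all(diff(r) == 1L))
    expect_true(all(l[seq_len(r[1] - 1L), cc] == 0L))
    if (r[length(r)] < nrow(l))
      expect_true(all(l[(r[length(r)] + 1L):nrow(l), cc] == 2L))
  }
})

test_that("true boundary profile matches the mask and the flat-layer ET is exact", {
  spec <- tinyPhantomSpec(nFollicles = 0L, speckleLevel = 0,
                          surfaceWavinessAmpPx = 0)
  ph <- generatePhantom(spec)
  prof <- extractBoundaries(ph$mask)
  expect_equal(surfaceRow(prof), surfaceRow(ph$profile))
  expect_equal(dejRow(prof), dejRow(ph$profile))
  # flat noise-free band: identical thickness in every column, exact ET
  expect_equal(length(unique(dejRow(prof) - surfaceRow(prof))), 1L)
  expect_equal(epidermalThickness(prof, axialPixelUm = spec@axialPixelUm),
               16 * spec@axialPixelUm)
})

test_that("follicle construction is recovered by the counting chain", {
  ph <- generatePhantom(PhantomSpec(nFollicles = 3L, seed = 21L))
  expect_identical(countFollicles(ph$mask), 3L)
  # noise-free: construction guarantees the count for separated follicles
  ph0 <- generatePhantom(tinyPhantomSpec(nFollicles = 0L, speckleLevel = 0,
                                         surfaceWavinessAmpPx = 0))
  expect_identical(countFollicles(ph0$mask, window = 95L), 0L)
})

test_that("below-baseline area grows with follicle depth", {
  areaOf <- function(depth) {
    ph <- generatePhantom(PhantomSpec(nFollicles = 2L, follicleDepthPx = depth,
                                      speckleLevel = 0,
                                      surfaceWavinessAmpPx = 0, seed = 4L))
    prof <- correctBaseline(computeBaseline(extractBoundaries(ph$mask)))
    sum(follicleAreas(detectFollicles(ph$mask, prof)))
  }
  a <- vapply(c(25, 40, 55), areaOf, numeric(1))
  expect_true(all(diff(a) > 0))
})

test_that("invalid phantom specs are rejected with the violated constraint", {
  expect_error(PhantomSpec(heightPx = 100L, surfaceDepthPx = 50,
                           epidermisThicknessPx = 40, follicleDepthPx = 20),
               "surfaceDepthPx \\+ epidermisThicknessPx")
  expect_error(PhantomSpec(widthPx = 100L, nFollicles = 5L,
                           follicleHalfwidthPx = 10),
               "separation")
  expect_error(PhantomSpec(epidermisThicknessPx = -1), "positive")
})

test_that("cohorts have the requested layout and are reproducible", {
  base <- tinyPhantomSpec()
  co <- generateCohort(2L, 1L, base, seed = 9L)
  expect_identical(length(co), 2L)
  expect_identical(patientIds(co), c("P01", "P02"))
  co2 <- generateCohort(2L, 1L, base, seed = 9L)
  expect_identical(pixels(cohortRecords(co)[[2]]$image),
                   pixels(cohortRecords(co2)[[2]]$image))
  expect_error(generateCohort(1L, 5L, base), ">= 2")

  # study layout: 9 patients x 30 images = 270
  tiny <- tinyPhantomSpec(heightPx = 24L, widthPx = 30L, surfaceDepthPx = 5,
                          epidermisThicknessPx = 6, nFollicles = 0L,
                          follicleDepthPx = 4, follicleHalfwidthPx = 2)
  co9 <- generateCohort(9L, 30L, tiny, seed = 2L)
  expect_identical(length(co9), 270L)
  expect_identical(length(patientIds(co9)), 9L)
})

test_that("cohort round-trips through disk manifests", {
  dir <- withr::local_tempdir()
  co <- generateCohort(2L, 1L, tinyPhantomSpec(), seed = 3L)
  writeCohort(co, dir)
  back <- readCohort(file.path(dir, "manifest.csv"))
  expect_identical(length(back), 2L)
  expect_identical(labels2d(cohortRecords(back)[[1]]$mask),
                   labels2d(cohortRecords(co)[[1]]$mask))
  # 16-bit TIFF quantization: intensities agree to 1/65535
  expect_lt(max(abs(pixels(cohortRecords(back)[[1]]$image) -
                    pixels(cohortRecords(co)[[1]]$image))), 1e-4)
})
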