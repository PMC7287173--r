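test_that("the smoothing matrix reduces to a moving average for d <= 1 centers", {
  sg0 <- sgSmoothingMatrix(9, 0)
  expect_equal(sg0$b0, rep(1 / 9, 9))
  # linear fit at the window center also equals the window mean
  sg1 <- sgSmoothingMatrix(9, 1)
  expect_equal(sg1$b0, rep(1 / 9, 9))
  # center response is symmetric for higher orders too
  sg2 <- sgSmoothingMatrix(11, 3)
  expect_equal(sg2$b0, rev(sg2$b0))
  expect_error(sgSmoothingMatrix(8, 1), "odd")
  expect_error(sgSmoothingMatrix(9, 5), "order")
})

test_that("polynomials up to the fit order are reproduced exactly, transients included", {
  n <- 0:59
  for (d in 0:2) {
    x <- 2 - 0.3 * n
    if (d >= 2) x <- x + 0.05 * n^2
    if (d == 0) x <- rep(1.7, 60)
    y <- savitzkyGolay(x, window = 11, order = d)
    expect_equal(y, x, tolerance = 1e-10)
  }
  # filtering the position sequence itself with d = 1 returns it
  expect_equal(savitzkyGolay(as.numeric(1:50), 11, 1), as.numeric(1:50))
  expect_error(savitzkyGolay(1:10, window = 11), "shorter")
})

test_that("every output sample equals its per-window least-squares fit", {
  set.seed(10)
  # generic-order oracle: explicit QR fit per window
  x <- cumsum(rnorm(80))
  for (d in c(1, 2, 3)) {
    y <- savitzkyGolay(x, window = 15, order = d)
    expect_equal(y, sgOracleLM(x, 15, d), tolerance = 1e-10)
  }
  # study-scale parameters against the closed-form linear oracle
  x2 <- cumsum(rnorm(975))
  expect_equal(savitzkyGolay(x2, 449, 1), sgOracleLinear(x2, 449),
               tolerance = 1e-10)
})

test_that("the filter agrees with an established implementation", {
  set.seed(11)
  x <- cumsum(rnorm(200))
  y <- savitzkyGolay(x, window = 21, order = 3)
  ref <- as.numeric(signal::sgolayfilt(x, p = 3, n = 21))
  expect_equal(y, ref, tolerance = 1e-9)
})

test_that("boundary extraction reads masks per column and interpolates gaps", {
  mask <- flatBandMask(100, 40, 50, 80)
  prof <- extractBoundaries(mask)
  expect_true(all(surfaceRow(prof) == 50))
  expect_true(all(dejRow(prof) == 80))
  expect_true(all(validColumns(prof)))

  # invalid column between neighbors with dej 82 and 80 -> interpolated 81
  l2 <- labels2d(flatBandMask(100, 40, 50, 80))
  l2[50:80, 20] <- 2L            # no class-1 pixels in column 20
  l2[81:82, 19] <- 1L            # dej 82 in column 19
  prof2 <- extractBoundaries(LabelMask(l2))
  expect_false(validColumns(prof2)[20])
  expect_equal(dejRow(prof2)[20], 81)

  expect_error(extractBoundaries(LabelMask(matrix(0L, 5, 5))), "label 1")
})

test_that("baseline correction aligns the shallowest points", {
  # bl constant at row 100, shallowest DEJ point at 95 -> blc constant 95
  dej <- c(rep(95, 5), rep(105, 30), rep(96, 5))
  prof <- BoundaryProfile(surface = rep(10, 40), dej = dej,
                          bl = rep(100, 40))
  prof <- correctBaseline(prof)
  expect_equal(correctedBaseline(prof), rep(95, 40))
  # already aligned: dif = 0
  prof2 <- BoundaryProfile(surface = rep(10, 40), dej = dej,
                           bl = dej)
  expect_equal(correctedBaseline(correctBaseline(prof2)), dej)
  # literal row-coordinate reading kept behind the mode switch
  dej3 <- c(rep(97, 10), rep(105, 30))
  prof3 <- BoundaryProfile(surface = rep(10, 40), dej = dej3,
                           bl = rep(100, 40))
  expect_equal(correctedBaseline(correctBaseline(prof3, "shallow_align")),
               rep(97, 40))
  expect_equal(correctedBaseline(correctBaseline(prof3, "literal_rows")),
               rep(95, 40))
  expect_error(correctBaseline(BoundaryProfile(rep(1, 5), rep(2, 5))),
               "baseline")
})

test_that("a deep follicle lies fully below the corrected baseline", {
  ph <- generatePhantom(PhantomSpec(nFollicles = 1L, follicleDepthPx = 40,
                                    speckleLevel = 0,
                                    surfaceWavinessAmpPx = 0, seed = 2L))
  prof <- correctBaseline(computeBaseline(extractBoundaries(ph$mask)))
  dej <- dejRow(prof); blc <- correctedBaseline(prof)
  # body of the invagination (deeper than 1/8 of the 40 px bump); the
  # outermost Gaussian tails (~3 px) can sit above the locally raised
  # baseline, like faint follicle shoulders in real scans
  invag <- dej - min(dej) > 5
  expect_true(all(dej[invag] > blc[invag] + 1))
})

test_that("area opening enforces the fractional threshold and is idempotent", {
  mkComp <- function(area, offset) {
    px <- cbind(rep(offset + seq_len(ceiling(area / 10)), each = 10)[1:area],
                rep(1:10, length.out = area))
    list(pixels = px, area = area)
  }
  fs <- FollicleSet(components = list(mkComp(100, 0), mkComp(90, 50),
                                      mkComp(20, 100)))
  op <- areaOpening(fs, fraction = 0.3)
  expect_identical(length(op), 2L)
  expect_equal(openingThreshold(op), 30)
  expect_equal(follicleAreas(op), c(100, 90))
  # idempotent, anti-extensive
  op2 <- areaOpening(op, fraction = 0.3)
  expect_identical(follicleAreas(op2), follicleAreas(op))
  expect_lte(length(op), length(fs))
  # single component always survives; equal areas all survive
  expect_identical(length(areaOpening(FollicleSet(list(mkComp(7, 0))), 0.3)), 1L)
  eq <- FollicleSet(list(mkComp(40, 0), mkComp(40, 50), mkComp(40, 100)))
  expect_identical(length(areaOpening(eq, 0.3)), 3L)
  # empty set stays empty with zero threshold
  expect_identical(length(areaOpening(FollicleSet(), 0.3)), 0L)
  expect_equal(openingThreshold(areaOpening(FollicleSet(), 0.3)), 0)
})

test_that("sub-baseline components use 8-connectivity", {
  l <- matrix(2L, 12, 12)
  l[1, ] <- 1L                      # epidermis band so extraction succeeds
  l[6, 3] <- 1L; l[7, 4] <- 1L      # diagonal pair below the baseline
  prof <- BoundaryProfile(surface = rep(1, 12), dej = rep(1, 12),
                          bl = rep(2, 12), blc = rep(2, 12))
  fs <- detectFollicles(LabelMask(l), prof)
  expect_identical(length(fs), 1L)    # diagonal pair is one 8-connected blob
  expect_equal(follicleAreas(fs), 2)
})
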