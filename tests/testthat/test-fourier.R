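test_that("an axis-aligned square is traced and resampled exactly", {
  px <- as.matrix(expand.grid(10:17, 20:27))
  colnames(px) <- NULL
  s <- contourResample(px)
  # side 8 -> crack perimeter 32, N the next power of two = 32,
  # resampled points at unit spacing lie exactly on the square
  expect_identical(length(s), 32L)
  expect_equal(contourPerimeter(s), 32)
  onSquare <- pmax(abs(Re(s) - 23.5), abs(Im(s) - 13.5))
  expect_true(all(abs(onSquare - 4) < 1e-9))
  # resampling an already equispaced N-point contour: same set of points
  s2 <- contourResample(px, nPoints = 32L)
  expect_equal(sort(Re(s2)), sort(Re(s)))
  expect_error(contourResample(px, nPoints = 20L), "power of two")
  expect_error(contourResample(px[1:2, , drop = FALSE]), "degenerate")
})

test_that("descriptors of elementary contours match analytic transforms", {
  # constant contour: DC bin only, S[0]/N is the centroid
  cst <- rep(complex(real = 3, imaginary = -2), 16)
  S <- fourierDescriptors(cst)
  expect_equal(S[1], complex(real = 48, imaginary = -32))
  expect_true(all(Mod(S[-1]) < 1e-9))
  # circle traversed once: energy confined to bins k in {0, 1}
  n <- 0:63
  circ <- complex(real = 5 + 2 * cos(2 * pi * n / 64),
                  imaginary = 7 + 2 * sin(2 * pi * n / 64))
  Sc <- fourierDescriptors(circ)
  expect_true(all(Mod(Sc[-c(1, 2)]) < 1e-9))
  expect_equal(Sc[1] / 64, complex(real = 5, imaginary = 7))
  # Parseval
  set.seed(12)
  z <- complex(real = rnorm(32), imaginary = rnorm(32))
  expect_equal(sum(Mod(z)^2), sum(Mod(fourierDescriptors(z))^2) / 32)
})

test_that("descriptor truncation reconstructs, smooths, and is a projection", {
  set.seed(13)
  z <- complex(real = rnorm(64), imaginary = rnorm(64))
  S <- fourierDescriptors(z)
  # P = N: exact inverse
  expect_lt(max(Mod(reconstructContour(S, P = 64L) - z)), 1e-9)
  # circle from its <= 3 retained bins
  n <- 0:31
  circ <- complex(real = cos(2 * pi * n / 32), imaginary = sin(2 * pi * n / 32))
  rec <- reconstructContour(fourierDescriptors(circ), P = 3L)
  expect_lt(max(Mod(rec - circ)), 1e-9)
  # truncation is idempotent
  r1 <- reconstructContour(S, P = 5L)
  r2 <- reconstructContour(fourierDescriptors(r1), P = 5L)
  expect_lt(max(Mod(r2 - r1)), 1e-9)
  # square at N = 64, P = 4: perimeter strictly shrinks; matches a
  # brute-force truncated inverse DFT
  px <- as.matrix(expand.grid(5:20, 5:20)); colnames(px) <- NULL
  sq <- contourResample(px, nPoints = 64L)
  Ssq <- fourierDescriptors(sq)
  sm <- reconstructContour(Ssq, P = 4L)
  expect_lt(contourPerimeter(sm), contourPerimeter(sq))
  keepK <- c(0, 1, 63, 2)                      # retention order for P = 4
  brute <- vapply(0:63, function(nn)
    sum(Ssq[keepK + 1] * exp(2i * pi * keepK * nn / 64)) / 64, complex(1))
  expect_lt(max(Mod(sm - brute)), 1e-9)
  # cutoff mode: P = max(1, round(fc * N))
  expect_equal(reconstructContour(Ssq, fc = 0.007),
               reconstructContour(Ssq, P = 1L))
  expect_error(reconstructContour(Ssq, P = 0L), ">= 1")
})

test_that("recombination unions the upper epidermis with smoothed follicles", {
  ph <- generatePhantom(PhantomSpec(nFollicles = 2L, speckleLevel = 0,
                                    surfaceWavinessAmpPx = 0,
                                    follicleHalfwidthPx = 25,
                                    follicleDepthPx = 35, seed = 3L))
  res <- postprocessMask(ph$mask)
  out <- labels2d(res$mask)
  expect_true(all(out %in% 0:2))
  # smooth low-curvature follicles are nearly preserved: < 5% of the
  # epidermis+follicle pixels change
  a <- labels2d(ph$mask) == 1L
  b <- out == 1L
  expect_lt(sum(xor(a, b)) / sum(a), 0.05)

  # empty follicle set: only the upper epidermis remains class 1
  flat <- generatePhantom(PhantomSpec(nFollicles = 0L, speckleLevel = 0,
                                      surfaceWavinessAmpPx = 0))
  prof <- correctBaseline(computeBaseline(extractBoundaries(flat$mask)))
  rec <- smoothAndRecombine(flat$mask, FollicleSet(), prof)
  expect_identical(labels2d(rec), labels2d(flat$mask))
})
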