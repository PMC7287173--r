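test_that("forward pass preserves the input size and yields probabilities", {
  cfg <- NetworkConfig(nBlocks = 4L, filtersPerConv = 4L, seed = 1L)
  model <- buildNetwork(cfg)
  # training patch size: 526 x 75 in, 526 x 75 x 3 out (height padded
  # internally to a multiple of 2^4 and cropped back)
  set.seed(1)
  img <- matrix(runif(526 * 75), 526, 75)
  pm <- predictProbs(model, img)
  expect_identical(dim(probs(pm)), c(526L, 75L, 3L))
  s <- apply(probs(pm), c(1, 2), sum)
  expect_true(all(abs(s - 1) < 1e-6))
  # deterministic in inference mode
  pm2 <- predictProbs(model, img)
  expect_identical(probs(pm), probs(pm2))
})

test_that("max-pool indices place each maximum back at its argmax position", {
  set.seed(2)
  x <- array(runif(8 * 6 * 2 * 2), c(8, 6, 2, 2))
  pl <- octskinseg:::.maxpool(x)
  up <- octskinseg:::.unpool(pl$y, pl$arg, 8L, 6L)
  # each 2x2 block of `up` holds the block max at one position, 0 elsewhere
  for (i in 1:4) for (j in 1:3) {
    blk <- up[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 1, 1]
    expect_equal(max(blk), pl$y[i, j, 1, 1])
    expect_identical(sum(blk != 0), 1L)
    expect_equal(max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 1, 1]),
                 pl$y[i, j, 1, 1])
  }
})

test_that("soft-Dice loss matches hand arithmetic and its invariants", {
  # identical one-hot maps -> 0
  g <- oneHotMask(matrix(c(0L, 1L, 2L, 1L), 2, 2), 3L)
  expect_equal(softDiceLoss(g, g), 0)
  # fully disjoint hard maps -> 1
  a <- oneHotMask(matrix(0L, 2, 2), 3L)
  b <- oneHotMask(matrix(1L, 2, 2), 3L)
  expect_equal(softDiceLoss(a, b), 1)
  # 1-pixel two-class toy: 1 - 2*0.8 / (0.8^2 + 0.2^2 + 1)
  p <- array(c(0.8, 0.2), c(1, 1, 2))
  gt <- array(c(1, 0), c(1, 1, 2))
  expect_equal(softDiceLoss(p, gt), 1 - 1.6 / 1.68)
  # both identically zero -> 0 by convention
  z <- array(0, c(2, 2, 3))
  expect_equal(softDiceLoss(z, z), 0)
  # symmetry and range on random soft maps
  set.seed(5)
  for (k in 1:20) {
    pr <- array(runif(24), c(2, 4, 3))
    gr <- array(runif(24), c(2, 4, 3))
    expect_equal(softDiceLoss(pr, gr), softDiceLoss(gr, pr))
    expect_gte(softDiceLoss(pr, gr), 0)
    expect_lte(softDiceLoss(pr, gr), 1)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- NetworkConfig(nBlocks = 2L, kernelShape = c(3L, 3L),
                       filtersPerConv = 3L, seed = 7L)
  model <- buildNetwork(cfg)
  params <- model@params
  H <- 8L; W <- 12L; N <- 2L
  x <- array(runif(H * W * N), c(H, W, 1L, N))
  labs <- matrix(sample(0:2, H * W * N, TRUE), H, W * N)
  g <- array(0, c(H, W, 3L, N))
  for (n in seq_len(N)) g[, , , n] <- oneHotMask(labs[, ((n - 1) * W + 1):(n * W)], 3L)
  lossAt <- function(p) {
    fw <- octskinseg:::.netForward(p, cfg, x, train = TRUE)
    octskinseg:::.batchLoss(fw, g, cfg)$loss
  }
  fw <- octskinseg:::.netForward(params, cfg, x, train = TRUE)
  bl <- octskinseg:::.batchLoss(fw, g, cfg, withGrad = TRUE)
  gr <- octskinseg:::.netBackward(params, cfg, fw$cache, bl$dlogits)
  eps <- 1e-6
  cases <- list(
    list(get = function(p) p$enc[[1]]$W, set = function(p, v) { p$enc[[1]]$W <- v; p },
         g = gr$enc[[1]]$W),
    list(get = function(p) p$dec[[2]]$W, set = function(p, v) { p$dec[[2]]$W <- v; p },
         g = gr$dec[[2]]$W),
    list(get = function(p) p$enc[[2]]$gamma, set = function(p, v) { p$enc[[2]]$gamma <- v; p },
         g = gr$enc[[2]]$gamma),
    list(get = function(p) p$dec[[1]]$beta, set = function(p, v) { p$dec[[1]]$beta <- v; p },
         g = gr$dec[[1]]$beta),
    list(get = function(p) p$head$W, set = function(p, v) { p$head$W <- v; p },
         g = gr$head$W))
  for (cs in cases) {
    v <- cs$get(params)
    for (idx in sample(length(v), min(4, length(v)))) {
      vp <- v; vp[idx] <- vp[idx] + eps
      vm <- v; vm[idx] <- vm[idx] - eps
      fd <- (lossAt(cs$set(params, vp)) - lossAt(cs$set(params, vm))) / (2 * eps)
      expect_lt(abs(fd - cs$g[idx]) / max(1e-6, abs(fd), abs(cs$g[idx])), 1e-4)
    }
  }
})

test_that("augmentation is paired, categorical, and involutive for flips", {
  ph <- generatePhantom(tinyPhantomSpec(seed = 6L))
  img <- ph$image; mask <- ph$mask
  # explicit flip applied twice is the identity
  f1 <- octskinseg:::.geomTransform(pixels(img), TRUE, 0, 0, 0)
  f2 <- octskinseg:::.geomTransform(f1, TRUE, 0, 0, 0)
  expect_identical(f2, pixels(img))
  # identity transform
  expect_identical(octskinseg:::.geomTransform(labels2d(mask), FALSE, 0, 0, 0),
                   labels2d(mask))
  # random draws never invent labels and keep shapes
  set.seed(7)
  for (k in 1:10) {
    out <- augmentPair(img, mask)
    expect_identical(dim(labels2d(out$mask)), dim(labels2d(mask)))
    expect_true(all(unique(as.vector(labels2d(out$mask))) %in%
                    unique(as.vector(labels2d(mask)))))
  }
})

test_that("the optimizer schedule follows the step rule", {
  cfg <- NetworkConfig()
  expect_equal(lrAtEpoch(cfg, 1), 0.001)
  expect_equal(lrAtEpoch(cfg, 20), 0.001)
  expect_equal(lrAtEpoch(cfg, 21), 0.0001)
  expect_equal(lrAtEpoch(cfg, 40), 0.0001)
  expect_equal(lrAtEpoch(cfg, 41), 1e-5)
  expect_identical(iterationsPerEpoch(2730, 4), 683L)
  expect_identical(iterationsPerEpoch(8, 4), 2L)
})

test_that("training records history and returns the checkpoint minimizing validation loss", {
  co <- generateCohort(2L, 2L, tinyPhantomSpec(), seed = 5L)
  trainP <- octskinseg:::.cohortPatches(co, "P01", 32L)
  valP <- octskinseg:::.cohortPatches(co, "P02", 32L)
  m <- trainNetwork(trainP, valP, tinyNetConfig(epochs = 3L))
  h <- trainingHistory(m)
  expect_identical(nrow(h), 3L)
  expect_identical(bestEpoch(m), which.min(h$valLoss))
  expect_lte(h$valLoss[bestEpoch(m)], h$valLoss[nrow(h)])
  expect_error(trainNetwork(list(), valP, tinyNetConfig()), "empty")
})

test_that("training separates layers on noise-free phantoms", {
  # smoke property: distinct layer intensities, loss < 0.2 within 10 epochs
  co <- generateCohort(2L, 3L, tinyPhantomSpec(speckleLevel = 0,
                                               surfaceWavinessAmpPx = 0),
                       seed = 5L)
  cfg <- tinyNetConfig(filtersPerConv = 8L, epochs = 10L)
  m <- trainNetwork(octskinseg:::.cohortPatches(co, "P01", 32L),
                    octskinseg:::.cohortPatches(co, "P02", 32L), cfg)
  expect_lt(min(trainingHistory(m)$trainLoss), 0.2)
})
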