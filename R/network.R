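# Encoder-decoder fully convolutional network for 3-class B-scan labeling.
#
# Encoder block: conv (same-size zero padding) -> batch norm -> ReLU ->
# 2x2 max pool with recorded pooling indices. Decoder block: index
# unpooling (doubling resolution with the matched encoder's indices) ->
# concatenation with the matched encoder's output feature map -> conv ->
# batch norm -> ReLU. Head: 1x1 conv to the class channels + softmax.
#
# Inputs whose height or width is not divisible by 2^nBlocks are padded by
# bottom/right symmetric reflection before the encoder and cropped back
# after the decoder, so the output spatial size equals the input size.

.initConvUnit <- function(kh, kw, cin, cout, withBn = TRUE) {
  fanIn <- kh * kw * cin
  u <- list(W = matrix(stats::rnorm(fanIn * cout, sd = sqrt(2 / fanIn)),
                       fanIn, cout),
            b = numeric(cout))
  if (withBn) {
    u$gamma <- rep(1, cout); u$beta <- numeric(cout)
    u$runMean <- numeric(cout); u$runVar <- rep(1, cout)
  }
  u
}

#' Build an untrained network
#'
#' Initializes all layer parameters (He-scaled random convolution weights,
#' unit batch-norm scale, zero shift) from the config seed.
#'
#' @param config a [NetworkConfig-class].
#' @return An untrained [ModelState-class].
#' @export
buildNetwork <- function(config) {
  validObject(config)
  set.seed(config@seed)
  kh <- config@kernelShape[1]; kw <- config@kernelShape[2]
  F <- config@filtersPerConv; B <- config@nBlocks
  enc <- lapply(seq_len(B), function(b)
    .initConvUnit(kh, kw, if (b == 1L) 1L else F, F))
  dec <- lapply(seq_len(B), function(b) .initConvUnit(kh, kw, 2L * F, F))
  head <- .initConvUnit(1L, 1L, F, config@nClasses, withBn = FALSE)
  new("ModelState", params = list(enc = enc, dec = dec, head = head),
      config = config,
      history = data.frame(epoch = integer(0), trainLoss = numeric(0),
                           valLoss = numeric(0), lr = numeric(0)),
      bestEpoch = 0L)
}

# full forward pass on a batch array (H, W, 1, N); returns padded-size
# probabilities, the original (unpadded) size, and caches when train = TRUE
.netForward <- function(params, config, x, train = FALSE) {
  kh <- config@kernelShape[1]; kw <- config@kernelShape[2]
  B <- config@nBlocks
  d0 <- dim(x)
  mult <- 2L^B
  Ht <- as.integer(ceiling(d0[1] / mult) * mult)
  Wt <- as.integer(ceiling(d0[2] / mult) * mult)
  x <- .reflectPad4d(x, Ht, Wt)

  encCaches <- vector("list", B)
  skips <- vector("list", B)
  args <- vector("list", B)
  sizes <- vector("list", B)
  cur <- x
  for (b in seq_len(B)) {
    cv <- .convForward(cur, params$enc[[b]], kh, kw)
    bn <- .bnForward(cv$y, params$enc[[b]], train)
    if (train) params$enc[[b]][c("runMean", "runVar")] <-
        bn$unit[c("runMean", "runVar")]
    act <- pmax(bn$y, 0)
    pl <- .maxpool(act)
    encCaches[[b]] <- list(conv = cv$cache, bn = bn$cache, preRelu = bn$y)
    skips[[b]] <- act
    args[[b]] <- pl$arg
    sizes[[b]] <- dim(act)[1:2]
    cur <- pl$y
  }

  decCaches <- vector("list", B)
  for (b in rev(seq_len(B))) {
    up <- .unpool(cur, args[[b]], sizes[[b]][1], sizes[[b]][2])
    cat <- .catChannels(up, skips[[b]])
    cv <- .convForward(cat, params$dec[[b]], kh, kw)
    bn <- .bnForward(cv$y, params$dec[[b]], train)
    if (train) params$dec[[b]][c("runMean", "runVar")] <-
        bn$unit[c("runMean", "runVar")]
    decCaches[[b]] <- list(conv = cv$cache, bn = bn$cache, preRelu = bn$y)
    cur <- pmax(bn$y, 0)
  }

  hv <- .convForward(cur, params$head, 1L, 1L)
  probs <- .softmax4d(hv$y)
  out <- list(probs = probs, origSize = d0[1:2], params = params)
  if (train)
    out$cache <- list(encCaches = encCaches, decCaches = decCaches,
                      args = args, sizes = sizes, headCache = hv$cache,
                      headIn = cur, probs = probs, padSize = c(Ht, Wt))
  out
}

# backward pass from d(loss)/d(logits); returns gradients shaped like the
# trainable parameters
.netBackward <- function(params, config, cache, dlogits) {
  kh <- config@kernelShape[1]; kw <- config@kernelShape[2]
  B <- config@nBlocks
  grads <- list(enc = vector("list", B), dec = vector("list", B))

  hb <- .convBackward(cache$headCache, dlogits, params$head)
  grads$head <- list(W = hb$dW, b = hb$db)
  du <- hb$dX

  skipGrads <- vector("list", B)
  for (b in seq_len(B)) {
    dc <- cache$decCaches[[b]]
    dPre <- du * (dc$preRelu > 0)
    bnb <- .bnBackward(dc$bn, dPre, params$dec[[b]])
    cvb <- .convBackward(dc$conv, bnb$dX, params$dec[[b]])
    grads$dec[[b]] <- list(W = cvb$dW, b = cvb$db,
                           gamma = bnb$dgamma, beta = bnb$dbeta)
    sp <- .splitChannels(cvb$dX, config@filtersPerConv)
    skipGrads[[b]] <- sp$b
    du <- .unpoolBackward(sp$a, cache$args[[b]],
                          cache$sizes[[b]][1], cache$sizes[[b]][2])
  }

  for (b in rev(seq_len(B))) {
    de <- .maxpoolBackward(du, cache$args[[b]],
                           cache$sizes[[b]][1], cache$sizes[[b]][2]) +
      skipGrads[[b]]
    ec <- cache$encCaches[[b]]
    dPre <- de * (ec$preRelu > 0)
    bnb <- .bnBackward(ec$bn, dPre, params$enc[[b]])
    cvb <- .convBackward(ec$conv, bnb$dX, params$enc[[b]])
    grads$enc[[b]] <- list(W = cvb$dW, b = cvb$db,
                           gamma = bnb$dgamma, beta = bnb$dbeta)
    du <- cvb$dX
  }
  grads
}

#' One-hot encode a label mask
#'
#' @param mask a [LabelMask-class] or integer matrix with values in
#'   `0:(nClasses-1)`.
#' @param nClasses number of classes.
#' @return rows x cols x nClasses array of 0/1 indicators.
#' @export
oneHotMask <- function(mask, nClasses = 3L) {
  l <- if (is(mask, "LabelMask")) labels2d(mask) else mask
  out <- array(0, c(nrow(l), ncol(l), nClasses))
  for (k in seq_len(nClasses)) out[, , k] <- (l == k - 1L) + 0
  out
}

# loss and gradient wrt the predicted probabilities; the class axis is
# dim 3 of a 3-D (H, W, C) or 4-D (H, W, C, N) array
.softDiceGrad <- function(p, g, perClass = FALSE) {
  d <- dim(p); nc <- d[3]
  toM <- function(a)
    if (length(d) == 4L) matrix(aperm(a, c(1, 2, 4, 3)), ncol = nc)
    else matrix(a, ncol = nc)
  fromM <- function(m)
    if (length(d) == 4L) aperm(array(m, c(d[1], d[2], d[4], d[3])),
                               c(1, 2, 4, 3))
    else array(m, d)
  pm <- toM(p); gm <- toM(g)
  if (perClass) {
    loss <- 0
    dpm <- matrix(0, nrow(pm), nc)
    for (l in seq_len(nc)) {
      num <- sum(pm[, l] * gm[, l])
      den <- sum(pm[, l]^2) + sum(gm[, l]^2)
      if (den == 0) next  # vacuous class: contributes 0 loss, 0 gradient
      loss <- loss + (1 - 2 * num / den)
      dpm[, l] <- (-2 * gm[, l] * den + 4 * num * pm[, l]) / den^2
    }
    list(loss = loss / nc, dp = fromM(dpm / nc))
  } else {
    num <- sum(pm * gm); den <- sum(pm * pm) + sum(gm * gm)
    if (den == 0) return(list(loss = 0, dp = array(0, d)))
    list(loss = 1 - 2 * num / den,
         dp = fromM((-2 * gm * den + 4 * num * pm) / den^2))
  }
}

#' Soft-Dice loss
#'
#' Differentiable overlap loss between a predicted probability map and a
#' one-hot ground truth: one minus twice the inner product over all pixels
#' and classes divided by the sum of squared entries of both maps. It is 0
#' iff the prediction equals the ground truth as hard one-hot maps and 1
#' for fully disjoint hard maps. By the stated convention, two identically
#' zero maps give 0 (vacuous perfect match). By default one global ratio
#' is formed over classes and pixels jointly; `perClass = TRUE` averages a
#' per-class ratio instead.
#'
#' @param pred [ProbabilityMap-class] or rows x cols x classes array.
#' @param gt [LabelMask-class] or one-hot array of the same shape.
#' @param perClass average per-class ratios instead of one global ratio.
#' @return Loss value in \[0, 1\].
#' @examples
#' p <- array(c(0.8, 0.2), c(1, 1, 2))
#' g <- array(c(1, 0), c(1, 1, 2))
#' softDiceLoss(p, g)  # 1 - 1.6/1.68
#' @export
softDiceLoss <- function(pred, gt, perClass = FALSE) {
  p <- if (is(pred, "ProbabilityMap")) probs(pred) else pred
  g <- if (is(gt, "LabelMask")) oneHotMask(gt, dim(p)[3]) else gt
  stopifnot(all(dim(p) == dim(g)))
  .softDiceGrad(p, g, perClass)$loss
}

# output coords -> input coords nearest-neighbor geometric transform,
# applied identically to image and mask (mask stays categorical)
.geomTransform <- function(m, flip, dx, dy, angleDeg) {
  H <- nrow(m); W <- ncol(m)
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  if (flip) cc <- W + 1L - cc
  th <- angleDeg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  vr <- r - cy; vc <- cc - cx
  ri <- round(cy + cos(th) * vr - sin(th) * vc + dy)
  ci <- round(cx + sin(th) * vr + cos(th) * vc + dx)
  ri <- pmin(H, pmax(1, ri))
  ci <- pmin(W, pmax(1, ci))
  matrix(m[cbind(as.vector(ri), as.vector(ci))], H, W)
}

#' Random geometric augmentation of a patch pair
#'
#' Applies one randomly drawn geometric transform (horizontal flip, integer
#' translation, small rotation; out-of-range samples take the nearest edge
#' value, restoring the patch size) identically to the intensity patch and
#' its mask. Sampling is nearest-neighbor for both so the mask stays
#' categorical and no new label can appear. Uses the current RNG state;
#' seed beforehand for reproducibility.
#'
#' @param image [OCTImage-class] patch.
#' @param mask paired [LabelMask-class] patch.
#' @param maxShift maximal translation in pixels (each axis).
#' @param maxAngleDeg maximal rotation magnitude in degrees.
#' @param pFlip probability of a horizontal flip.
#' @return List with transformed `image` and `mask`.
#' @export
augmentPair <- function(image, mask, maxShift = 5L, maxAngleDeg = 10,
                        pFlip = 0.5) {
  flip <- stats::runif(1) < pFlip
  dx <- sample(seq(-maxShift, maxShift), 1)
  dy <- sample(seq(-maxShift, maxShift), 1)
  ang <- stats::runif(1, -maxAngleDeg, maxAngleDeg)
  list(image = OCTImage(.geomTransform(pixels(image), flip, dx, dy, ang),
                        axialPixelUm = axialPixelUm(image),
                        sourceId = sourceId(image)),
       mask = LabelMask(.geomTransform(labels2d(mask), flip, dx, dy, ang)))
}

#' Iterations per epoch
#'
#' Number of SGD iterations per epoch: the number of training samples
#' divided by the batch size, rounded up (the final partial batch is run).
#'
#' @param nTrain number of training samples.
#' @param batchSize minibatch size.
#' @return Integer iteration count.
#' @examples
#' iterationsPerEpoch(2730, 4)  # 683
#' @export
iterationsPerEpoch <- function(nTrain, batchSize) {
  as.integer(ceiling(nTrain / batchSize))
}

#' Learning rate at a given epoch
#'
#' The step schedule: `initialLr * lrDropFactor^((epoch - 1) %/%
#' lrDropEveryEpochs)` for 1-based epochs, i.e. one order-of-magnitude drop
#' every 20 epochs under the defaults.
#'
#' @param config a [NetworkConfig-class].
#' @param epoch 1-based epoch index.
#' @return The learning rate in effect during that epoch.
#' @export
lrAtEpoch <- function(config, epoch) {
  config@initialLr * config@lrDropFactor^((epoch - 1) %/% config@lrDropEveryEpochs)
}

.zeroLikeGrads <- function(params) {
  zl <- function(u) {
    out <- list(W = array(0, dim(u$W)), b = numeric(length(u$b)))
    if (!is.null(u$gamma)) {
      out$gamma <- numeric(length(u$gamma))
      out$beta <- numeric(length(u$beta))
    }
    out
  }
  list(enc = lapply(params$enc, zl), dec = lapply(params$dec, zl),
       head = zl(params$head))
}

.sgdUpdate <- function(params, grads, vel, lr, momentum) {
  upd <- function(p, g, v) {
    for (nm in names(g)) {
      v[[nm]] <- momentum * v[[nm]] - lr * g[[nm]]
      p[[nm]] <- p[[nm]] + v[[nm]]
    }
    list(p = p, v = v)
  }
  for (b in seq_along(params$enc)) {
    r <- upd(params$enc[[b]], grads$enc[[b]], vel$enc[[b]])
    params$enc[[b]] <- r$p; vel$enc[[b]] <- r$v
  }
  for (b in seq_along(params$dec)) {
    r <- upd(params$dec[[b]], grads$dec[[b]], vel$dec[[b]])
    params$dec[[b]] <- r$p; vel$dec[[b]] <- r$v
  }
  r <- upd(params$head, grads$head, vel$head)
  params$head <- r$p; vel$head <- r$v
  list(params = params, vel = vel)
}

.pairsToBatch <- function(pairs, nClasses) {
  H <- nrow(pixels(pairs[[1]]$image)); W <- ncol(pixels(pairs[[1]]$image))
  N <- length(pairs)
  x <- array(0, c(H, W, 1L, N))
  g <- array(0, c(H, W, nClasses, N))
  for (n in seq_len(N)) {
    x[, , 1L, n] <- pixels(pairs[[n]]$image)
    g[, , , n] <- oneHotMask(pairs[[n]]$mask, nClasses)
  }
  list(x = x, g = g)
}

# loss (and optionally dlogits) for one forward result against one-hot gt
.batchLoss <- function(fw, g, config, withGrad = FALSE) {
  H0 <- dim(g)[1]; W0 <- dim(g)[2]
  p <- fw$probs
  pc <- p[seq_len(H0), seq_len(W0), , , drop = FALSE]
  sg <- .softDiceGrad(pc, g, config@dicePerClass)
  if (!withGrad) return(list(loss = sg$loss))
  dp <- array(0, dim(p))
  dp[seq_len(H0), seq_len(W0), , ] <- sg$dp
  # softmax jacobian: dlogit = p * (dp - sum_l p_l dp_l)
  pm <- .toChanMat(p); dpm <- .toChanMat(dp)
  dlm <- pm * (dpm - rowSums(pm * dpm))
  list(loss = sg$loss, dlogits = .fromChanMat(dlm, dim(p)))
}

#' Train the network
#'
#' Runs minibatch SGD with momentum under the configured step learning-rate
#' schedule, optimizing the Soft-Dice loss on the training patches. After
#' every epoch the Soft-Dice loss on the validation patches is evaluated in
#' inference mode (batch-norm running statistics); the returned model holds
#' the checkpoint of the epoch minimizing validation loss.
#'
#' @param trainPairs list of `list(image =, mask =)` patch pairs
#'   (all patches of equal size), e.g. from [extractPatches()].
#' @param valPairs validation patch pairs.
#' @param config a [NetworkConfig-class].
#' @return A trained [ModelState-class] with per-epoch history.
#' @export
trainNetwork <- function(trainPairs, valPairs, config) {
  if (length(trainPairs) == 0L) stop("empty training set")
  model <- buildNetwork(config)
  params <- model@params
  vel <- .zeroLikeGrads(params)
  nTrain <- length(trainPairs)
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  bestLoss <- Inf; bestParams <- params; bestEpoch <- 0L
  set.seed(config@seed)
  for (epoch in seq_len(config@epochs)) {
    lr <- lrAtEpoch(config, epoch)
    ord <- sample(nTrain)
    epochLoss <- 0; nBatches <- 0L
    for (start in seq(1L, nTrain, by = config@batchSize)) {
      idx <- ord[start:min(start + config@batchSize - 1L, nTrain)]
      batch <- lapply(trainPairs[idx], function(pr) {
        if (config@augment) augmentPair(pr$image, pr$mask) else pr
      })
      bt <- .pairsToBatch(batch, config@nClasses)
      fw <- .netForward(params, config, bt$x, train = TRUE)
      params <- fw$params  # batch-norm running statistics advanced
      bl <- .batchLoss(fw, bt$g, config, withGrad = TRUE)
      grads <- .netBackward(params, config, fw$cache, bl$dlogits)
      st <- .sgdUpdate(params, grads, vel, lr, config@momentum)
      params <- st$params; vel <- st$vel
      epochLoss <- epochLoss + bl$loss; nBatches <- nBatches + 1L
    }
    valLoss <- .evalLoss(params, config, valPairs)
    hist[nrow(hist) + 1L, ] <- list(epoch, epochLoss / nBatches, valLoss, lr)
    if (valLoss < bestLoss) {
      bestLoss <- valLoss; bestParams <- params; bestEpoch <- epoch
    }
  }
  new("ModelState", params = bestParams, config = config, history = hist,
      bestEpoch = bestEpoch)
}

.evalLoss <- function(params, config, pairs) {
  if (length(pairs) == 0L) return(NA_real_)
  tot <- 0
  for (pr in pairs) {
    bt <- .pairsToBatch(list(pr), config@nClasses)
    fw <- .netForward(params, config, bt$x, train = FALSE)
    tot <- tot + .batchLoss(fw, bt$g, config)$loss
  }
  tot / length(pairs)
}

#' Predict class probabilities for one image
#'
#' Forward pass in inference mode (deterministic: batch-norm running
#' statistics, no augmentation); the output is cropped to the input size.
#'
#' @param model a [ModelState-class].
#' @param image an [OCTImage-class] (or matrix).
#' @return A [ProbabilityMap-class] the size of the input.
#' @export
predictProbs <- function(model, image) {
  m <- if (is(image, "OCTImage")) pixels(image) else image
  x <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  fw <- .netForward(model@params, model@config, x, train = FALSE)
  ProbabilityMap(fw$probs[seq_len(nrow(m)), seq_len(ncol(m)), , 1L,
                          drop = TRUE])
}
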