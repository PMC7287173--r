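# Internal neural-network primitives operating on 4-D arrays (H, W, C, N).
# Convolutions are computed as im2col gathers followed by one BLAS matrix
# product; max-pooling records its argmax indices so the decoder can place
# activations back at their original positions (index unpooling).

# linear gather indices into the zero-padded plane for a same-size conv
.convIndex <- function(H, W, kh, kw) {
  Hp <- H + kh - 1L
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  I <- matrix(0L, H * W, kh * kw)
  k <- 0L
  for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
    k <- k + 1L
    I[, k] <- (i + di) + (j + dj - 1L) * Hp
  }
  I
}

.convForward <- function(x, unit, kh, kw) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  I <- .convIndex(H, W, kh, kw)
  khkw <- kh * kw
  Cout <- length(unit$b)
  y <- array(0, c(H, W, Cout, N))
  cols <- vector("list", N)
  pad <- array(0, c(Hp, Wp, C))
  for (n in seq_len(N)) {
    pad[ph + seq_len(H), pw + seq_len(W), ] <- x[, , , n]
    col <- matrix(0, H * W, khkw * C)
    for (c in seq_len(C)) {
      plane <- pad[, , c]
      col[, ((c - 1L) * khkw + 1L):(c * khkw)] <- plane[I]
    }
    y[, , , n] <- array(col %*% unit$W, c(H, W, Cout)) +
      rep(unit$b, each = H * W)
    cols[[n]] <- col
  }
  list(y = y, cache = list(cols = cols, I = I, dims = d, kh = kh, kw = kw))
}

.convBackward <- function(cache, dY, unit) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- cache$kh; kw <- cache$kw
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  khkw <- kh * kw
  Cout <- length(unit$b)
  dW <- matrix(0, nrow(unit$W), Cout)
  db <- numeric(Cout)
  dX <- array(0, d)
  I <- cache$I
  for (n in seq_len(N)) {
    dYm <- matrix(dY[, , , n], H * W, Cout)
    dW <- dW + crossprod(cache$cols[[n]], dYm)
    db <- db + colSums(dYm)
    dcol <- dYm %*% t(unit$W)
    for (c in seq_len(C)) {
      dplane <- matrix(0, Hp, Wp)
      blk <- dcol[, ((c - 1L) * khkw + 1L):(c * khkw), drop = FALSE]
      for (k in seq_len(khkw))
        dplane[I[, k]] <- dplane[I[, k]] + blk[, k]
      dX[, , c, n] <- dplane[ph + seq_len(H), pw + seq_len(W)]
    }
  }
  list(dX = dX, dW = dW, db = db)
}

.toChanMat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
}

.fromChanMat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

.bnForward <- function(x, unit, train, eps = 1e-5, runMomentum = 0.1) {
  d <- dim(x)
  xm <- .toChanMat(x)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu  # biased, standard for batch norm
    unit$runMean <- (1 - runMomentum) * unit$runMean + runMomentum * mu
    unit$runVar <- (1 - runMomentum) * unit$runVar + runMomentum * v
  } else {
    mu <- unit$runMean
    v <- unit$runVar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  ym <- sweep(sweep(xhat, 2, unit$gamma, "*"), 2, unit$beta, "+")
  list(y = .fromChanMat(ym, d), unit = unit,
       cache = list(xhat = xhat, invstd = invstd, dims = d))
}

.bnBackward <- function(cache, dY, unit) {
  d <- cache$dims
  dym <- .toChanMat(dY)
  xhat <- cache$xhat
  m <- nrow(dym)
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, unit$gamma, "*")
  mean1 <- colMeans(dxhat)
  mean2 <- colMeans(dxhat * xhat)
  dxm <- sweep(dxhat, 2, mean1) - sweep(xhat, 2, mean2, "*")
  dxm <- sweep(dxm, 2, cache$invstd, "*")
  list(dX = .fromChanMat(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

.poolGrids <- function(d) {
  Ho <- d[1]; Wo <- d[2]; C <- d[3]; N <- d[4]
  list(i = array(rep(seq_len(Ho), Wo * C * N), d),
       j = array(rep(rep(seq_len(Wo), each = Ho), C * N), d),
       c = array(rep(rep(seq_len(C), each = Ho * Wo), N), d),
       n = array(rep(seq_len(N), each = Ho * Wo * C), d))
}

# 2x2 stride-2 max pooling; argmax recorded as 1..4 (ties -> lowest code)
# codes: 1 = top-left, 2 = bottom-left, 3 = top-right, 4 = bottom-right
.maxpool <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  or <- seq(1L, H, by = 2L); er <- or + 1L
  oc <- seq(1L, W, by = 2L); ec <- oc + 1L
  cand <- list(x[or, oc, , , drop = FALSE], x[er, oc, , , drop = FALSE],
               x[or, ec, , , drop = FALSE], x[er, ec, , , drop = FALSE])
  best <- cand[[1]]
  arg <- array(1L, dim(best))
  for (k in 2:4) {
    m <- cand[[k]] > best
    best[m] <- cand[[k]][m]
    arg[m] <- k
  }
  list(y = best, arg = arg)
}

.poolLinearIndex <- function(arg, H, W) {
  g <- .poolGrids(dim(arg))
  row <- 2L * g$i - 1L + (arg == 2L | arg == 4L)
  col <- 2L * g$j - 1L + (arg == 3L | arg == 4L)
  row + (col - 1L) * H + (g$c - 1L) * H * W + (g$n - 1L) * H * W * dim(arg)[3]
}

.maxpoolBackward <- function(dY, arg, H, W) {
  dX <- array(0, c(H, W, dim(arg)[3], dim(arg)[4]))
  dX[.poolLinearIndex(arg, H, W)] <- dY
  dX
}

# index unpooling: doubles resolution, placing each value at its recorded
# argmax position, zeros elsewhere
.unpool <- function(z, arg, H, W) {
  y <- array(0, c(H, W, dim(z)[3], dim(z)[4]))
  y[.poolLinearIndex(arg, H, W)] <- z
  y
}

.unpoolBackward <- function(dY, arg, H, W) {
  array(dY[.poolLinearIndex(arg, H, W)], dim(arg))
}

.catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  ap <- aperm(a, c(1, 2, 4, 3)); bp <- aperm(b, c(1, 2, 4, 3))
  aperm(array(c(ap, bp), c(da[1], da[2], da[4], da[3] + db[3])), c(1, 2, 4, 3))
}

.splitChannels <- function(x, c1) {
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , (c1 + 1L):dim(x)[3], , drop = FALSE])
}

# bottom/right symmetric reflection padding of each (H, W) plane
.reflectPad4d <- function(x, Ht, Wt) {
  d <- dim(x)
  if (d[1] == Ht && d[2] == Wt) return(x)
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(Ht)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(Wt)]
  x[ri, ci, , , drop = FALSE]
}

.softmax4d <- function(logits) {
  d <- dim(logits)
  lm <- .toChanMat(logits)
  lm <- lm - apply(lm, 1, max)
  em <- exp(lm)
  .fromChanMat(em / rowSums(em), d)
}
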