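# Shared fixtures: small phantom specs and network configs sized for unit
# tests, and independent least-squares oracles for the Savitzky-Golay
# filter.

tinyPhantomSpec <- function(...) {
  args <- utils::modifyList(
    list(heightPx = 64L, widthPx = 96L, surfaceDepthPx = 14,
         epidermisThicknessPx = 16, nFollicles = 1L, follicleDepthPx = 12,
         follicleHalfwidthPx = 6, speckleLevel = 0.15,
         surfaceWavinessAmpPx = 1, seed = 1L),
    list(...))
  do.call(PhantomSpec, args)
}

tinyNetConfig <- function(...) {
  args <- utils::modifyList(
    list(nBlocks = 2L, filtersPerConv = 6L, kernelShape = c(7L, 3L),
         batchSize = 4L, epochs = 2L, initialLr = 0.01,
         lrDropEveryEpochs = 20L, augment = FALSE, seed = 3L),
    list(...))
  do.call(NetworkConfig, args)
}

# flat-band mask: label 1 on rows surf..dej in every column
flatBandMask <- function(H, W, surf, dej) {
  l <- matrix(2L, H, W)
  l[seq_len(surf - 1L), ] <- 0L
  l[surf:dej, ] <- 1L
  LabelMask(l)
}

# Independent SG oracle, any order: explicit per-sample least-squares
# polynomial fit over the window of that sample, evaluated at the sample's
# position (QR-based lm.fit, no projection matrix).
sgOracleLM <- function(x, window, order) {
  L <- length(x); M <- (window - 1L) %/% 2L
  vapply(seq_len(L), function(n) {
    if (n <= M) { win <- 1:window; pos <- n }
    else if (n >= L - M + 1L) { win <- (L - window + 1L):L; pos <- n - (L - window) }
    else { win <- (n - M):(n + M); pos <- M + 1L }
    m <- seq_along(win) - pos          # window positions relative to sample
    fit <- stats::lm.fit(outer(m, 0:order, "^"), x[win])
    fit$coefficients[1]
  }, numeric(1))
}

# Fast independent oracle for order 1: closed-form line fits (running sums
# for the steady state, explicit slope/intercept at the transients).
sgOracleLinear <- function(x, window) {
  L <- length(x); M <- (window - 1L) %/% 2L; N <- window
  y <- numeric(L)
  # steady state: center of an LS line over a symmetric window = window mean
  cs <- cumsum(c(0, x))
  steady <- (M + 1L):(L - M)
  y[steady] <- (cs[steady + M + 1L] - cs[steady - M]) / N
  lineFit <- function(win) {
    m <- seq_len(N); mb <- mean(m); xb <- mean(win)
    beta <- sum((m - mb) * (win - xb)) / sum((m - mb)^2)
    c(intercept = xb - beta * mb, slope = beta)
  }
  f1 <- lineFit(x[1:N])
  y[1:M] <- f1["intercept"] + f1["slope"] * (1:M)
  f2 <- lineFit(x[(L - N + 1L):L])
  y[(L - M + 1L):L] <- f2["intercept"] + f2["slope"] * ((N - M + 1L):N)
  y
}

# perimeter of a closed complex contour
contourPerimeter <- function(s) sum(Mod(diff(c(s, s[1]))))
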