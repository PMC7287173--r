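# Contour tracing, equispaced resampling, Fourier descriptors and
# truncated-descriptor smoothing of follicular components, plus the final
# recombination into a label mask.

# Traces the boundary of a pixel component as the closed polygon of pixel
# edges separating foreground from background ("crack" boundary): a pixel
# (r, c) occupies the unit square [c-.5, c+.5] x [r-.5, r+.5]. Directed so
# the interior stays on a fixed side; at pinch vertices (diagonal touches
# of an 8-connected component) the traversal prefers the left turn, which
# crosses into the diagonal neighbor and keeps the component on one loop.
# Returns complex vertices x + iy (x = column, y = row).
.traceBoundary <- function(pixels) {
  r0 <- min(pixels[, 1]) - 2L; c0 <- min(pixels[, 2]) - 2L
  H <- max(pixels[, 1]) - r0 + 2L; W <- max(pixels[, 2]) - c0 + 2L
  fg <- matrix(FALSE, H, W)
  fg[cbind(pixels[, 1] - r0, pixels[, 2] - c0)] <- TRUE

  # directed edges in doubled (integer) coordinates: key = 2*coord
  from <- to <- integer(0)
  idx <- which(fg, arr.ind = TRUE)
  enc <- function(x2, y2) x2 * 100000L + y2
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; cc <- idx[k, 2]
    x1 <- 2L * cc - 1L; x2 <- 2L * cc + 1L   # doubled x of left/right edges
    y1 <- 2L * r - 1L; y2 <- 2L * r + 1L
    if (!fg[r - 1L, cc]) { from <- c(from, enc(x1, y1)); to <- c(to, enc(x2, y1)) }
    if (!fg[r, cc + 1L]) { from <- c(from, enc(x2, y1)); to <- c(to, enc(x2, y2)) }
    if (!fg[r + 1L, cc]) { from <- c(from, enc(x2, y2)); to <- c(to, enc(x1, y2)) }
    if (!fg[r, cc - 1L]) { from <- c(from, enc(x1, y2)); to <- c(to, enc(x1, y1)) }
  }
  nE <- length(from)
  used <- logical(nE)
  outEdges <- split(seq_len(nE), from)
  decode <- function(key) c(key %/% 100000L, key %% 100000L)  # (x2, y2)
  dirOf <- function(e) {
    f <- decode(from[e]); t <- decode(to[e])
    c(sign(t[1] - f[1]), sign(t[2] - f[2]))
  }
  loops <- list()
  for (startE in seq_len(nE)) {
    if (used[startE]) next
    loop <- integer(0)
    e <- startE
    repeat {
      used[e] <- TRUE
      loop <- c(loop, e)
      cand <- outEdges[[as.character(to[e])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) == 1L) e <- cand[1L]
      else {
        d <- dirOf(e)
        # preference: left turn, straight, right turn, reverse
        prefs <- list(c(d[2], -d[1]), d, c(-d[2], d[1]), -d)
        score <- vapply(cand, function(ce) {
          dc <- dirOf(ce)
          which(vapply(prefs, function(p) all(p == dc), logical(1)))[1]
        }, numeric(1))
        e <- cand[which.min(score)]
      }
      if (to[e] == from[startE]) { used[e] <- TRUE; loop <- c(loop, e); break }
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loop <- loops[[which.max(lengths(loops))]]
  xy <- vapply(from[loop], decode, numeric(2))
  complex(real = (xy[1, ] / 2) + c0, imaginary = (xy[2, ] / 2) + r0)
}

#' Trace and resample a component contour
#'
#' Traces the closed boundary polygon of a connected pixel component and
#' resamples it to N points equispaced in arc length, N the smallest power
#' of two at or above the raw boundary vertex count (unless given). Points
#' are complex, x + iy with x the lateral (column) and y the depth (row)
#' coordinate.
#'
#' @param component a component record (list with a `pixels` matrix) or a
#'   two-column row/col matrix.
#' @param nPoints optional number of resampled points; must be a power of
#'   two.
#' @return Complex vector of N contour points.
#' @export
contourResample <- function(component, nPoints = NULL) {
  px <- if (is.list(component)) component$pixels else component
  if (nrow(px) < 3L)
    stop("degenerate component: at least 3 boundary pixels are required")
  poly <- .traceBoundary(px)
  k <- length(poly)
  N <- if (is.null(nPoints)) 2L^ceiling(log2(k)) else as.integer(nPoints)
  if (bitwAnd(N, N - 1L) != 0L) stop("nPoints must be a power of two")
  closed <- c(poly, poly[1L])
  seg <- Mod(diff(closed))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- (seq_len(N) - 1L) * total / N
  ii <- findInterval(targets, cum, rightmost.closed = TRUE)
  frac <- (targets - cum[ii]) / pmax(seg[ii], .Machine$double.eps)
  closed[ii] + frac * (closed[ii + 1L] - closed[ii])
}

#' Fourier descriptors of a closed contour
#'
#' The discrete Fourier transform `S[k] = sum_n s[n] exp(-i 2 pi k n / N)`
#' of the complex contour sequence; `S[0]/N` is the contour centroid.
#'
#' @param s complex contour of N points (N a power of two).
#' @return Complex vector of N descriptors (k = 0, ..., N-1).
#' @export
fourierDescriptors <- function(s) stats::fft(s)

#' Reconstruct a contour from truncated Fourier descriptors
#'
#' Inverse DFT over the retained low-frequency descriptors only. Retention
#' is symmetric about zero frequency: k = 0 first, then the pairs
#' (k, N - k) by increasing k, until P bins are kept; for even P the last
#' pair contributes only its lower k. With P = N the original contour is
#' recovered exactly; decreasing P smooths the contour.
#'
#' @param S complex descriptor vector of length N.
#' @param P number of retained descriptors (1 <= P <= N). Ignored when
#'   `fc` is given.
#' @param fc optional frequency cutoff; retains `P = max(1, round(fc * N))`
#'   descriptors.
#' @return Complex vector of N smoothed contour points.
#' @export
reconstructContour <- function(S, P = 4L, fc = NULL) {
  N <- length(S)
  if (!is.null(fc)) P <- max(1, round(fc * N))
  if (P < 1L) stop("P must be >= 1")
  P <- min(P, N)
  ord <- 1L  # R index of k = 0
  k <- 1L
  while (length(ord) < P) {
    ord <- c(ord, k + 1L)
    if (length(ord) < P && N - k + 1L > k + 1L) ord <- c(ord, N - k + 1L)
    k <- k + 1L
  }
  keep <- logical(N)
  keep[ord[seq_len(P)]] <- TRUE
  stats::fft(S * keep, inverse = TRUE) / N
}

#' Smooth all follicle contours by descriptor truncation
#'
#' For each component: trace and resample its boundary, take Fourier
#' descriptors, reconstruct from the retained low-frequency descriptors
#' (fixed P, default 4, or `P = round(fc * N)` when a cutoff is given).
#' Components too small to trace keep their raw pixel set.
#'
#' @param follicles a [FollicleSet-class] (after area opening).
#' @param P retained descriptor count in fixed-P mode.
#' @param fc optional frequency cutoff overriding the fixed P per contour.
#' @return The [FollicleSet-class] with `contour`, `descriptors`,
#'   `smoothed` and `retainedP` filled in per component.
#' @export
smoothFollicles <- function(follicles, P = 4L, fc = NULL) {
  comps <- lapply(follicleComponents(follicles), function(co) {
    if (nrow(co$pixels) < 3L) return(co)
    co$contour <- contourResample(co)
    co$descriptors <- fourierDescriptors(co$contour)
    N <- length(co$contour)
    co$retainedP <- if (is.null(fc)) min(P, N) else max(1, round(fc * N))
    co$smoothed <- reconstructContour(co$descriptors, P = co$retainedP)
    co
  })
  FollicleSet(components = comps, alpha = follicles@alpha,
              fc = if (is.null(fc)) NA_real_ else fc)
}

# even-odd rasterization of a closed polygon onto pixel centers
.fillPolygon <- function(poly, H, W) {
  xs <- Re(poly); ys <- Im(poly)
  rr <- max(1L, floor(min(ys))):min(H, ceiling(max(ys)))
  cc <- max(1L, floor(min(xs))):min(W, ceiling(max(xs)))
  if (length(rr) == 0L || length(cc) == 0L) return(matrix(FALSE, H, W))
  py <- rep(rr, length(cc))
  px <- rep(cc, each = length(rr))
  inside <- rep(FALSE, length(py))
  n <- length(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- ys[i]; yj <- ys[j]; xi <- xs[i]; xj <- xs[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xc <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xc)
    }
    j <- i
  }
  out <- matrix(FALSE, H, W)
  out[cbind(py[inside], px[inside])] <- TRUE
  out
}

#' Recombine the upper epidermis with smoothed follicles
#'
#' The final epidermis+follicle class is the union of the class-1 pixels
#' at or above the corrected baseline with the filled (rasterized)
#' smoothed follicle contours; pixels above the surface are class 0 and
#' everything else class 2.
#'
#' @param mask the input [LabelMask-class].
#' @param follicles a smoothed [FollicleSet-class]
#'   (see [smoothFollicles()]).
#' @param profile a [BoundaryProfile-class] with `blc` set.
#' @return The recombined [LabelMask-class].
#' @export
smoothAndRecombine <- function(mask, follicles, profile) {
  l <- labels2d(mask)
  H <- nrow(l); W <- ncol(l)
  rows <- matrix(seq_len(H), H, W)
  blcM <- matrix(correctedBaseline(profile), H, W, byrow = TRUE)
  class1 <- (l == 1L) & (rows <= blcM)
  for (co in follicleComponents(follicles)) {
    if (!is.null(co$smoothed)) class1 <- class1 | .fillPolygon(co$smoothed, H, W)
    else class1[co$pixels] <- TRUE
  }
  surfM <- matrix(surfaceRow(profile), H, W, byrow = TRUE)
  out <- matrix(2L, H, W)
  out[rows < surfM] <- 0L
  out[class1] <- 1L
  LabelMask(out)
}

#' Full post-processing of a label mask
#'
#' Runs the complete refinement chain on a (typically network-predicted)
#' label mask: boundary extraction, Savitzky-Golay baseline of the DEJ with
#' correction, sub-baseline component detection, area opening,
#' Fourier-descriptor contour smoothing, and recombination.
#'
#' @param mask a [LabelMask-class].
#' @param window,order Savitzky-Golay window and polynomial order.
#' @param fraction area-opening fraction of the maximal component area.
#' @param P retained descriptor count (fixed-P mode).
#' @param fc optional frequency cutoff; when given, P is derived per
#'   contour as `round(fc * N)`.
#' @param baselineMode baseline correction mode, see [correctBaseline()].
#' @return List with `mask` (final [LabelMask-class]), `profile`
#'   ([BoundaryProfile-class] with baselines) and `follicles`
#'   (smoothed [FollicleSet-class]).
#' @export
postprocessMask <- function(mask, window = 449L, order = 1L, fraction = 0.3,
                            P = 4L, fc = NULL,
                            baselineMode = "shallow_align") {
  profile <- correctBaseline(computeBaseline(extractBoundaries(mask),
                                             window = window, order = order),
                             mode = baselineMode)
  fol <- areaOpening(detectFollicles(mask, profile), fraction = fraction)
  fol <- smoothFollicles(fol, P = P, fc = fc)
  list(mask = smoothAndRecombine(mask, fol, profile), profile = profile,
       follicles = fol)
}
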