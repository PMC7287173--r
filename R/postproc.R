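# Refinement of a 3-class label mask: DEJ boundary extraction,
# Savitzky-Golay baseline with correction, isolation of sub-baseline
# follicular components by 8-connected labeling and area opening, and
# recombination with the smoothed contours into the final mask.

#' Extract per-column boundary signals from a label mask
#'
#' For each column, the surface is the smallest row carrying the epidermis
#' class (label 1) and the DEJ is the largest such row. Columns with no
#' epidermis pixel are flagged invalid and filled by linear interpolation
#' from the nearest valid columns (edge columns take the nearest valid
#' value).
#'
#' @param mask a [LabelMask-class] containing at least one label-1 pixel.
#' @return A [BoundaryProfile-class] (baselines not yet computed).
#' @export
extractBoundaries <- function(mask) {
  l <- labels2d(mask)
  W <- ncol(l)
  surface <- rep(NA_real_, W); dej <- rep(NA_real_, W)
  for (cc in seq_len(W)) {
    r <- which(l[, cc] == 1L)
    if (length(r)) {
      surface[cc] <- r[1L]
      dej[cc] <- r[length(r)]
    }
  }
  valid <- !is.na(surface)
  if (!any(valid)) stop("mask contains no epidermis-class (label 1) pixels")
  if (!all(valid)) {
    iv <- which(valid)
    surface <- stats::approx(iv, surface[iv], xout = seq_len(W), rule = 2)$y
    dej <- stats::approx(iv, dej[iv], xout = seq_len(W), rule = 2)$y
  }
  BoundaryProfile(surface = surface, dej = dej, valid = valid)
}

#' Savitzky-Golay baseline of the DEJ signal
#'
#' Smooths the per-column DEJ rows with a long low-order Savitzky-Golay
#' window (defaults: order 1, window 449 samples) to obtain the baseline
#' separating the flat epidermis from the follicular invaginations. For
#' signals shorter than the window, the window is reduced to the largest
#' odd length that fits.
#'
#' @param profile a [BoundaryProfile-class].
#' @param window odd Savitzky-Golay window length.
#' @param order polynomial order.
#' @return The profile with its `bl` slot set.
#' @export
computeBaseline <- function(profile, window = 449L, order = 1L) {
  s <- dejRow(profile)
  L <- length(s)
  w <- as.integer(min(window, if (L %% 2L == 1L) L else L - 1L))
  if (w %% 2L == 0L) w <- w - 1L
  profile@bl <- savitzkyGolay(s, window = w, order = order)
  validObject(profile)
  profile
}

#' Correct the DEJ baseline
#'
#' Shifts the baseline by the scalar offset between the extrema of the DEJ
#' signal and of the baseline so that the baseline hugs the non-follicular
#' DEJ and the full follicular invaginations fall below it. In the default
#' `"shallow_align"` mode the signals are read in height-up coordinates
#' (image height minus row), where the correction subtracts
#' `max(s_dej) - max(bl)`; in row coordinates this aligns the shallowest
#' point of the baseline with the shallowest DEJ point:
#' `blc = bl - (min(bl) - min(s_dej))`. The `"literal_rows"` mode applies
#' the same formula directly to row coordinates
#' (`blc = bl - (max(s_dej) - max(bl))`), which shifts the baseline toward
#' the deepest invagination instead and is kept only as a switch.
#'
#' @param profile a [BoundaryProfile-class] with `bl` computed.
#' @param mode `"shallow_align"` (default) or `"literal_rows"`.
#' @return The profile with its `blc` slot set.
#' @export
correctBaseline <- function(profile, mode = c("shallow_align", "literal_rows")) {
  mode <- match.arg(mode)
  bl <- baseline(profile)
  if (is.null(bl)) stop("compute the baseline first (computeBaseline)")
  s <- dejRow(profile)
  dif <- switch(mode,
    shallow_align = min(bl) - min(s),
    literal_rows = max(s) - max(bl))
  profile@blc <- bl - dif
  validObject(profile)
  profile
}

# 8-connected labeling: 4-connected pass (EBImage) + union-find merge of
# diagonally adjacent labels
.label8 <- function(binary) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::as.Image(binary * 1)))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  parent <- seq_len(nl)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nl), findRoot, integer(1))
    remap <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

#' Detect candidate follicular components
#'
#' Candidate pixels are epidermis-class pixels lying strictly deeper than
#' the corrected baseline at their column; their 8-connected components
#' are the candidate follicles, recorded with their pixel sets and areas.
#'
#' @param mask a [LabelMask-class].
#' @param profile a [BoundaryProfile-class] with `blc` set.
#' @return A [FollicleSet-class] (before area opening); empty when no
#'   pixel lies below the corrected baseline.
#' @export
detectFollicles <- function(mask, profile) {
  blc <- correctedBaseline(profile)
  if (is.null(blc)) stop("corrected baseline required (correctBaseline)")
  l <- labels2d(mask)
  H <- nrow(l)
  below <- (l == 1L) & (matrix(seq_len(H), H, ncol(l)) >
                          matrix(blc, H, ncol(l), byrow = TRUE))
  if (!any(below)) return(FollicleSet())
  lab <- .label8(below)
  comps <- lapply(seq_len(max(lab)), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    list(pixels = unname(px), area = nrow(px))
  })
  FollicleSet(components = comps)
}

#' Morphological area opening of a follicle set
#'
#' Removes components whose area is below `alpha = fraction * max(A_c)`,
#' the fraction of the largest component area (default 0.3). A single
#' component always survives; an empty set stays empty with threshold 0.
#' The operation is idempotent and never adds components.
#'
#' @param follicles a [FollicleSet-class].
#' @param fraction fraction of the maximal component area in (0, 1\].
#' @return The opened [FollicleSet-class] with its `alpha` slot set.
#' @export
areaOpening <- function(follicles, fraction = 0.3) {
  stopifnot(fraction > 0, fraction <= 1)
  areas <- follicleAreas(follicles)
  if (length(areas) == 0L) return(FollicleSet(alpha = 0, fc = follicles@fc))
  alpha <- fraction * max(areas)
  keep <- areas >= alpha
  FollicleSet(components = follicleComponents(follicles)[keep],
              alpha = alpha, fc = follicles@fc)
}

#' Run the baseline chain and count surviving follicles
#'
#' Convenience wrapper: boundary extraction, Savitzky-Golay baseline,
#' correction, sub-baseline 8-connected components and area opening;
#' returns the surviving component count.
#'
#' @param mask a [LabelMask-class].
#' @param window,order Savitzky-Golay parameters.
#' @param fraction area-opening fraction.
#' @param baselineMode baseline correction mode, see [correctBaseline()].
#' @return Non-negative integer follicle count.
#' @export
countFollicles <- function(mask, window = 449L, order = 1L, fraction = 0.3,
                           baselineMode = "shallow_align") {
  profile <- correctBaseline(computeBaseline(extractBoundaries(mask),
                                             window = window, order = order),
                             mode = baselineMode)
  length(areaOpening(detectFollicles(mask, profile), fraction = fraction))
}
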