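# Evaluation: Dice and Jaccard per layer, follicle counting with the
# relative success rate, epidermal thickness, RMSE/MAE of thickness, and
# per-patient / cohort aggregation.

.layerSets <- function(a, b, layer) {
  la <- if (is(a, "LabelMask")) labels2d(a) else a
  lb <- if (is(b, "LabelMask")) labels2d(b) else b
  if (!all(dim(la) == dim(lb))) stop("masks must share dimensions")
  list(a = la == layer, b = lb == layer)
}

#' Dice coefficient for one layer
#'
#' `2 |A intersect B| / (|A| + |B|)` on the binary masks of the given
#' class. When both layer masks are empty the result is 1 (vacuous
#' perfect agreement, the standard convention in segmentation evaluation).
#'
#' @param a,b [LabelMask-class] objects (or integer matrices) of equal
#'   shape.
#' @param layer class id (0, 1 or 2).
#' @return Dice coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(a, b, layer = 1L) {
  s <- .layerSets(a, b, layer)
  denom <- sum(s$a) + sum(s$b)
  if (denom == 0) return(1)
  2 * sum(s$a & s$b) / denom
}

#' Jaccard index for one layer
#'
#' `|A intersect B| / |A union B|`; 1 when both are empty.
#'
#' @inheritParams diceCoefficient
#' @return Jaccard index in \[0, 1\].
#' @export
jaccardIndex <- function(a, b, layer = 1L) {
  s <- .layerSets(a, b, layer)
  uni <- sum(s$a | s$b)
  if (uni == 0) return(1)
  sum(s$a & s$b) / uni
}

#' Relative success rate of follicle counting
#'
#' `RSR = 1 - |F_GT - F_P| / F_GT`, the agreement between the ground-truth
#' and predicted follicle counts (at most 1; negative when the error
#' exceeds the true count).
#'
#' @param fGt ground-truth follicle count (>= 1).
#' @param fP predicted follicle count (>= 0).
#' @return The relative success rate (unrounded; tables conventionally
#'   show two decimals).
#' @examples
#' round(rsr(3, 4), 2)  # 0.67
#' round(rsr(4, 6), 2)  # 0.50
#' @export
rsr <- function(fGt, fP) {
  if (any(fGt < 1)) stop("rsr is undefined for fGt = 0; need fGt >= 1")
  if (any(fP < 0)) stop("fP must be non-negative")
  1 - abs(fGt - fP) / fGt
}

#' Epidermal thickness
#'
#' Mean surface-to-DEJ distance over the valid, non-follicular columns,
#' scaled by the axial pixel pitch. Columns laterally intersecting any
#' surviving follicle component are excluded, so the thin (non-follicular)
#' epidermis is measured. Thickness is the boundary-to-boundary row
#' difference `dej - surface`.
#'
#' @param profile a [BoundaryProfile-class].
#' @param follicles optional [FollicleSet-class]; its components' columns
#'   are excluded.
#' @param axialPixelUm axial pixel pitch; with the default 1 the result is
#'   in pixel units.
#' @return Thickness in micrometres (or pixels).
#' @export
epidermalThickness <- function(profile, follicles = NULL, axialPixelUm = 1) {
  stopifnot(axialPixelUm > 0)
  use <- validColumns(profile)
  if (!is.null(follicles)) {
    for (co in follicleComponents(follicles))
      use[unique(co$pixels[, 2])] <- FALSE
  }
  if (!any(use)) stop("no valid non-follicular columns to measure")
  mean(dejRow(profile)[use] - surfaceRow(profile)[use]) * axialPixelUm
}

#' RMSE and MAE between thickness series
#'
#' Root-mean-square error `sqrt(mean((G - P)^2))` and mean absolute error
#' `mean(|G - P|)` between per-image ground-truth and predicted epidermal
#' thicknesses; RMSE >= MAE always.
#'
#' @param g,p numeric vectors of equal length (per-image thicknesses).
#' @return Named numeric vector `c(rmse =, mae =)`.
#' @examples
#' thicknessErrors(c(0, 0), c(3, 4))  # rmse sqrt(12.5), mae 3.5
#' @export
thicknessErrors <- function(g, p) {
  if (length(g) != length(p)) stop("g and p must have equal length")
  if (length(g) == 0L) stop("need at least one pair")
  c(rmse = sqrt(mean((g - p)^2)), mae = mean(abs(g - p)))
}

#' Aggregate per-image metrics into a study report
#'
#' Builds per-patient and cohort summaries from a per-image table: mean
#' and sd of Dice/Jaccard per layer over images, per-patient follicle
#' counts with RSR, per-patient thickness mean/sd plus RMSE and MAE over
#' that patient's images, and unweighted cohort means of the per-patient
#' values.
#'
#' @param perImage data.frame with columns `patient` and any of
#'   `diceEpi`, `diceDermis`, `jaccardEpi`, `jaccardDermis`, `etGt`,
#'   `etPred`.
#' @param counts optional data.frame with columns `patient`, `fGt`, `fP`
#'   (one row per patient).
#' @return List with `perImage`, `perPatient` and `cohort` (a named list
#'   of cohort means).
#' @export
aggregateReport <- function(perImage, counts = NULL) {
  stopifnot("patient" %in% names(perImage))
  pats <- unique(perImage$patient)
  metricCols <- intersect(c("diceEpi", "diceDermis", "jaccardEpi",
                            "jaccardDermis"), names(perImage))
  perPatient <- data.frame(patient = pats, stringsAsFactors = FALSE)
  for (mc in metricCols) {
    perPatient[[paste0(mc, "Mean")]] <- vapply(pats, function(p)
      mean(perImage[[mc]][perImage$patient == p]), numeric(1))
    perPatient[[paste0(mc, "Sd")]] <- vapply(pats, function(p)
      stats::sd(perImage[[mc]][perImage$patient == p]), numeric(1))
  }
  if (all(c("etGt", "etPred") %in% names(perImage))) {
    for (col in c("etGt", "etPred")) {
      perPatient[[paste0(col, "Mean")]] <- vapply(pats, function(p)
        mean(perImage[[col]][perImage$patient == p]), numeric(1))
      perPatient[[paste0(col, "Sd")]] <- vapply(pats, function(p)
        stats::sd(perImage[[col]][perImage$patient == p]), numeric(1))
    }
    err <- t(vapply(pats, function(p) {
      sel <- perImage$patient == p
      thicknessErrors(perImage$etGt[sel], perImage$etPred[sel])
    }, numeric(2)))
    perPatient$rmse <- err[, "rmse"]
    perPatient$mae <- err[, "mae"]
  }
  if (!is.null(counts)) {
    stopifnot(all(c("patient", "fGt", "fP") %in% names(counts)))
    m <- match(pats, counts$patient)
    perPatient$fGt <- counts$fGt[m]
    perPatient$fP <- counts$fP[m]
    perPatient$rsr <- rsr(perPatient$fGt, perPatient$fP)
  }
  cohort <- list()
  for (col in setdiff(names(perPatient), "patient"))
    if (is.numeric(perPatient[[col]]))
      cohort[[paste0("mean_", col)]] <- mean(perPatient[[col]])
  list(perImage = perImage, perPatient = perPatient, cohort = cohort)
}

#' Published reference tables from the nine-subject study cohort
#'
#' Convenience accessors for the published per-patient reference values
#' shipped with the package: follicle counts of ground truth and method
#' with the reported relative success rate, and the per-patient epidermal
#' thickness summaries with reported RMSE and MAE (micrometres).
#'
#' @return A data.frame (`referenceFollicleCounts`: columns `patient`,
#'   `fGt`, `fP`, `rsrReported`; `referenceThicknessErrors`: columns
#'   `patient`, `etGtMean`, `etGtSd`, `etPredMean`, `etPredSd`, `rmseUm`,
#'   `maeUm`).
#' @export
referenceFollicleCounts <- function() {
  utils::read.csv(system.file("extdata", "reference_follicle_counts.csv",
                              package = "octskinseg"))
}

#' @rdname referenceFollicleCounts
#' @export
referenceThicknessErrors <- function() {
  utils::read.csv(system.file("extdata", "reference_thickness_errors.csv",
                              package = "octskinseg"))
}
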