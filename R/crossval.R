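# Patient-wise external K-fold cross-validation with internal
# leave-one-fold-out validation, and ensemble-averaged prediction.

#' Build a patient-wise fold plan
#'
#' Creates K external folds, one per patient (K defaults to the number of
#' patients). For each external test fold, every remaining patient serves
#' once as the internal validation fold while the others train, giving
#' K * (K - 1) models in total. A patient never appears in the training or
#' validation set of a model that is evaluated on them.
#'
#' @param x an [OCTCohort-class] or a character vector of patient ids.
#' @param K number of folds; must not exceed the number of distinct
#'   patients.
#' @return A [FoldPlan-class].
#' @examples
#' plan <- makeFolds(sprintf("P%02d", 1:9))
#' modelCount(plan)  # 9 * 8 = 72
#' @export
makeFolds <- function(x, K = NULL) {
  pats <- if (is(x, "OCTCohort")) patientIds(x) else unique(as.character(x))
  if (is.null(K)) K <- length(pats)
  if (length(pats) < K)
    stop(sprintf("need at least K = %d distinct patients, found %d",
                 K, length(pats)))
  pats <- pats[seq_len(K)]
  assignments <- lapply(pats, function(test) {
    others <- setdiff(pats, test)
    list(test = test,
         models = lapply(others, function(val) {
           train <- setdiff(others, val)
           # smallest case K = 2: the single remaining patient both trains
           # and validates the one model of the fold
           if (length(train) == 0L) train <- val
           list(val = val, train = train)
         }))
  })
  new("FoldPlan", patients = pats, assignments = assignments)
}

#' Serialize / read a fold plan as JSON
#'
#' @param plan a [FoldPlan-class].
#' @param path JSON file path.
#' @return `writeFoldPlan` invisibly returns `path`; `readFoldPlan`
#'   returns the [FoldPlan-class].
#' @export
writeFoldPlan <- function(plan, path) {
  jsonlite::write_json(list(patients = plan@patients,
                            assignments = plan@assignments),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeFoldPlan
#' @export
readFoldPlan <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  assignments <- lapply(o$assignments, function(a)
    list(test = a$test,
         models = lapply(a$models, function(m)
           list(val = m$val, train = unlist(m$train)))))
  new("FoldPlan", patients = unlist(o$patients), assignments = assignments)
}

#' Ensemble prediction for one image
#'
#' Each model predicts the image by tiled inference (fixed-width slices,
#' overlap-averaged recombination); the ensemble probability map is the
#' arithmetic mean over the per-model maps, taken before any argmax, and is
#' invariant to the order of the models.
#'
#' @param models non-empty list of [ModelState-class] objects (the K-1
#'   models of the test patient's external fold).
#' @param image an [OCTImage-class] at the common working dimension.
#' @param sliceWidth inference slice width; images wider than the slice are
#'   predicted as two overlapping slices. Defaults to 512, or the full
#'   image width when the image is narrower.
#' @return A [ProbabilityMap-class].
#' @export
ensemblePredict <- function(models, image, sliceWidth = 512L) {
  if (length(models) == 0L) stop("model list must not be empty")
  w <- ncol(pixels(image))
  sliceWidth <- min(as.integer(sliceWidth), w)
  slices <- splitForInference(image, sliceWidth)
  acc <- NULL
  for (m in models) {
    maps <- lapply(slices, function(s)
      list(probs = predictProbs(m, s$image), offset = s$offset))
    p <- probs(recombineSlices(maps, w))
    acc <- if (is.null(acc)) p else acc + p
  }
  ProbabilityMap(acc / length(models))
}

#' Hard labels from a probability map
#'
#' Per-pixel argmax over the class axis; ties are broken deterministically
#' in favor of the lowest class index.
#'
#' @param prob a [ProbabilityMap-class] (or rows x cols x classes array).
#' @return A [LabelMask-class].
#' @examples
#' p <- array(c(0.4, 0.4, 0.2), c(1, 1, 3))
#' labels2d(argmaxLabels(p))  # 0 by the tie rule
#' @export
argmaxLabels <- function(prob) {
  p <- if (is(prob, "ProbabilityMap")) probs(prob) else prob
  d <- dim(p)
  lab <- matrix(0L, d[1], d[2])
  best <- p[, , 1L]
  for (l in 2:d[3]) {
    m <- p[, , l] > best  # strict: earlier class wins ties
    best[m] <- p[, , l][m]
    lab[m] <- l - 1L
  }
  LabelMask(lab)
}
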