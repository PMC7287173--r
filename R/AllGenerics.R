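# Accessors and show methods. Slots are never reached into from user code.

#' @rdname OCTImage-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname OCTImage-class
#' @export
setMethod("pixels", "OCTImage", function(x) x@pixels)

#' @rdname OCTImage-class
#' @export
setGeneric("axialPixelUm", function(x) standardGeneric("axialPixelUm"))

#' @rdname OCTImage-class
#' @export
setMethod("axialPixelUm", "OCTImage", function(x) x@axialPixelUm)

#' @rdname OCTImage-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname OCTImage-class
#' @export
setMethod("sourceId", "OCTImage", function(x) x@sourceId)

#' @rdname LabelMask-class
#' @param x a `LabelMask`.
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))

#' @rdname LabelMask-class
#' @export
setMethod("labels2d", "LabelMask", function(x) x@labels)

#' @rdname ProbabilityMap-class
#' @param x a `ProbabilityMap`.
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname ProbabilityMap-class
#' @export
setMethod("probs", "ProbabilityMap", function(x) x@probs)

#' @rdname BoundaryProfile-class
#' @param x a `BoundaryProfile`.
#' @export
setGeneric("surfaceRow", function(x) standardGeneric("surfaceRow"))

#' @rdname BoundaryProfile-class
#' @export
setMethod("surfaceRow", "BoundaryProfile", function(x) x@surface)

#' @rdname BoundaryProfile-class
#' @export
setGeneric("dejRow", function(x) standardGeneric("dejRow"))

#' @rdname BoundaryProfile-class
#' @export
setMethod("dejRow", "BoundaryProfile", function(x) x@dej)

#' @rdname BoundaryProfile-class
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' @rdname BoundaryProfile-class
#' @export
setMethod("baseline", "BoundaryProfile", function(x) x@bl)

#' @rdname BoundaryProfile-class
#' @export
setGeneric("correctedBaseline", function(x) standardGeneric("correctedBaseline"))

#' @rdname BoundaryProfile-class
#' @export
setMethod("correctedBaseline", "BoundaryProfile", function(x) x@blc)

#' @rdname BoundaryProfile-class
#' @export
setGeneric("validColumns", function(x) standardGeneric("validColumns"))

#' @rdname BoundaryProfile-class
#' @export
setMethod("validColumns", "BoundaryProfile", function(x) x@valid)

#' @rdname FollicleSet-class
#' @param x a `FollicleSet`.
#' @export
setGeneric("follicleComponents", function(x) standardGeneric("follicleComponents"))

#' @rdname FollicleSet-class
#' @export
setMethod("follicleComponents", "FollicleSet", function(x) x@components)

#' @rdname FollicleSet-class
#' @export
setGeneric("follicleAreas", function(x) standardGeneric("follicleAreas"))

#' @rdname FollicleSet-class
#' @export
setMethod("follicleAreas", "FollicleSet", function(x)
  vapply(x@components, function(co) as.numeric(co$area), numeric(1)))

#' @rdname FollicleSet-class
#' @export
setGeneric("openingThreshold", function(x) standardGeneric("openingThreshold"))

#' @rdname FollicleSet-class
#' @export
setMethod("openingThreshold", "FollicleSet", function(x) x@alpha)

#' Number of elements
#'
#' `length` of a `FollicleSet` is its component count; of an `OCTCohort`,
#' its image count.
#' @param x the object.
#' @rdname length-methods
#' @export
setMethod("length", "FollicleSet", function(x) length(x@components))

#' @rdname length-methods
#' @export
setMethod("length", "OCTCohort", function(x) length(x@records))

#' @rdname OCTCohort-class
#' @param x an `OCTCohort`.
#' @export
setGeneric("cohortRecords", function(x) standardGeneric("cohortRecords"))

#' @rdname OCTCohort-class
#' @export
setMethod("cohortRecords", "OCTCohort", function(x) x@records)

#' @rdname OCTCohort-class
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname OCTCohort-class
#' @export
setMethod("patientIds", "OCTCohort", function(x)
  unique(vapply(x@records, function(r) r$patientId, character(1))))

#' @rdname FoldPlan-class
#' @param x a `FoldPlan`.
#' @export
setMethod("patientIds", "FoldPlan", function(x) x@patients)

#' @rdname FoldPlan-class
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname FoldPlan-class
#' @export
setMethod("foldAssignments", "FoldPlan", function(x) x@assignments)

#' @rdname FoldPlan-class
#' @export
setGeneric("modelCount", function(x) standardGeneric("modelCount"))

#' @rdname FoldPlan-class
#' @export
setMethod("modelCount", "FoldPlan", function(x)
  sum(vapply(x@assignments, function(a) length(a$models), integer(1))))

#' @rdname ModelState-class
#' @param x a `ModelState`.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname ModelState-class
#' @export
setMethod("trainingHistory", "ModelState", function(x) x@history)

#' @rdname ModelState-class
#' @export
setGeneric("networkConfig", function(x) standardGeneric("networkConfig"))

#' @rdname ModelState-class
#' @export
setMethod("networkConfig", "ModelState", function(x) x@config)

#' @rdname ModelState-class
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))

#' @rdname ModelState-class
#' @export
setMethod("bestEpoch", "ModelState", function(x) x@bestEpoch)

setMethod("show", "OCTImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("OCTImage %dx%d (rows x cols), axial pitch %s um/px, source '%s'\n",
              d[1], d[2],
              ifelse(is.na(object@axialPixelUm), "unknown",
                     format(object@axialPixelUm)),
              object@sourceId))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf("LabelMask %dx%d; pixels per class 0/1/2: %d/%d/%d\n",
              d[1], d[2], tab[1], tab[2], tab[3]))
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbabilityMap %dx%d over %d classes\n", d[1], d[2], d[3]))
})

setMethod("show", "BoundaryProfile", function(object) {
  cat(sprintf("BoundaryProfile over %d columns (%d valid); baseline %s\n",
              length(object@surface), sum(object@valid),
              if (is.null(object@blc)) {
                if (is.null(object@bl)) "not computed" else "uncorrected"
              } else "corrected"))
})

setMethod("show", "FollicleSet", function(object) {
  cat(sprintf("FollicleSet with %d component(s), opening threshold %.1f px\n",
              length(object@components), object@alpha))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %dx%d px, surface %.0f, epidermis %.0f px,",
                     " %d follicle(s) depth %.0f px, speckle %.2f, seed %d\n"),
              object@heightPx, object@widthPx, object@surfaceDepthPx,
              object@epidermisThicknessPx, object@nFollicles,
              object@follicleDepthPx, object@speckleLevel, object@seed))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(paste0("NetworkConfig: %d block(s), %d filters %dx%d, ",
                     "batch %d, momentum %.2f, lr %.4g (x%.2g every %d epochs), ",
                     "%d epochs\n"),
              object@nBlocks, object@filtersPerConv, object@kernelShape[1],
              object@kernelShape[2], object@batchSize, object@momentum,
              object@initialLr, object@lrDropFactor, object@lrDropEveryEpochs,
              object@epochs))
})

setMethod("show", "ModelState", function(object) {
  cat(sprintf("ModelState: %s; best epoch %d of %d\n",
              if (nrow(object@history)) "trained" else "untrained",
              object@bestEpoch, nrow(object@history)))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d patient folds, %d models\n",
              length(object@patients), modelCount(object)))
})

setMethod("show", "OCTCohort", function(object) {
  cat(sprintf("OCTCohort: %d image(s) from %d patient(s)\n",
              length(object@records), length(patientIds(object))))
})
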