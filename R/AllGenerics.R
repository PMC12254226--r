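#' @name accessors
#' @title Accessors for amyloidCRF S4 objects
#' @description Slot accessors for [CRFSlide-class], [Morphometry-class],
#'   [TileSet-class], [FoldPlan-class], [ConfusionMatrix-class] and
#'   [MetricReport-class]. Use these instead of `@`.
#' @param object an amyloidCRF S4 object.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("tritc", function(object) standardGeneric("tritc"))
#' @rdname accessors
#' @export
setGeneric("scramble", function(object) standardGeneric("scramble"))
#' @rdname accessors
#' @export
setGeneric("brightfield", function(object) standardGeneric("brightfield"))
#' @rdname accessors
#' @export
setGeneric("truthAmyloid", function(object) standardGeneric("truthAmyloid"))
#' @rdname accessors
#' @export
setGeneric("truthTissue", function(object) standardGeneric("truthTissue"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))
#' @rdname accessors
#' @export
setGeneric("slideLabel", function(object) standardGeneric("slideLabel"))
#' @rdname accessors
#' @export
setGeneric("burden", function(object) standardGeneric("burden"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(object) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("folds", function(object) standardGeneric("folds"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setMethod("tritc", "CRFSlide", function(object) object@tritc)
#' @rdname accessors
#' @export
setMethod("scramble", "CRFSlide", function(object) object@scramble)
#' @rdname accessors
#' @export
setMethod("brightfield", "CRFSlide", function(object) object@brightfield)
#' @rdname accessors
#' @export
setMethod("truthAmyloid", "CRFSlide", function(object) object@truthAmyloid)
#' @rdname accessors
#' @export
setMethod("truthTissue", "CRFSlide", function(object) object@truthTissue)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CRFSlide", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "TileSet", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("slideId", "CRFSlide", function(object) object@slideId)
#' @rdname accessors
#' @export
setMethod("caseId", "CRFSlide", function(object) object@caseId)
#' @rdname accessors
#' @export
setMethod("slideLabel", "CRFSlide", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("burden", "Morphometry", function(object) object@burden)
#' @rdname accessors
#' @export
setMethod("manifest", "TileSet", function(object) object@manifest)
#' @rdname accessors
#' @export
setMethod("folds", "FoldPlan", function(object) object@folds)
#' @rdname accessors
#' @export
setMethod("metricValues", "MetricReport", function(object) object@metrics)
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionMatrix", function(object)
  c(tp = object@tp, tn = object@tn, fp = object@fp, fn = object@fn))

setMethod("show", "CRFSlide", function(object) {
  d <- dim(object@tritc)
  cat(sprintf(
    "CRFSlide %s (case %s, %s): %d x %d px @ %.4f um/px%s\n",
    object@slideId, object@caseId, object@label, d[1], d[2],
    object@pixelSizeUm,
    if (!is.null(object@truthAmyloid)) " [with ground truth]" else ""))
})

setMethod("show", "Morphometry", function(object) {
  cat(sprintf(
    "Morphometry: burden %.4f (%d / %d px), %d components\n",
    object@burden, object@amyloidPx, object@tissuePx, object@nComponents))
})

setMethod("show", "TileSet", function(object) {
  m <- object@manifest
  cat(sprintf(
    "TileSet: %d tiles (%d x %d px), %d slides, %d cases; %d positive\n",
    nrow(m), object@sizePx, object@sizePx, length(unique(m$slideId)),
    length(unique(m$caseId)), sum(m$label == "positive")))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds over %d cases (seed %d)\n",
              object@k, length(object@caseIds), object@seed))
  f1 <- object@folds[[1]]
  cat(sprintf("  fold 1: %d train / %d val / %d test cases\n",
              length(f1$train), length(f1$val), length(f1$test)))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP %d, TN %d, FP %d, FN %d (n = %d)\n",
              object@tp, object@tn, object@fp, object@fn,
              object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "MetricReport", function(object) {
  v <- object@metrics
  txt <- vapply(seq_along(v), function(i) {
    if (is.na(v[i])) sprintf("%s = undefined", names(v)[i])
    else sprintf("%s = %.2f", names(v)[i], v[i])
  }, character(1))
  cat("MetricReport (n =", object@n, "):\n ", paste(txt, collapse = ", "),
      "\n")
})
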