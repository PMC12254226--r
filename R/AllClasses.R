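#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib amyloidCRF, .registration = TRUE
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Paired-channel Congo red fluorescence slide
#'
#' Container for one digitized slide: the Texas Red (TRITC) fluorescence
#' channel that captures Congo-red-bound amyloid, the "scramble"
#' autofluorescence channel of the same physical slide, and the aligned
#' brightfield RGB image. All rasters live on the same pixel grid, so masks
#' and annotations transfer between them without co-registration. Synthetic
#' slides additionally carry ground-truth amyloid and tissue masks.
#'
#' @slot tritc numeric matrix in \[0, 1\]; dye fluorescence channel.
#' @slot scramble numeric matrix in \[0, 1\]; tissue autofluorescence channel.
#' @slot brightfield numeric H x W x 3 array in \[0, 1\].
#' @slot pixelSizeUm positive scalar, microns per pixel.
#' @slot slideId,caseId character identifiers.
#' @slot label slide diagnosis: "positive", "negative" or "unknown".
#' @slot truthAmyloid,truthTissue optional ground-truth binary masks
#'   (synthetic slides only; `NULL` for real data).
#' @slot meta list of free-form metadata (e.g. the generating parameters).
#' @exportClass CRFSlide
setClass("CRFSlide",
  representation(
    tritc = "matrix", scramble = "matrix", brightfield = "array",
    pixelSizeUm = "numeric", slideId = "character", caseId = "character",
    label = "character", truthAmyloid = "matrixOrNULL",
    truthTissue = "matrixOrNULL", meta = "list"
  )
)

setValidity("CRFSlide", function(object) {
  d <- dim(object@tritc)
  msgs <- character()
  if (!identical(dim(object@scramble), d))
    msgs <- c(msgs, "tritc and scramble shapes differ")
  if (length(dim(object@brightfield)) != 3L ||
      !identical(dim(object@brightfield)[1:2], d) ||
      dim(object@brightfield)[3] != 3L)
    msgs <- c(msgs, "brightfield must be H x W x 3 on the same grid")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msgs <- c(msgs, "pixelSizeUm must be a positive scalar")
  if (!object@label %in% c("positive", "negative", "unknown"))
    msgs <- c(msgs, "label must be positive/negative/unknown")
  for (nm in c("truthAmyloid", "truthTissue")) {
    m <- slot(object, nm)
    if (!is.null(m) && !identical(dim(m), d))
      msgs <- c(msgs, sprintf("%s shape differs from channels", nm))
  }
  if (!is.null(object@truthAmyloid) && !is.null(object@truthTissue) &&
      any(object@truthAmyloid > 0 & object@truthTissue == 0))
    msgs <- c(msgs, "truthAmyloid must be contained in truthTissue")
  if (length(msgs)) msgs else TRUE
})

#' Slide morphometry
#'
#' Pixel-count morphometry of a segmented slide. Amyloid burden is the area
#' covered by deposits divided by the whole tissue area; connected
#' components are 8-connected.
#'
#' @slot amyloidPx,tissuePx integer pixel counts.
#' @slot burden `amyloidPx / tissuePx`, in \[0, 1\].
#' @slot nComponents number of 8-connected deposit components.
#' @slot componentAreasPx integer vector of per-component areas.
#' @exportClass Morphometry
setClass("Morphometry",
  representation(
    amyloidPx = "integer", tissuePx = "integer", burden = "numeric",
    nComponents = "integer", componentAreasPx = "integer"
  )
)

setValidity("Morphometry", function(object) {
  msgs <- character()
  if (object@tissuePx <= 0L) msgs <- c(msgs, "tissuePx must be positive")
  if (object@amyloidPx > object@tissuePx)
    msgs <- c(msgs, "amyloidPx cannot exceed tissuePx")
  if (abs(object@burden - object@amyloidPx / object@tissuePx) > 1e-12)
    msgs <- c(msgs, "burden must equal amyloidPx / tissuePx")
  if (length(msgs)) msgs else TRUE
})

#' Tile collection
#'
#' A set of 256 x 256 brightfield tiles with matched binary deposit masks
#' and weak labels derived from the slide-level segmentation. The manifest
#' keeps one row per tile (ids, grid origin, label, variant, slide truth).
#'
#' @slot images list of H x W x 3 arrays.
#' @slot masks list of binary matrices congruent with the images.
#' @slot manifest data.frame with columns tileId, slideId, caseId, row, col,
#'   label, variant, slideLabel.
#' @slot sizePx tile side in pixels (256 by default).
#' @slot pixelSizeUm microns per pixel.
#' @exportClass TileSet
setClass("TileSet",
  representation(
    images = "list", masks = "list", manifest = "data.frame",
    sizePx = "integer", pixelSizeUm = "numeric"
  )
)

setValidity("TileSet", function(object) {
  msgs <- character()
  n <- nrow(object@manifest)
  if (length(object@images) != n || length(object@masks) != n)
    msgs <- c(msgs, "images/masks length must match manifest rows")
  need <- c("tileId", "slideId", "caseId", "row", "col", "label", "variant")
  miss <- setdiff(need, names(object@manifest))
  if (length(miss))
    msgs <- c(msgs, paste("manifest missing columns:",
                          paste(miss, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Case-level cross-validation plan
#'
#' Assignment of every case to train/validation/test for each of `k` folds.
#' Splits are made at the case level so that no patient contributes tiles
#' to more than one role within a fold (no leakage); every case appears in
#' exactly one test set across the folds.
#'
#' @slot caseIds character vector of all case ids.
#' @slot labels named character vector of case labels.
#' @slot k number of folds.
#' @slot seed integer seed the plan was drawn with.
#' @slot folds list of length `k`; each element a list with character
#'   vectors `train`, `val`, `test`.
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(
    caseIds = "character", labels = "character", k = "integer",
    seed = "integer", folds = "list"
  )
)

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (length(object@folds) != object@k)
    msgs <- c(msgs, "folds list length must equal k")
  tested <- character()
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    roles <- c(f$train, f$val, f$test)
    if (!setequal(roles, object@caseIds))
      msgs <- c(msgs, sprintf("fold %d does not cover all cases", i))
    if (anyDuplicated(roles))
      msgs <- c(msgs, sprintf("fold %d assigns a case to two roles", i))
    tested <- c(tested, f$test)
  }
  if (!setequal(tested, object@caseIds))
    msgs <- c(msgs, "every case must appear in a test set")
  if (length(msgs)) msgs else TRUE
})

#' Slide-level confusion matrix
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0L)) return("counts must be nonnegative")
  if (sum(v) == 0L) return("confusion matrix is empty")
  TRUE
})

#' Bundle of evaluation metrics
#'
#' Named metric values with an explicit defined/undefined flag per metric:
#' a metric whose denominator vanishes (e.g. sensitivity with no positive
#' cases) is reported as `NA` and flagged, never silently zero.
#'
#' @slot metrics named numeric vector (NA where undefined).
#' @slot defined named logical vector, parallel to `metrics`.
#' @slot n problem size the metrics were computed on.
#' @slot provenance free-form list (fold id, split, counts...).
#' @exportClass MetricReport
setClass("MetricReport",
  representation(metrics = "numeric", defined = "logical", n = "integer",
                 provenance = "list")
)

setValidity("MetricReport", function(object) {
  if (!identical(names(object@metrics), names(object@defined)))
    return("metrics and defined must have identical names")
  if (any(is.na(object@metrics) & object@defined))
    return("NA metric marked as defined")
  TRUE
})
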