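# Fluorescence-subtraction amyloid segmentation.
#
# The slide is acquired twice on the same pixel grid: once through a Texas
# Red (TRITC) filter that captures Congo-red-bound amyloid, and once
# through a "scramble" filter that captures tissue autofluorescence only.
# Subtracting the autofluorescence channel from the TRITC channel removes
# signal common to both -- plain myocardium and fibrotic confounders --
# leaving the one-sided amyloid excess, which is then binarized within the
# tissue mask and cleaned of sub-resolution speckle.

#' Segmentation parameters
#'
#' @param binarizeMethod `"otsu"` (parameter-free, computed within the
#'   tissue mask; the default) or `"fixed"`.
#' @param fixedThreshold threshold on the subtracted image in (0, 1);
#'   required iff `binarizeMethod = "fixed"`.
#' @param minObjectPx minimum 8-connected amyloid component size kept, in
#'   pixels. The default 16 px corresponds to ~3 um^2 at 0.4415 um/px:
#'   speckle removal that keeps minimal vascular-scale deposits.
#' @param minSignal floor on the Otsu threshold of the subtracted image
#'   (default 0.1, ~26/255 on an 8-bit scale). On a slide without deposits
#'   Otsu has no second mode to find and would otherwise split the noise
#'   distribution in half; subtraction residue below this floor is
#'   indistinguishable from autofluorescence noise. Ignored for
#'   `binarizeMethod = "fixed"`.
#' @param tissueMethod `"otsu_on_fluorescence"` (default): threshold the
#'   pixelwise maximum of the scramble and TRITC channels --
#'   autofluorescence is a whole-tissue signal except where the bound dye
#'   dominates, so the maximum covers parenchyma and deposits alike.
#'   `"otsu_on_brightfield_sat"` uses the saturation of the brightfield
#'   image instead (for slides without usable fluorescence channels).
#' @param tissueMinObjectPx minimum tissue component size kept.
#' @return List of class `segParams`.
#' @export
segParams <- function(binarizeMethod = c("otsu", "fixed"),
                      fixedThreshold = NULL, minObjectPx = 16L,
                      minSignal = 0.1,
                      tissueMethod = c("otsu_on_fluorescence",
                                       "otsu_on_brightfield_sat"),
                      tissueMinObjectPx = 256L) {
  binarizeMethod <- match.arg(binarizeMethod)
  tissueMethod <- match.arg(tissueMethod)
  if (binarizeMethod == "fixed") {
    if (is.null(fixedThreshold) || fixedThreshold <= 0 ||
        fixedThreshold >= 1)
      stop("fixedThreshold in (0,1) is required when binarizeMethod = 'fixed'")
  } else if (!is.null(fixedThreshold)) {
    stop("fixedThreshold is only meaningful with binarizeMethod = 'fixed'")
  }
  structure(list(binarizeMethod = binarizeMethod,
                 fixedThreshold = fixedThreshold,
                 minObjectPx = as.integer(minObjectPx),
                 minSignal = minSignal,
                 tissueMethod = tissueMethod,
                 tissueMinObjectPx = as.integer(tissueMinObjectPx)),
            class = "segParams")
}

#' Subtract the autofluorescence channel from the TRITC channel
#'
#' Pixelwise `max(tritc - scramble, 0)`. The difference is clipped at zero
#' (not absolute-valued): subtracting autofluorescence targets the
#' one-sided dye excess, and pixels brighter in the scramble channel carry
#' no amyloid evidence.
#'
#' @param tritc,scramble numeric matrices of identical shape, values in
#'   \[0, 1\].
#' @return Difference matrix of the same shape.
#' @export
subtractChannels <- function(tritc, scramble) {
  if (!identical(dim(tritc), dim(scramble)))
    stop("tritc and scramble shapes differ")
  pmax(tritc - scramble, 0)
}

#' Detect the tissue region
#'
#' Otsu-thresholds the configured source channel (scramble
#' autofluorescence by default -- a whole-tissue signal), fills enclosed
#' holes and removes components below `tissueMinObjectPx`. A constant
#' blank raster yields an empty mask with a warning, not an error.
#'
#' @param slide a [CRFSlide-class], or a plain matrix treated as the
#'   scramble channel.
#' @param params [segParams()].
#' @return Logical tissue mask.
#' @export
detectTissue <- function(slide, params = segParams()) {
  src <- if (is(slide, "CRFSlide")) {
    if (params$tissueMethod == "otsu_on_fluorescence")
      pmax(scramble(slide), tritc(slide))
    else {
      bf <- brightfield(slide) # saturation = 1 - min/max over channels
      mx <- pmax(bf[, , 1], bf[, , 2], bf[, , 3])
      mn <- pmin(bf[, , 1], bf[, , 2], bf[, , 3])
      s <- 1 - ifelse(mx > 0, mn / mx, 1)
      matrix(s, dim(bf)[1], dim(bf)[2])
    }
  } else as.matrix(slide)
  rng <- range(src)
  if (diff(rng) < 1e-8) { # constant image: no texture to threshold
    if (rng[1] <= 1e-8) {
      warning("blank channel: returning empty tissue mask")
      return(matrix(FALSE, nrow(src), ncol(src)))
    }
    return(matrix(TRUE, nrow(src), ncol(src)))
  }
  thr <- backgroundThreshold(src)
  mask <- src > thr
  if (any(mask)) {
    img <- EBImage::fillHull(EBImage::Image(mask * 1))
    mask <- EBImage::imageData(img) > 0.5
    mask <- removeSmall(mask, params$tissueMinObjectPx)
  }
  if (!any(mask)) warning("tissue detection produced an empty mask")
  mask
}

#' Segment amyloid deposits on the subtracted image
#'
#' Binarizes the subtracted image within the tissue mask (Otsu on the
#' in-tissue intensities by default, or a fixed threshold) and removes
#' 8-connected components smaller than `minObjectPx`. The result is always
#' contained in the tissue mask.
#'
#' @param diff subtracted image from [subtractChannels()].
#' @param tissue logical tissue mask of the same shape.
#' @param params [segParams()].
#' @return Logical amyloid mask.
#' @export
segmentAmyloid <- function(diff, tissue, params = segParams()) {
  if (!identical(dim(diff), dim(tissue)))
    stop("diff and tissue shapes differ")
  empty <- matrix(FALSE, nrow(diff), ncol(diff))
  if (!any(tissue)) return(empty)
  vals <- diff[tissue]
  thr <- if (params$binarizeMethod == "fixed") params$fixedThreshold
  else {
    t0 <- otsuThreshold(vals)
    if (is.na(t0)) return(empty) # constant difference: nothing to segment
    max(t0, params$minSignal)
  }
  mask <- diff > thr & tissue
  removeSmall(mask, params$minObjectPx)
}

#' Compute slide morphometry
#'
#' Exact pixel counts of the amyloid and tissue masks, the amyloid burden
#' (deposit area / tissue area) and the 8-connected component census.
#'
#' @param amyloid logical amyloid mask (clipped to tissue with a warning
#'   if it protrudes).
#' @param tissue logical tissue mask; an empty tissue mask is an error
#'   (burden undefined).
#' @return A [Morphometry-class].
#' @export
computeMorphometry <- function(amyloid, tissue) {
  if (!identical(dim(amyloid), dim(tissue)))
    stop("amyloid and tissue shapes differ")
  amyloid <- amyloid != 0; tissue <- tissue != 0
  if (!any(tissue)) stop("tissue mask is empty: burden undefined")
  if (any(amyloid & !tissue)) {
    warning("amyloid mask protrudes outside tissue; clipping")
    amyloid <- amyloid & tissue
  }
  lab <- labelComponents(amyloid)
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L]) else integer()
  aPx <- as.integer(sum(amyloid)); tPx <- as.integer(sum(tissue))
  new("Morphometry", amyloidPx = aPx, tissuePx = tPx,
      burden = aPx / tPx, nComponents = as.integer(length(areas)),
      componentAreasPx = as.integer(areas))
}

#' Transfer the amyloid mask onto the brightfield image
#'
#' Because both fluorescence channels and the brightfield image of one
#' slide share a single pixel grid, the mask transfers by identity -- no
#' co-registration. Renders the mask contours onto the brightfield image
#' and optionally writes the polygon annotation (GeoJSON).
#'
#' @param amyloid logical amyloid mask.
#' @param brightfield H x W x 3 array on the same grid (shape mismatch is
#'   an error; no resampling is attempted).
#' @param annotationPath optional path for [writeAnnotation()].
#' @param contourColor RGB triplet for the rendered contours.
#' @return List with `overlay` (H x W x 3 array) and `rings` (polygon
#'   list as from `maskToRings`); an empty mask returns the brightfield
#'   unchanged with zero rings.
#' @export
transferToBrightfield <- function(amyloid, brightfield,
                                  annotationPath = NULL,
                                  contourColor = c(0, 1, 0)) {
  d <- dim(brightfield)
  if (length(d) != 3L || !identical(d[1:2], dim(amyloid)))
    stop("amyloid mask and brightfield image are on different grids")
  rings <- maskToRings(amyloid)
  overlay <- brightfield
  if (length(rings)) {
    m <- amyloid != 0
    # contour pixels: foreground with at least one 4-neighbour background
    H <- d[1]; W <- d[2]
    shift <- function(mm, dr, dc) {
      out <- matrix(FALSE, H, W)
      rs <- max(1, 1 + dr):min(H, H + dr)
      cs <- max(1, 1 + dc):min(W, W + dc)
      out[rs, cs] <- mm[rs - dr, cs - dc]
      out
    }
    edge <- m & !(shift(m, 1, 0) & shift(m, -1, 0) &
                    shift(m, 0, 1) & shift(m, 0, -1))
    for (ch in 1:3) {
      pl <- overlay[, , ch]
      pl[edge] <- contourColor[ch]
      overlay[, , ch] <- pl
    }
  }
  if (!is.null(annotationPath)) writeAnnotation(amyloid, annotationPath)
  list(overlay = overlay, rings = rings)
}

#' Run the full subtraction segmentation on one slide
#'
#' Convenience wrapper: tissue detection, channel subtraction, amyloid
#' binarization and morphometry in one call.
#'
#' @param slide a [CRFSlide-class].
#' @param params [segParams()].
#' @return List with `tissue`, `diff`, `amyloid` and `morphometry`.
#' @examples
#' sl <- generateSlide(synthSpec(widthPx = 128, heightPx = 128,
#'                               targetBurden = 0.1, noiseSd = 0, seed = 2))
#' res <- segmentSlide(sl)
#' res$morphometry
#' @export
segmentSlide <- function(slide, params = segParams()) {
  tissue <- detectTissue(slide, params)
  dif <- subtractChannels(tritc(slide), scramble(slide))
  amy <- segmentAmyloid(dif, tissue, params)
  morph <- if (any(tissue)) computeMorphometry(amy, tissue) else NULL
  list(tissue = tissue, diff = dif, amyloid = amy, morphometry = morph)
}
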