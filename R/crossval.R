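# Case-level nested cross-validation: fold planning, HSV color
# augmentation, slide-level aggregation and the CV driver. Splits are made
# at the case (patient) level -- never at the tile or slide level -- so a
# patient's tiles can never leak between train, validation and test.

#' Build a case-level nested cross-validation plan
#'
#' k folds; within each fold the cases are split 80/10/10 into train,
#' validation and test. The test sets rotate so that every case is tested
#' exactly once across the folds; the validation set is the next test
#' block, and splits are stratified by case label (with an optional
#' secondary balancing key, e.g. specimen type).
#'
#' @param caseIds character vector of case ids.
#' @param labels parallel vector of case labels ("positive"/"negative").
#' @param k number of folds (default 10); must not exceed the number of
#'   cases.
#' @param seed integer; identical inputs and seed give an identical plan.
#' @param strata2 optional secondary key balanced within label strata.
#' @return A [FoldPlan-class].
#' @examples
#' plan <- makeFolds(sprintf("c%02d", 1:43),
#'                   rep(c("positive", "negative"), c(28, 15)),
#'                   k = 10, seed = 1)
#' plan
#' @export
makeFolds <- function(caseIds, labels, k = 10L, seed = 1L,
                      strata2 = NULL) {
  stopifnot(length(caseIds) == length(labels),
            !anyDuplicated(caseIds))
  k <- as.integer(k)
  if (length(caseIds) < k)
    stop("fewer cases (", length(caseIds), ") than folds (", k, ")")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to stratify folds")
  withSeed(seed, {
    # round-robin fold assignment within each label stratum spreads the
    # classes (and optionally specimen types) evenly over folds
    fid <- integer(length(caseIds))
    offset <- 0L
    for (lv in sort(unique(labels))) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      if (!is.null(strata2))
        idx <- idx[order(strata2[idx])] # stable: keeps the shuffle inside
      fid[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
    foldList <- lapply(seq_len(k), function(i) {
      testIds <- caseIds[fid == i]
      valFold <- if (i == k) 1L else i + 1L
      valIds <- caseIds[fid == valFold]
      list(train = setdiff(caseIds, c(testIds, valIds)),
           val = valIds, test = testIds)
    })
    new("FoldPlan", caseIds = as.character(caseIds),
        labels = stats::setNames(as.character(labels),
                                 as.character(caseIds)),
        k = k, seed = as.integer(seed), folds = foldList)
  })
}

#' Color augmentation parameters
#'
#' HSV-space jitter addressing the high stain-to-stain color variability
#' of Congo red brightfield slides. With all ranges degenerate the
#' transform is the identity.
#'
#' @param hueShiftMax maximum absolute hue shift (hue on \[0, 1\]).
#' @param saturationScaleRange,valueScaleRange multiplicative ranges.
#' @return List of class `augmentParams`.
#' @export
augmentParams <- function(hueShiftMax = 0.05,
                          saturationScaleRange = c(0.7, 1.3),
                          valueScaleRange = c(0.8, 1.2)) {
  stopifnot(hueShiftMax >= 0,
            saturationScaleRange[1] <= saturationScaleRange[2],
            valueScaleRange[1] <= valueScaleRange[2])
  structure(list(hueShiftMax = hueShiftMax,
                 saturationScaleRange = saturationScaleRange,
                 valueScaleRange = valueScaleRange),
            class = "augmentParams")
}

# Vectorized HSV -> RGB (h, s, v on [0,1]); inverse of grDevices::rgb2hsv.
hsv2rgbMat <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Apply HSV color jitter to a tile image
#'
#' Draws one hue shift, one saturation scale and one value scale per call
#' (from the caller's RNG stream) and applies them to the whole tile;
#' output is clipped to \[0, 1\].
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param params [augmentParams()].
#' @return Augmented image of the same shape.
#' @export
augmentColor <- function(img, params = augmentParams()) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  dh <- stats::runif(1, -params$hueShiftMax, params$hueShiftMax)
  ds <- stats::runif(1, params$saturationScaleRange[1],
                     params$saturationScaleRange[2])
  dv <- stats::runif(1, params$valueScaleRange[1],
                     params$valueScaleRange[2])
  if (dh == 0 && ds == 1 && dv == 1) return(img)
  d <- dim(img)
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  out <- hsv2rgbMat(hsv[1, ] + dh, clip01(hsv[2, ] * ds),
                    clip01(hsv[3, ] * dv))
  array(clip01(c(out[, 1], out[, 2], out[, 3])), d)
}

#' Aggregate tile probabilities into a slide-level prediction
#'
#' The slide probability is the arithmetic mean of its tile
#' probabilities; the slide is called positive when the mean is strictly
#' greater than the threshold (a mean of exactly 0.5 is negative).
#'
#' @param tileProbs numeric vector of tile probabilities (>= 1).
#' @param threshold decision threshold (default 0.5).
#' @return List with `slideProbability` and `predictedLabel`.
#' @examples
#' aggregateSlide(c(1, 1, 0, 0)) # mean 0.5 -> negative under strict >
#' @export
aggregateSlide <- function(tileProbs, threshold = 0.5) {
  if (length(tileProbs) == 0L) stop("no tile probabilities to aggregate")
  p <- mean(tileProbs)
  list(slideProbability = p,
       predictedLabel = if (p > threshold) "positive" else "negative")
}

#' Permute labels of a tiled cohort (permutation nulls)
#'
#' `permuteCaseLabels` reassigns the case-level diagnosis labels by
#' permutation and propagates the permuted label to every tile of the
#' case. Note that under this case-coherent null a cross-validated score
#' is *pessimistically biased* on small cohorts: whatever chance majority
#' pairing a fold's model learns from its training cases is
#' anti-correlated with the held-out cases (labels are permuted without
#' replacement), and flipping all labels leaves the score invariant, so
#' the bias does not cancel. `permuteTileLabels` shuffles the labels at
#' the tile level instead, severing the image-label link entirely; this
#' is the null under which cross-validated AUC genuinely concentrates at
#' chance.
#'
#' @param tileset a [TileSet-class].
#' @param seed integer seed.
#' @return A [TileSet-class] with permuted labels.
#' @export
permuteCaseLabels <- function(tileset, seed = 1L) {
  man <- manifest(tileset)
  caseLab <- unique(man[, c("caseId", "slideLabel")])
  withSeed(seed, {
    perm <- caseLab$slideLabel[sample.int(nrow(caseLab))]
  })
  newLab <- stats::setNames(perm, caseLab$caseId)
  man$slideLabel <- unname(newLab[man$caseId])
  man$label <- man$slideLabel
  new("TileSet", images = tileset@images, masks = tileset@masks,
      manifest = man, sizePx = tileset@sizePx,
      pixelSizeUm = tileset@pixelSizeUm)
}

#' @rdname permuteCaseLabels
#' @export
permuteTileLabels <- function(tileset, seed = 1L) {
  man <- manifest(tileset)
  withSeed(seed, {
    man$label <- man$label[sample.int(nrow(man))]
  })
  new("TileSet", images = tileset@images, masks = tileset@masks,
      manifest = man, sizePx = tileset@sizePx,
      pixelSizeUm = tileset@pixelSizeUm)
}
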