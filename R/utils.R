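# Shared numerical helpers.

# Evaluate `expr` under a fixed RNG seed and restore the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Otsu threshold of a set of intensities
#'
#' Histogram-based Otsu threshold (maximum between-class variance) computed
#' on an arbitrary set of pixel values, so it can be restricted to the
#' pixels inside a region of interest such as the tissue mask.
#'
#' @param x numeric vector of intensities in `range`.
#' @param nbins number of histogram bins (default 256, the 8-bit convention).
#' @param range intensity range spanned by the histogram.
#' @return Scalar threshold; pixels strictly above it are foreground.
#'   `NA` when the values are (near-)constant and no threshold separates
#'   two classes.
#' @export
otsuThreshold <- function(x, nbins = 256L, range = c(0, 1)) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) < 1e-8) return(NA_real_)
  breaks <- seq(range[1], range[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  # between-class variance for thresholds after each bin
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (muT * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)
  breaks[k + 1L]
}

# Background/foreground threshold for fluorescence tissue detection.
# Hierarchical: a first linear-scale Otsu strips bright minority modes
# (deposits, fibrotic autofluorescence); a second Otsu in log-intensity
# below that split separates dark background from dim tissue
# autofluorescence (fluorescence contrast is multiplicative). The second
# split is only accepted when the two classes are well separated
# (standardized mean difference > 3.5); otherwise the histogram below the
# first threshold is unimodal -- pure background -- and the first
# threshold already is the background cut.
backgroundThreshold <- function(src) {
  v <- as.vector(src)
  tHi <- otsuThreshold(v)
  if (is.na(tHi)) return(NA_real_)
  lsub <- log(v[v <= tHi] + 1 / 256)
  if (length(lsub) < 4L || diff(range(lsub)) < 1e-6) return(tHi)
  tLo <- otsuThreshold(lsub, range = range(lsub))
  if (is.na(tLo)) return(tHi)
  lo <- lsub[lsub <= tLo]; hi <- lsub[lsub > tLo]
  if (length(lo) < 2L || length(hi) < 2L) return(tHi)
  sep <- (mean(hi) - mean(lo)) /
    sqrt((stats::var(lo) + stats::var(hi)) / 2 + 1e-12)
  if (sep < 3.5) tHi else exp(tLo) - 1 / 256
}

# 8-connected component labelling (integer label matrix, 0 = background).
labelComponents <- function(mask) {
  storage.mode(mask) <- "integer"
  .label8(mask)
}

# Remove 8-connected components smaller than minPx from a binary mask.
removeSmall <- function(mask, minPx) {
  if (minPx <= 0L || !any(mask > 0)) return(mask != 0)
  lab <- labelComponents(mask != 0)
  if (max(lab) == 0L) return(mask != 0)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minPx)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

# Block-mean downsampling of a matrix or H x W x C array by integer factor.
blockMean <- function(x, factor) {
  f <- as.integer(factor)
  if (f == 1L) return(x)
  down1 <- function(m) {
    H <- nrow(m); W <- ncol(m)
    stopifnot(H %% f == 0L, W %% f == 0L)
    m <- colMeans(array(m, c(f, H %/% f, W)), dims = 1L) # (H/f) x W
    t(colMeans(array(t(m), c(f, W %/% f, H %/% f)), dims = 1L))
  }
  if (length(dim(x)) == 2L) return(down1(x))
  out <- array(0, c(nrow(x) %/% f, ncol(x) %/% f, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- down1(x[, , c])
  out
}

# Bilinear upsampling of a matrix to a target size (used for Grad-CAM and
# segmenter probability maps).
upsampleBilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  # target pixel centres in 0-based source pixel coordinates
  py <- (seq_len(H) - 0.5) * h / H - 0.5
  px <- (seq_len(W) - 0.5) * w / W - 0.5
  y0 <- pmin(pmax(floor(py), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(px), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(py - y0, 0), 1)
  fx <- pmin(pmax(px - x0, 0), 1)
  iy0 <- as.integer(y0) + 1L; iy1 <- as.integer(y1) + 1L
  ix0 <- as.integer(x0) + 1L; ix1 <- as.integer(x1) + 1L
  A <- m[iy0, ix0, drop = FALSE]; B <- m[iy0, ix1, drop = FALSE]
  C <- m[iy1, ix0, drop = FALSE]; D <- m[iy1, ix1, drop = FALSE]
  FX <- matrix(fx, H, W, byrow = TRUE)
  FY <- matrix(fy, H, W)
  (A * (1 - FX) + B * FX) * (1 - FY) + (C * (1 - FX) + D * FX) * FY
}

# Internal constructor shortcuts ------------------------------------------

newMetricReport <- function(metrics, n, provenance = list()) {
  def <- !is.na(metrics)
  names(def) <- names(metrics)
  new("MetricReport", metrics = metrics, defined = def,
      n = as.integer(n), provenance = provenance)
}
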