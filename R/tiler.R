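# Tile extraction: non-overlapping 256 x 256 crops of the brightfield
# image with matched binary deposit masks and weak labels derived from the
# slide-level segmentation. At 0.4415 um/px a tile covers ~113 x 113 um of
# tissue.

#' Enumerate tile origins over a slide
#'
#' Non-overlapping grid aligned to the (0, 0) corner; partial edge tiles
#' are excluded, as are tiles whose tissue fraction falls below
#' `minTissueFraction`.
#'
#' @param tissue logical tissue mask (defines the slide shape).
#' @param sizePx tile side in pixels (default 256).
#' @param minTissueFraction minimum fraction of tissue pixels for a tile
#'   to be kept (boundary inclusive).
#' @return Two-column integer matrix of 0-based (row, col) origins; zero
#'   rows (with a warning) when the slide is smaller than one tile.
#' @export
tileGrid <- function(tissue, sizePx = 256L, minTissueFraction = 0.1) {
  H <- nrow(tissue); W <- ncol(tissue)
  sizePx <- as.integer(sizePx)
  if (H < sizePx || W < sizePx) {
    warning("slide is smaller than one tile; no origins")
    return(matrix(integer(), 0, 2,
                  dimnames = list(NULL, c("row", "col"))))
  }
  rows <- seq(0L, H - sizePx, by = sizePx)
  cols <- seq(0L, W - sizePx, by = sizePx)
  grid <- as.matrix(expand.grid(row = rows, col = cols))
  frac <- apply(grid, 1, function(o) {
    mean(tissue[(o[1] + 1):(o[1] + sizePx), (o[2] + 1):(o[2] + sizePx)])
  })
  grid <- grid[frac >= minTissueFraction, , drop = FALSE]
  storage.mode(grid) <- "integer"
  grid
}

#' Label a tile from its deposit mask
#'
#' A tile is positive when it contains at least `positiveMinPx` amyloid
#' pixels (boundary inclusive). The default 64 px (~0.1% of a 256 x 256
#' tile, ~12.5 um^2) keeps minimal or focal deposits positive while
#' suppressing single-pixel label noise.
#'
#' @param mask binary tile mask.
#' @param positiveMinPx inclusive pixel threshold.
#' @return `"positive"` or `"negative"`.
#' @export
labelTile <- function(mask, positiveMinPx = 64L) {
  if (sum(mask != 0) >= positiveMinPx) "positive" else "negative"
}

#' Extract one tile
#'
#' Crops the brightfield image and the deposit mask at a grid origin. The
#' `"original"` variant is the raw crop; the `"masked"` variant zeroes
#' every pixel outside the deposit mask (dark background), so only the
#' annotated amyloid remains visible.
#'
#' @param brightfield H x W x 3 array.
#' @param amyloid binary deposit mask on the same grid.
#' @param origin 0-based (row, col) origin from [tileGrid()].
#' @param variant `"original"` or `"masked"`.
#' @param sizePx tile side.
#' @param positiveMinPx see [labelTile()].
#' @return List with `image`, `mask`, `label`, `origin`, `variant`.
#' @export
extractTile <- function(brightfield, amyloid, origin,
                        variant = c("original", "masked"), sizePx = 256L,
                        positiveMinPx = 64L) {
  variant <- match.arg(variant)
  d <- dim(brightfield)
  r <- origin[1]; c <- origin[2]
  if (r < 0 || c < 0 || r + sizePx > d[1] || c + sizePx > d[2])
    stop("tile origin out of bounds: (", r, ", ", c, ")")
  ys <- (r + 1):(r + sizePx); xs <- (c + 1):(c + sizePx)
  img <- brightfield[ys, xs, , drop = FALSE]
  msk <- (amyloid[ys, xs] != 0) * 1
  if (variant == "masked")
    img <- img * array(rep(msk, 3L), dim(img))
  list(image = img, mask = msk, label = labelTile(msk, positiveMinPx),
       origin = c(row = r, col = c), variant = variant)
}

#' Tile one slide
#'
#' Runs [tileGrid()] on the tissue mask and extracts all tiles with their
#' deposit-mask labels.
#'
#' @param slide a [CRFSlide-class].
#' @param amyloid binary deposit mask (typically from [segmentSlide()]).
#' @param tissue logical tissue mask.
#' @param sizePx,minTissueFraction,positiveMinPx,variant see
#'   [tileGrid()], [labelTile()], [extractTile()].
#' @return A [TileSet-class].
#' @export
tileSlide <- function(slide, amyloid, tissue, sizePx = 256L,
                      minTissueFraction = 0.1, positiveMinPx = 64L,
                      variant = "original") {
  grid <- tileGrid(tissue, sizePx, minTissueFraction)
  n <- nrow(grid)
  images <- vector("list", n); masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tl <- extractTile(brightfield(slide), amyloid, grid[i, ], variant,
                      sizePx, positiveMinPx)
    images[[i]] <- tl$image; masks[[i]] <- tl$mask
    rows[[i]] <- data.frame(
      tileId = sprintf("%s_r%d_c%d", slideId(slide), grid[i, 1],
                       grid[i, 2]),
      slideId = slideId(slide), caseId = caseId(slide),
      row = grid[i, 1], col = grid[i, 2], label = tl$label,
      variant = variant, slideLabel = slideLabel(slide),
      stringsAsFactors = FALSE)
  }
  man <- if (n) do.call(rbind, rows) else
    data.frame(tileId = character(), slideId = character(),
               caseId = character(), row = integer(), col = integer(),
               label = character(), variant = character(),
               slideLabel = character(), stringsAsFactors = FALSE)
  new("TileSet", images = images, masks = masks, manifest = man,
      sizePx = as.integer(sizePx), pixelSizeUm = pixelSize(slide))
}

#' Tile a whole cohort through the segmentation pipeline
#'
#' For every slide: detect tissue, subtract channels, segment deposits,
#' then tile the brightfield image, labelling tiles from the
#' segmentation-derived mask (weak labels, as when no manual annotation
#' exists).
#'
#' @param cohort list as returned by [generateCohort()] (elements `cases`,
#'   `slides`).
#' @param params [segParams()].
#' @param sizePx,minTissueFraction,positiveMinPx,variant tiling options.
#' @return A [TileSet-class] covering all slides.
#' @export
tileCohort <- function(cohort, params = segParams(), sizePx = 256L,
                       minTissueFraction = 0.1, positiveMinPx = 64L,
                       variant = "original") {
  sets <- lapply(cohort$slides, function(sl) {
    seg <- segmentSlide(sl, params)
    tileSlide(sl, seg$amyloid, seg$tissue, sizePx, minTissueFraction,
              positiveMinPx, variant)
  })
  new("TileSet",
      images = do.call(c, lapply(sets, function(s) s@images)),
      masks = do.call(c, lapply(sets, function(s) s@masks)),
      manifest = do.call(rbind, lapply(sets, manifest)),
      sizePx = as.integer(sizePx),
      pixelSizeUm = pixelSize(cohort$slides[[1]]))
}

#' Write tiles and manifest to disk
#'
#' Tiles and masks go out as PNG with a sidecar CSV manifest.
#'
#' @param tileset a [TileSet-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeTiles <- function(tileset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  man <- manifest(tileset)
  man$imagePath <- file.path("images", paste0(man$tileId, ".png"))
  man$maskPath <- file.path("masks", paste0(man$tileId, "_mask.png"))
  for (i in seq_len(nrow(man))) {
    writeChannel(tileset@images[[i]], file.path(dir, man$imagePath[i]))
    writeMask(tileset@masks[[i]], file.path(dir, man$maskPath[i]))
  }
  p <- file.path(dir, "tiles.csv")
  writeTable(man, p)
  invisible(p)
}

# Subset a TileSet by manifest row index.
subsetTiles <- function(tileset, idx) {
  new("TileSet", images = tileset@images[idx],
      masks = tileset@masks[idx],
      manifest = tileset@manifest[idx, , drop = FALSE],
      sizePx = tileset@sizePx, pixelSizeUm = tileset@pixelSizeUm)
}
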