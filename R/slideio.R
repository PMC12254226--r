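# Raster, annotation and manifest I/O.
#
# Coordinate convention, fixed package-wide: rasters are matrices indexed
# (row, col) with a top-left origin; pixel (r, c) has 0-based centre
# coordinates (x, y) = (c - 1, r - 1). GeoJSON annotations use (x, y) per
# the format; all conversion happens in this file.

isTiff <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

resolutionToPixelSize <- function(res, unit) {
  # TIFF resolution tag is pixels per unit; convert to um/px
  if (is.null(res) || !is.finite(res) || res <= 0) return(NA_real_)
  perUm <- switch(as.character(unit),
                  cm = res / 1e4, inch = res / 25400, NA_real_)
  if (is.na(perUm)) NA_real_ else 1 / perUm
}

#' Read a single image channel from TIFF or PNG
#'
#' Reads a raster and scales it to \[0, 1\]. For TIFFs carrying resolution
#' tags the pixel size is decoded from `x.resolution`/`resolution.unit`;
#' otherwise `pixelSizeUm` (typically from the slide manifest) is used.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param expectedChannels 1 for fluorescence channels, 3 for brightfield.
#' @param pixelSizeUm fallback pixel size in microns per pixel; an error is
#'   raised when neither the file nor this argument provides one and
#'   `requirePixelSize` is `TRUE`.
#' @param requirePixelSize set `FALSE` to allow reading without a pixel
#'   size (e.g. plain masks).
#' @return A matrix (1 channel) or H x W x 3 array, values in \[0, 1\],
#'   with attribute `pixelSizeUm`.
#' @export
readChannel <- function(path, expectedChannels = 1L, pixelSizeUm = NULL,
                        requirePixelSize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  filePx <- NA_real_
  if (isTiff(path)) {
    img <- tiff::readTIFF(path, info = TRUE)
    at <- attributes(img)
    if (!is.null(at$x.resolution))
      filePx <- resolutionToPixelSize(at$x.resolution,
                                      if (is.null(at$resolution.unit))
                                        "inch" else at$resolution.unit)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else stop("unsupported raster format: ", path)
  nch <- if (length(dim(img)) == 2L) 1L else dim(img)[3]
  if (nch != expectedChannels)
    stop(sprintf("channel-count mismatch in %s: expected %d, found %d",
                 path, expectedChannels, nch))
  img <- if (expectedChannels == 1L) {
    if (length(dim(img)) == 3L) img[, , 1] else unclass(img)
  } else unclass(img)
  px <- if (!is.na(filePx)) filePx else
    if (!is.null(pixelSizeUm)) as.numeric(pixelSizeUm) else NA_real_
  if (requirePixelSize && is.na(px))
    stop("pixel size unavailable for ", path,
         ": no TIFF resolution tag and no manifest value")
  attr(img, "pixelSizeUm") <- px
  img
}

#' Write a binary mask as an 8-bit raster
#'
#' @param mask binary matrix (logical or 0/1 numeric).
#' @param path output `.png` or `.tif` path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  m <- (as.matrix(mask) != 0) * 1
  if (isTiff(path)) tiff::writeTIFF(m, path, bits.per.sample = 8L,
                                    compression = "none")
  else png::writePNG(m, path)
  invisible(path)
}

#' Write an image (grayscale matrix or RGB array)
#'
#' @param img matrix or H x W x 3 array in \[0, 1\].
#' @param path output `.png` or `.tif` path.
#' @return `path`, invisibly.
#' @export
writeChannel <- function(img, path) {
  img <- clip01(img)
  if (isTiff(path)) tiff::writeTIFF(img, path, bits.per.sample = 8L,
                                    compression = "none")
  else png::writePNG(img, path)
  invisible(path)
}

# Closed polygon rings (x, y in 0-based pixel-centre coordinates) tracing
# the 0.5 level set of a zero-padded binary mask. Axis-aligned boundaries
# land half a pixel outside the outermost foreground pixel centres, so a
# filled 10x10 square vectorizes to a ring of area 100 px^2.
maskToRings <- function(mask) {
  m <- (as.matrix(mask) != 0) * 1
  H <- nrow(m); W <- ncol(m)
  if (!any(m > 0)) return(list())
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  # contourLines indexes z as z[x, y]: pass the transpose, x = columns
  cl <- grDevices::contourLines(x = -1:W, y = -1:H, z = t(pad),
                                levels = 0.5)
  lapply(cl, function(l) {
    n <- length(l$x)
    if (l$x[1] == l$x[n] && l$y[1] == l$y[n]) n <- n - 1L
    cbind(x = l$x[seq_len(n)], y = l$y[seq_len(n)])
  })
}

shoelaceArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Write a mask as a GeoJSON polygon annotation
#'
#' Vectorizes the connected components of a binary mask into closed
#' polygons (pixel coordinates, 0-based, x right / y down) and writes a
#' GeoJSON FeatureCollection readable by common WSI annotation viewers.
#' Because the fluorescence channels and the brightfield image share one
#' pixel grid, these annotations transfer across modalities without
#' co-registration.
#'
#' @param mask binary matrix.
#' @param path output `.geojson`/`.json` path.
#' @return `path`, invisibly. An empty mask yields a FeatureCollection
#'   with zero features.
#' @export
writeAnnotation <- function(mask, path) {
  rings <- maskToRings(mask)
  features <- lapply(seq_along(rings), function(i) {
    ring <- rings[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close per GeoJSON spec
    list(type = "Feature",
         properties = list(object_id = i,
                           area_px = shoelaceArea(rings[[i]])),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(ring))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON annotation back into polygon rings
#'
#' @param path GeoJSON path written by [writeAnnotation()].
#' @return List of 2-column (x, y) matrices, one ring per feature.
#' @export
readAnnotation <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gj$features, function(f) {
    cc <- f$geometry$coordinates[[1]]
    ring <- do.call(rbind, lapply(cc, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    colnames(ring) <- c("x", "y")
    ring
  })
}

#' Rasterize polygon rings back to a binary mask
#'
#' Even-odd scanline fill over all rings jointly, so holes carve out
#' correctly. Coordinates follow the package convention (0-based pixel
#' centres).
#'
#' @param rings list of (x, y) matrices as returned by [readAnnotation()].
#' @param heightPx,widthPx output mask size.
#' @return Logical matrix.
#' @export
rasterizeAnnotation <- function(rings, heightPx, widthPx) {
  if (length(rings) == 0L) return(matrix(FALSE, heightPx, widthPx))
  rings <- lapply(rings, function(r) {
    n <- nrow(r)
    if (n > 1L && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    r
  })
  .rasterize_rings(rings, as.integer(heightPx), as.integer(widthPx)) > 0
}

manifestColumns <- c("slideId", "caseId", "specimenType", "pixelSizeUm",
                     "tritcPath", "scramblePath", "brightfieldPath",
                     "maskPath", "diagnosisLabel")

#' Read and validate a slide manifest (CSV or YAML)
#'
#' A manifest lists one slide per record with columns/fields `slideId`,
#' `caseId`, `specimenType` (`EMB`/`autopsy`), `pixelSizeUm`, channel paths
#' (`tritcPath`, `scramblePath`, `brightfieldPath`), optional `maskPath`
#' and `diagnosisLabel` (`positive`/`negative`/`unknown`). Duplicate slide
#' ids and invalid field values are rejected with row-level messages.
#'
#' @param path `.csv`, `.yml` or `.yaml` manifest.
#' @param checkFiles verify that referenced raster files exist.
#' @return data.frame of validated slide records (empty, with a warning,
#'   for an empty manifest).
#' @export
readManifest <- function(path, checkFiles = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- if (length(recs) == 0L) data.frame() else
      do.call(rbind, lapply(recs, function(r)
        as.data.frame(r[intersect(names(r), manifestColumns)],
                      stringsAsFactors = FALSE)))
  } else {
    if (file.size(path) == 0L ||
        length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
      warning("empty manifest: ", path)
      return(data.frame())
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty manifest: ", path)
    return(data.frame())
  }
  need <- c("slideId", "caseId", "pixelSizeUm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing required columns: ", paste(miss, collapse = ", "))
  dup <- df$slideId[duplicated(df$slideId)]
  if (length(dup))
    stop("duplicate slideId in manifest: ", paste(unique(dup),
                                                  collapse = ", "))
  bad <- which(!is.finite(df$pixelSizeUm) | df$pixelSizeUm <= 0)
  if (length(bad))
    stop("row ", bad[1], " (slideId ", df$slideId[bad[1]],
         "): pixelSizeUm must be a positive number")
  if ("specimenType" %in% names(df)) {
    bad <- which(!df$specimenType %in% c("EMB", "autopsy"))
    if (length(bad))
      stop("row ", bad[1], " (slideId ", df$slideId[bad[1]],
           "): specimenType must be EMB or autopsy")
  }
  if ("diagnosisLabel" %in% names(df)) {
    bad <- which(!df$diagnosisLabel %in%
                   c("positive", "negative", "unknown"))
    if (length(bad))
      stop("row ", bad[1], " (slideId ", df$slideId[bad[1]],
           "): diagnosisLabel must be positive/negative/unknown")
  }
  if (checkFiles) {
    for (col in c("tritcPath", "scramblePath", "brightfieldPath",
                  "maskPath")) {
      if (!col %in% names(df)) next
      p <- df[[col]]
      bad <- which(!is.na(p) & nzchar(p) & !file.exists(p))
      if (length(bad))
        stop("row ", bad[1], " (slideId ", df$slideId[bad[1]], "): ",
             col, " does not exist: ", p[bad[1]])
    }
  }
  df
}

#' Write a table of results as CSV
#'
#' @param rows data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
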