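# Raster, annotation and manifest I/O.

test_that("binary masks round-trip losslessly through PNG and TIFF", {
  set.seed(1)
  m <- matrix(runif(64 * 48) > 0.6, 64, 48)
  for (ext in c(".png", ".tif")) {
    p <- tempfile(fileext = ext)
    writeMask(m, p)
    back <- readChannel(p, 1L, requirePixelSize = FALSE) > 0.5
    expect_identical(unname(back), unname(m))
  }
})

test_that("8-bit rasters round-trip to quantization accuracy", {
  set.seed(2)
  x <- matrix(runif(32 * 32), 32, 32)
  p <- tempfile(fileext = ".png")
  writeChannel(x, p)
  back <- readChannel(p, 1L, requirePixelSize = FALSE)
  expect_lt(max(abs(back - x)), 1 / 255)
  # full-scale value maps to exactly 1.0
  writeChannel(matrix(1, 4, 4), p)
  expect_equal(max(readChannel(p, 1L, requirePixelSize = FALSE)), 1.0)
})

test_that("an all-zero 16-bit TIFF reads back as an all-zero raster", {
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 8, 8), p, bits.per.sample = 16L,
                  compression = "none")
  expect_true(all(readChannel(p, 1L, requirePixelSize = FALSE) == 0))
})

test_that("channel-count and existence contracts are enforced", {
  p <- tempfile(fileext = ".png")
  writeChannel(array(runif(48), c(4, 4, 3)), p)
  expect_error(readChannel(p, 1L, requirePixelSize = FALSE), "mismatch")
  expect_error(readChannel(tempfile(fileext = ".png")), "not found")
  writeChannel(matrix(0.5, 4, 4), p)
  expect_error(readChannel(p, 1L), "pixel size")
  expect_equal(attr(readChannel(p, 1L, pixelSizeUm = 0.4415),
                    "pixelSizeUm"), 0.4415)
})

test_that("TIFF resolution tags decode to microns per pixel", {
  r2p <- amyloidCRF:::resolutionToPixelSize
  expect_equal(r2p(10000 / 0.4415, "cm"), 0.4415)
  expect_equal(r2p(25400 / 0.25, "inch"), 0.25)
  expect_true(is.na(r2p(NULL, "cm")))
  expect_true(is.na(r2p(300, "furlong")))
})

test_that("annotation features: empty mask, square area, blob count", {
  p <- tempfile(fileext = ".geojson")
  writeAnnotation(matrix(FALSE, 20, 20), p)
  expect_length(readAnnotation(p), 0)

  sq <- matrix(FALSE, 32, 32); sq[1:10, 1:10] <- TRUE
  writeAnnotation(sq, p)
  rings <- readAnnotation(p)
  expect_length(rings, 1)
  # independent shoelace computation of the polygon area
  ring <- rings[[1]]
  n <- nrow(ring); j <- c(2:n, 1)
  area <- abs(sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2])) / 2
  expect_lte(abs(area - 100) / 100, 0.005)

  two <- matrix(FALSE, 40, 40)
  two[3:10, 3:10] <- TRUE; two[25:35, 20:30] <- TRUE
  writeAnnotation(two, p)
  expect_length(readAnnotation(p), 2)
})

test_that("polygons rasterize back to the source mask (Dice >= 0.99)", {
  for (seed in 1:3) {
    m <- blobMask(64, 64, 30 + seed, 28, r = 14, seed = seed) |
      blobMask(64, 64, 50, 50, r = 8, seed = seed + 10)
    p <- tempfile(fileext = ".geojson")
    writeAnnotation(m, p)
    back <- rasterizeAnnotation(readAnnotation(p), 64, 64)
    expect_gte(as.numeric(dice(back, m)), 0.99)
  }
  # orientation: an off-centre rectangle must land on the same pixels
  rect <- matrix(FALSE, 30, 50); rect[5:9, 20:40] <- TRUE
  p <- tempfile(fileext = ".geojson")
  writeAnnotation(rect, p)
  back <- rasterizeAnnotation(readAnnotation(p), 30, 50)
  expect_gte(as.numeric(dice(back, rect)), 0.99)
})

test_that("manifest validation accepts good records and names offenders", {
  man <- data.frame(
    slideId = sprintf("s%02d", 1:43), caseId = sprintf("c%02d", 1:43),
    specimenType = rep(c("EMB", "autopsy"), c(21, 22)),
    pixelSizeUm = 0.4415,
    diagnosisLabel = rep(c("positive", "negative"), c(28, 15)))
  p <- tempfile(fileext = ".csv")
  utils::write.csv(man, p, row.names = FALSE)
  got <- readManifest(p)
  expect_equal(nrow(got), 43)
  expect_equal(sum(got$diagnosisLabel == "positive"), 28)

  man2 <- man; man2$slideId[2] <- "s01"
  utils::write.csv(man2, p, row.names = FALSE)
  expect_error(readManifest(p), "s01")

  man3 <- man; man3$specimenType[5] <- "surgical"
  utils::write.csv(man3, p, row.names = FALSE)
  expect_error(readManifest(p), "specimenType")

  writeLines(character(), p)
  expect_warning(got <- readManifest(p), "empty")
  expect_equal(nrow(got), 0)
})

test_that("YAML manifests are accepted too", {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(slideId = "s1", caseId = "c1", pixelSizeUm = 0.4415,
         specimenType = "EMB", diagnosisLabel = "positive"),
    list(slideId = "s2", caseId = "c2", pixelSizeUm = 0.4415,
         specimenType = "autopsy", diagnosisLabel = "negative")), p)
  got <- readManifest(p)
  expect_equal(got$slideId, c("s1", "s2"))
})
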