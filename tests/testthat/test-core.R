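# Subtraction segmentation: channel arithmetic, tissue detection,
# binarization, morphometry, annotation transfer.

test_that("channel subtraction matches an elementwise loop oracle", {
  set.seed(3)
  a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
  d <- subtractChannels(a, b)
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- max(a[i, j] - b[i, j], 0)
  expect_equal(d, oracle)
  expect_true(all(subtractChannels(a, a) == 0))
  expect_equal(subtractChannels(a, matrix(0, 20, 20)), a)
  expect_error(subtractChannels(a, matrix(0, 10, 10)), "shape")
})

test_that("otsuThreshold maximizes between-class variance (brute-force oracle)", {
  set.seed(4)
  for (rep in 1:5) {
    x <- pmin(pmax(c(rnorm(600, 0.2, 0.05), rnorm(400, 0.7, 0.05)), 0), 1)
    ours <- otsuThreshold(x)
    # independent O(nbins^2) scan over every candidate cut
    breaks <- seq(0, 1, length.out = 257)
    h <- tabulate(findInterval(x, breaks, all.inside = TRUE), 256)
    p <- h / sum(h); mids <- (breaks[-1] + breaks[-257]) / 2
    best <- -Inf; bt <- NA
    for (k in 1:255) {
      w0 <- sum(p[1:k]); w1 <- 1 - w0
      if (w0 == 0 || w1 == 0) next
      m0 <- sum(p[1:k] * mids[1:k]) / w0
      m1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
      v <- w0 * w1 * (m0 - m1)^2
      if (v > best) { best <- v; bt <- breaks[k + 1] }
    }
    expect_equal(ours, bt)
    # the cut falls between the two modes
    expect_gt(ours, 0.2); expect_lt(ours, 0.7)
  }
  expect_true(is.na(otsuThreshold(rep(0.5, 100))))
})

test_that("tissue detection: blank, constant and synthetic slides", {
  expect_warning(m <- detectTissue(matrix(0, 64, 64)), "blank")
  expect_false(any(m))
  expect_true(all(detectTissue(matrix(0.15, 64, 64))))
  sl <- generateSlide(smallSpec(targetBurden = 0.15, noiseSd = 0,
                                seed = 9))
  tis <- detectTissue(sl)
  expect_gte(as.numeric(dice(tis, truthTissue(sl))), 0.98)
})

test_that("amyloid segmentation recovers the truth mask exactly without noise", {
  for (p in c("diffuse_pericellular", "nodular")) {
    sl <- generateSlide(smallSpec(targetBurden = 0.15, pattern = p,
                                  noiseSd = 0, seed = 11))
    seg <- segmentSlide(sl)
    expect_equal(as.numeric(iou(seg$amyloid, truthAmyloid(sl))), 1.0)
  }
})

test_that("degenerate inputs: zero difference and empty tissue", {
  tis <- matrix(TRUE, 32, 32)
  expect_false(any(segmentAmyloid(matrix(0, 32, 32), tis)))
  expect_false(any(segmentAmyloid(matrix(0.5, 32, 32),
                                  matrix(FALSE, 32, 32))))
})

test_that("increasing a fixed threshold never increases the amyloid area", {
  sl <- generateSlide(smallSpec(targetBurden = 0.2, seed = 13))
  seg <- segmentSlide(sl)
  last <- Inf
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    m <- segmentAmyloid(seg$diff, seg$tissue,
                        segParams(binarizeMethod = "fixed",
                                  fixedThreshold = thr))
    expect_lte(sum(m), last)
    last <- sum(m)
  }
})

test_that("morphometry counts pixels exactly and uses 8-connectivity", {
  tis <- matrix(TRUE, 10, 10)
  amy <- matrix(FALSE, 10, 10); amy[1:3, 1:5] <- TRUE # 15 px
  mo <- computeMorphometry(amy, tis)
  expect_equal(burden(mo), 0.15)
  expect_equal(mo@amyloidPx, 15L)
  expect_equal(mo@tissuePx, 100L)

  expect_equal(burden(computeMorphometry(matrix(FALSE, 10, 10), tis)), 0)
  expect_equal(burden(computeMorphometry(tis, tis)), 1)
  expect_error(computeMorphometry(amy, matrix(FALSE, 10, 10)), "empty")

  diag2 <- matrix(FALSE, 10, 10); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(computeMorphometry(diag2, tis)@nComponents, 1L)

  outside <- matrix(FALSE, 10, 10); outside[1, 1] <- TRUE
  halfTis <- tis; halfTis[1, ] <- FALSE
  expect_warning(mo2 <- computeMorphometry(outside, halfTis), "clip")
  expect_equal(mo2@amyloidPx, 0L)
})

test_that("mask transfer to brightfield round-trips through polygons", {
  sl <- generateSlide(smallSpec(targetBurden = 0.15, pattern = "nodular",
                                noiseSd = 0, seed = 15))
  seg <- segmentSlide(sl)
  p <- tempfile(fileext = ".geojson")
  tb <- transferToBrightfield(seg$amyloid, brightfield(sl),
                              annotationPath = p)
  back <- rasterizeAnnotation(readAnnotation(p), nrow(seg$amyloid),
                              ncol(seg$amyloid))
  expect_gte(as.numeric(dice(back, seg$amyloid)), 0.99)

  # empty mask: overlay is the brightfield itself, zero rings
  tb0 <- transferToBrightfield(matrix(FALSE, 256, 256), brightfield(sl))
  expect_identical(tb0$overlay, brightfield(sl))
  expect_length(tb0$rings, 0)

  expect_error(
    transferToBrightfield(matrix(FALSE, 10, 10), brightfield(sl)),
    "grids")
})

test_that("segParams validates its threshold contract", {
  expect_error(segParams(binarizeMethod = "fixed"), "fixedThreshold")
  expect_error(segParams(fixedThreshold = 0.5), "only meaningful")
  expect_silent(segParams(binarizeMethod = "fixed", fixedThreshold = 0.4))
})
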