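# The built-in networks: analytical gradients, separable-fixture
# learning, Grad-CAM, segmenter behaviour, slide aggregation.

numGradCheck <- function(par, lossFun, grads, nPerBlock = 4) {
  eps <- 1e-6; worst <- 0
  for (nm in names(par)) {
    for (k in sample(seq_along(par[[nm]]), min(nPerBlock,
                                               length(par[[nm]])))) {
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (lossFun(pp) - lossFun(pm)) / (2 * eps)
      got <- grads[[nm]][k]
      worst <- max(worst, abs(num - got) /
                     max(1e-8, abs(num) + abs(got)))
    }
  }
  worst
}

test_that("classifier backward pass matches finite differences", {
  ns <- asNamespace("amyloidCRF")
  set.seed(11)
  spec <- cnnSpec(inputSize = 8, channels = c(2L, 3L, 3L))
  par <- ns$classifierInit(spec)
  x <- array(runif(192), c(8, 8, 3))
  cache <- ns$classifierForward(par, x, keepCache = TRUE)
  g <- ns$classifierBackward(par, cache, 1)
  worst <- numGradCheck(par, function(p)
    ns$bceLoss(ns$classifierForward(p, x)$z, 1), g)
  expect_lt(worst, 1e-5)
})

test_that("segmenter backward pass matches finite differences", {
  ns <- asNamespace("amyloidCRF")
  set.seed(12)
  spec <- cnnSpec(inputSize = 8, channels = c(2L, 3L, 3L))
  par <- ns$segmenterInit(spec)
  x <- array(runif(192), c(8, 8, 3))
  tg <- matrix(runif(64), 8, 8)
  cache <- ns$segmenterForward(par, x, keepCache = TRUE)
  g <- ns$segmenterBackward(par, cache, tg)
  worst <- numGradCheck(par, function(p)
    ns$segBCE(ns$segmenterForward(p, x)$z4[, , 1], tg), g)
  expect_lt(worst, 1e-5)
})

test_that("the classifier separates bright-blob tiles within 5 epochs", {
  tiles <- separableTiles(32, seed = 21)
  tr <- amyloidCRF:::subsetTiles(tiles, 1:24)
  va <- amyloidCRF:::subsetTiles(tiles, 25:32)
  model <- trainTileClassifier(tr, va, seed = 5, epochs = 5, lr = 1e-2,
                               batchSize = 2L)
  probs <- predictProba(model, va)
  acc <- mean((probs > 0.5) == (manifest(va)$label == "positive"))
  expect_gte(acc, 0.95)
})

test_that("label shuffling destroys validation performance", {
  tiles <- separableTiles(32, seed = 22)
  man <- manifest(tiles)
  set.seed(31)
  man$label <- sample(man$label)
  shuffled <- new("TileSet", images = tiles@images, masks = tiles@masks,
                  manifest = man, sizePx = tiles@sizePx,
                  pixelSizeUm = tiles@pixelSizeUm)
  tr <- amyloidCRF:::subsetTiles(shuffled, 1:24)
  va <- amyloidCRF:::subsetTiles(shuffled, 25:32)
  model <- trainTileClassifier(tr, va, seed = 5, epochs = 5, lr = 1e-2,
                               batchSize = 2L)
  auc <- aucROC(predictProba(model, va),
                manifest(va)$label == "positive")
  expect_gte(auc, 0.35 - 1e-9)
  expect_lte(auc, 0.65 + 1e-9)
})

test_that("training is deterministic under seed and rejects one-class input", {
  tiles <- separableTiles(16, seed = 23)
  tr <- amyloidCRF:::subsetTiles(tiles, 1:12)
  va <- amyloidCRF:::subsetTiles(tiles, 13:16)
  m1 <- trainTileClassifier(tr, va, seed = 9, epochs = 3)
  m2 <- trainTileClassifier(tr, va, seed = 9, epochs = 3)
  expect_identical(predictProba(m1, va), predictProba(m2, va))
  onlyPos <- amyloidCRF:::subsetTiles(tiles,
                                      which(manifest(tiles)$label ==
                                              "positive"))
  expect_error(trainTileClassifier(onlyPos, va, seed = 1), "single class")
})

test_that("Grad-CAM is normalized and localizes the deposit", {
  tiles <- separableTiles(32, seed = 24)
  tr <- amyloidCRF:::subsetTiles(tiles, 1:24)
  va <- amyloidCRF:::subsetTiles(tiles, 25:32)
  model <- trainTileClassifier(tr, va, seed = 5, epochs = 10, lr = 1e-2,
                               batchSize = 2L)
  posIdx <- which(manifest(tiles)$label == "positive")[1:4]
  insideHigher <- 0
  for (j in posIdx) {
    hm <- gradCAM(model, tiles@images[[j]])
    expect_true(all(hm >= 0 & hm <= 1))
    expect_equal(max(hm), 1)
    m <- tiles@masks[[j]] > 0
    if (mean(hm[m]) > mean(hm[!m])) insideHigher <- insideHigher + 1
  }
  expect_gte(insideHigher, 3) # deposit drives the activation
})

test_that("a constant-activation model yields a defined all-zero heatmap", {
  tiles <- separableTiles(4, seed = 25)
  model <- trainTileClassifier(amyloidCRF:::subsetTiles(tiles, 1:2),
                               amyloidCRF:::subsetTiles(tiles, 3:4),
                               seed = 1, epochs = 1)
  model$par$W3[] <- 0; model$par$b3[] <- 0
  hm <- gradCAM(model, tiles@images[[1]])
  expect_false(any(is.na(hm)))
  expect_true(all(hm == 0))
  expect_error(gradCAM(structure(list(par = list()),
                                 class = "crfClassifier"),
                       tiles@images[[1]]), "convolutional")
})

test_that("the segmenter reaches Dice >= 0.8 on a high-contrast fixture", {
  tiles <- separableTiles(32, seed = 26)
  tr <- amyloidCRF:::subsetTiles(tiles, 1:24)
  va <- amyloidCRF:::subsetTiles(tiles, 25:32)
  model <- trainSegmenter(tr, va, seed = 6)
  vaPos <- which(manifest(va)$label == "positive")
  dices <- vapply(vaPos, function(j)
    as.numeric(dice(predictMask(model, va@images[[j]]) > 0.5,
                    va@masks[[j]] != 0)), numeric(1))
  expect_gte(stats::median(dices), 0.8)
  m1 <- trainSegmenter(tr, va, seed = 6, epochs = 3)
  m2 <- trainSegmenter(tr, va, seed = 6, epochs = 3)
  expect_identical(predictMask(m1, va@images[[1]]),
                   predictMask(m2, va@images[[1]]))
})

test_that("an all-negative training set keeps predicted foreground near zero", {
  tiles <- separableTiles(24, seed = 27)
  negIdx <- which(manifest(tiles)$label == "negative")
  neg <- amyloidCRF:::subsetTiles(tiles, negIdx)
  model <- trainSegmenter(amyloidCRF:::subsetTiles(neg, 1:8),
                          amyloidCRF:::subsetTiles(neg, 9:12),
                          seed = 7, epochs = 10)
  frac <- mean(predictMask(model, neg@images[[1]]) > 0.5)
  expect_lte(frac, 0.05)
})

test_that("slide aggregation follows the strict-threshold mean rule", {
  ag <- aggregateSlide(c(1, 1, 0, 0))
  expect_equal(ag$slideProbability, 0.5)
  expect_identical(ag$predictedLabel, "negative") # tie goes negative
  expect_identical(aggregateSlide(rep(0.9, 7))$predictedLabel, "positive")
  set.seed(13)
  p <- runif(25)
  expect_equal(aggregateSlide(p)$slideProbability, sum(p) / length(p))
  expect_true(aggregateSlide(p)$slideProbability >= min(p))
  expect_true(aggregateSlide(p)$slideProbability <= max(p))
  expect_error(aggregateSlide(numeric()), "no tile")
})

test_that("unknown architectures are rejected by the model spec", {
  expect_error(cnnSpec("efficientnet-b0"), "tinycnn")
})
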