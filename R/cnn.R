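# Desk-scale convolutional models: a 3-conv-block tile classifier and a
# small U-shaped per-pixel segmenter, trained with Adam on block-mean
# downsampled tiles. The conv/pool/upsample kernels live in src/cnn.cpp;
# the training loop, initialization and all randomness live here so a
# fixed seed gives bit-identical fits. The architecture is injected via a
# model spec, so larger backbones can be swapped in by users with the
# hardware for them; the built-in network is the reference
# implementation.

relu <- function(a) { a[a < 0] <- 0; a }
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Model specification for the built-in networks
#'
#' @param architecture `"tinycnn"` -- the only built-in backend. Other
#'   names (e.g. large pretrained families) are rejected with a message;
#'   the training harness is architecture-agnostic, so an alternative
#'   backend only needs to honour the same fit/predict contract.
#' @param inputSize side of the square network input; tiles are
#'   block-mean downsampled to this size (default 32).
#' @param channels feature channels of the three conv blocks.
#' @return List of class `cnnSpec`.
#' @export
cnnSpec <- function(architecture = "tinycnn", inputSize = 32L,
                    channels = c(8L, 16L, 16L)) {
  if (!identical(architecture, "tinycnn"))
    stop("unknown architecture '", architecture,
         "'; the built-in backend is 'tinycnn'")
  stopifnot(inputSize >= 8, inputSize %% 4 == 0, length(channels) == 3L)
  structure(list(architecture = architecture,
                 inputSize = as.integer(inputSize),
                 channels = as.integer(channels)), class = "cnnSpec")
}

heInit <- function(kh, kw, ci, co) {
  array(stats::rnorm(kh * kw * ci * co, 0, sqrt(2 / (kh * kw * ci))),
        c(kh, kw, ci, co))
}

# Downsample a tile image (H x W x C) to the network input size.
tileToInput <- function(img, inputSize) {
  H <- dim(img)[1]
  if (H == inputSize) return(img)
  f <- H / inputSize
  if (f == round(f)) return(blockMean(img, f))
  out <- array(0, c(inputSize, inputSize, dim(img)[3]))
  for (c in seq_len(dim(img)[3]))
    out[, , c] <- upsampleBilinear(img[, , c], inputSize, inputSize)
  out
}

# Centre a [0,1] image for the network (brightfield values live in the
# upper half of [0,1]; centred inputs keep the first conv layer out of
# one-sided ReLU saturation). Applied after any color augmentation.
centerInput <- function(x) x - 0.5

# Adam optimizer over a named list of arrays.
adamStep <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (nm in names(state$par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

zeroLike <- function(par) lapply(par, function(p) p * 0)

# --- classifier ----------------------------------------------------------

classifierInit <- function(spec) {
  ch <- spec$channels
  list(W1 = heInit(3, 3, 3, ch[1]), b1 = numeric(ch[1]),
       W2 = heInit(3, 3, ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = heInit(3, 3, ch[2], ch[3]), b3 = numeric(ch[3]),
       Wd = stats::rnorm(ch[3], 0, sqrt(1 / ch[3])), bd = 0)
}

classifierForward <- function(par, x, keepCache = FALSE) {
  z1 <- .conv2d_fw(x, par$W1, par$b1); a1 <- relu(z1)
  p1 <- .maxpool2_fw(a1)
  z2 <- .conv2d_fw(p1$out, par$W2, par$b2); a2 <- relu(z2)
  p2 <- .maxpool2_fw(a2)
  z3 <- .conv2d_fw(p2$out, par$W3, par$b3); a3 <- relu(z3)
  hw <- dim(a3)[1] * dim(a3)[2]
  g <- apply(a3, 3, mean)
  z <- sum(par$Wd * g) + par$bd
  if (!keepCache) return(list(z = z, p = sigmoid(z), a3 = a3))
  list(z = z, p = sigmoid(z), x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2,
       z3 = z3, a3 = a3, g = g, hw = hw)
}

classifierBackward <- function(par, cache, y) {
  dz <- sigmoid(cache$z) - y # d(BCE)/d(logit)
  gWd <- dz * cache$g
  gbd <- dz
  da3 <- array(rep(par$Wd * dz / cache$hw, each = cache$hw),
               dim(cache$a3))
  da3[cache$z3 <= 0] <- 0
  b3 <- .conv2d_bw(cache$p2$out, par$W3, da3)
  dp2 <- .maxpool2_bw(b3$gx, cache$p2$argmax, dim(relu(cache$z2)))
  dp2[cache$z2 <= 0] <- 0
  b2 <- .conv2d_bw(cache$p1$out, par$W2, dp2)
  dp1 <- .maxpool2_bw(b2$gx, cache$p1$argmax, dim(cache$z1))
  dp1[cache$z1 <= 0] <- 0
  b1 <- .conv2d_bw(cache$x, par$W1, dp1)
  list(W1 = b1$gw, b1 = b1$gb, W2 = b2$gw, b2 = b2$gb,
       W3 = b3$gw, b3 = b3$gb, Wd = gWd, bd = gbd)
}

bceLoss <- function(z, y) {
  # numerically stable binary cross-entropy on the logit
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

#' Train the tile classifier
#'
#' Fits the built-in 3-conv-block CNN (conv-ReLU-pool x2, conv-ReLU,
#' global average pooling, sigmoid head) on downsampled tiles with Adam
#' and stable binary cross-entropy, optionally applying HSV color
#' augmentation to each (downsampled) training input per epoch. Training
#' stops early
#' when the validation loss has not improved for `patience` epochs; the
#' best-validation parameters are kept.
#'
#' @param trainTiles,valTiles [TileSet-class] objects with tile labels.
#' @param modelSpec [cnnSpec()].
#' @param seed integer; fixes initialization, shuffling and augmentation.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param augment optional [augmentParams()]; `NULL` disables.
#' @param patience early-stopping patience in epochs.
#' @return A fitted model of class `crfClassifier` with a `$log`
#'   data.frame of per-epoch train/val losses.
#' @export
trainTileClassifier <- function(trainTiles, valTiles,
                                modelSpec = cnnSpec(), seed = 1L,
                                epochs = 20L, lr = 3e-3, batchSize = 8L,
                                augment = NULL, patience = 5L) {
  trMan <- manifest(trainTiles)
  if (length(unique(trMan$label)) < 2L)
    stop("training set contains a single class")
  withSeed(seed, {
    yTr <- as.numeric(trMan$label == "positive")
    # downsample once; augmentation operates on the network input
    xTr <- lapply(trainTiles@images, tileToInput, modelSpec$inputSize)
    xVal <- lapply(valTiles@images, function(im)
      centerInput(tileToInput(im, modelSpec$inputSize)))
    yVal <- as.numeric(manifest(valTiles)$label == "positive")
    state <- list(par = classifierInit(modelSpec))
    state$m <- zeroLike(state$par); state$v <- zeroLike(state$par)
    t <- 0L
    best <- list(loss = Inf, par = state$par, epoch = 0L)
    log <- data.frame()
    n <- nrow(trMan)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epLoss <- 0
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        grads <- NULL
        for (i in idx) {
          x <- xTr[[i]]
          if (!is.null(augment)) x <- augmentColor(x, augment)
          x <- centerInput(x)
          cache <- classifierForward(state$par, x, keepCache = TRUE)
          epLoss <- epLoss + bceLoss(cache$z, yTr[i])
          g <- classifierBackward(state$par, cache, yTr[i])
          grads <- if (is.null(grads)) g else
            Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        t <- t + 1L
        state <- adamStep(state, grads, lr, t)
      }
      valLoss <- if (length(xVal)) {
        mean(vapply(seq_along(xVal), function(i) {
          bceLoss(classifierForward(state$par, xVal[[i]])$z, yVal[i])
        }, numeric(1)))
      } else epLoss / n
      log <- rbind(log, data.frame(epoch = ep, trainLoss = epLoss / n,
                                   valLoss = valLoss))
      if (valLoss < best$loss - 1e-6) {
        best <- list(loss = valLoss, par = state$par, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
    structure(list(spec = modelSpec, par = best$par, log = log,
                   seed = as.integer(seed)),
              class = "crfClassifier")
  })
}

#' Predict tile probabilities
#'
#' @param model a `crfClassifier`.
#' @param tiles a [TileSet-class] or list of H x W x 3 arrays.
#' @return Numeric vector of per-tile positive-class probabilities.
#' @export
predictProba <- function(model, tiles) {
  stopifnot(inherits(model, "crfClassifier"))
  imgs <- if (is(tiles, "TileSet")) tiles@images else tiles
  vapply(imgs, function(img) {
    x <- centerInput(tileToInput(img, model$spec$inputSize))
    classifierForward(model$par, x)$p
  }, numeric(1))
}

#' Grad-CAM heatmap for a tile
#'
#' Gradient-weighted class activation mapping on the final convolutional
#' feature map: channel weights are the spatially pooled gradients of the
#' positive-class logit, the weighted activation sum is rectified,
#' min-max normalized and bilinearly upsampled to the tile size. A
#' constant activation map yields a defined all-zero heatmap.
#'
#' @param model a `crfClassifier` (must expose conv features).
#' @param tileImage H x W x 3 array.
#' @return Heatmap matrix in \[0, 1\] at the tile resolution.
#' @export
gradCAM <- function(model, tileImage) {
  if (!inherits(model, "crfClassifier") || is.null(model$par$W3))
    stop("model does not expose a final convolutional feature map")
  x <- centerInput(tileToInput(tileImage, model$spec$inputSize))
  fw <- classifierForward(model$par, x)
  A <- fw$a3
  hw <- dim(A)[1] * dim(A)[2]
  alpha <- model$par$Wd / hw # pooled gradient of the logit wrt A
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(dim(A)[3])) cam <- cam + alpha[c] * A[, , c]
  cam <- relu(cam)
  if (diff(range(cam)) < 1e-12)
    return(matrix(0, dim(tileImage)[1], dim(tileImage)[2]))
  cam <- upsampleBilinear(cam, dim(tileImage)[1], dim(tileImage)[2])
  rng <- range(cam) # normalize after upsampling so the maximum is exactly 1
  (cam - rng[1]) / diff(rng)
}

# --- segmenter -----------------------------------------------------------

segmenterInit <- function(spec) {
  ch <- spec$channels
  list(W1 = heInit(3, 3, 3, ch[1]), b1 = numeric(ch[1]),
       W2 = heInit(3, 3, ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = heInit(3, 3, ch[1] + ch[2], ch[1]), b3 = numeric(ch[1]),
       W4 = heInit(3, 3, ch[1], 1), b4 = numeric(1))
}

segmenterForward <- function(par, x, keepCache = FALSE) {
  z1 <- .conv2d_fw(x, par$W1, par$b1); a1 <- relu(z1)
  p1 <- .maxpool2_fw(a1)
  z2 <- .conv2d_fw(p1$out, par$W2, par$b2); a2 <- relu(z2)
  u2 <- .upsample2_fw(a2)
  cc <- array(c(a1, u2), c(dim(a1)[1], dim(a1)[2],
                           dim(a1)[3] + dim(u2)[3]))
  z3 <- .conv2d_fw(cc, par$W3, par$b3); a3 <- relu(z3)
  z4 <- .conv2d_fw(a3, par$W4, par$b4)
  p <- sigmoid(z4[, , 1])
  if (!keepCache) return(list(p = p, z4 = z4))
  list(p = p, x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2, u2 = u2,
       cc = cc, z3 = z3, a3 = a3, z4 = z4)
}

segmenterBackward <- function(par, cache, target) {
  npx <- length(target)
  dz4 <- array((sigmoid(cache$z4[, , 1]) - target) / npx,
               dim(cache$z4))
  b4 <- .conv2d_bw(cache$a3, par$W4, dz4)
  da3 <- b4$gx; da3[cache$z3 <= 0] <- 0
  b3 <- .conv2d_bw(cache$cc, par$W3, da3)
  c1 <- dim(cache$a1)[3]
  dcc <- b3$gx
  da1 <- dcc[, , seq_len(c1), drop = FALSE]
  du2 <- dcc[, , -seq_len(c1), drop = FALSE]
  da2 <- .upsample2_bw(du2); da2[cache$z2 <= 0] <- 0
  b2 <- .conv2d_bw(cache$p1$out, par$W2, da2)
  dp1 <- .maxpool2_bw(b2$gx, cache$p1$argmax, dim(cache$z1))
  dp1 <- dp1 + da1
  dp1[cache$z1 <= 0] <- 0
  b1 <- .conv2d_bw(cache$x, par$W1, dp1)
  list(W1 = b1$gw, b1 = b1$gb, W2 = b2$gw, b2 = b2$gb,
       W3 = b3$gw, b3 = b3$gb, W4 = b4$gw, b4 = b4$gb)
}

segBCE <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

#' Train the per-pixel segmenter
#'
#' Fits a small U-shaped CNN (one downsampling stage with a skip
#' connection) that predicts a per-pixel deposit probability on
#' downsampled tiles; targets are the block-mean deposit fractions of the
#' matching masks (soft labels). Early stopping mirrors
#' [trainTileClassifier()].
#'
#' @inheritParams trainTileClassifier
#' @return A fitted model of class `crfSegmenter`.
#' @export
trainSegmenter <- function(trainTiles, valTiles, modelSpec = cnnSpec(),
                           seed = 1L, epochs = 40L, lr = 1e-2,
                           batchSize = 8L, augment = NULL,
                           patience = 8L) {
  withSeed(seed, {
    ins <- modelSpec$inputSize
    xTr <- lapply(trainTiles@images, tileToInput, ins)
    tTr <- lapply(trainTiles@masks, function(m)
      as.matrix(blockMean(m, nrow(m) / ins)))
    xVal <- lapply(valTiles@images, function(im)
      centerInput(tileToInput(im, ins)))
    tVal <- lapply(valTiles@masks, function(m)
      as.matrix(blockMean(m, nrow(m) / ins)))
    state <- list(par = segmenterInit(modelSpec))
    state$m <- zeroLike(state$par); state$v <- zeroLike(state$par)
    t <- 0L
    best <- list(loss = Inf, par = state$par, epoch = 0L)
    log <- data.frame()
    n <- length(tTr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      epLoss <- 0
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        grads <- NULL
        for (i in idx) {
          x <- xTr[[i]]
          if (!is.null(augment)) x <- augmentColor(x, augment)
          x <- centerInput(x)
          cache <- segmenterForward(state$par, x, keepCache = TRUE)
          epLoss <- epLoss + segBCE(cache$z4[, , 1], tTr[[i]])
          g <- segmenterBackward(state$par, cache, tTr[[i]])
          grads <- if (is.null(grads)) g else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(idx))
        t <- t + 1L
        state <- adamStep(state, grads, lr, t)
      }
      valLoss <- if (length(xVal)) {
        mean(vapply(seq_along(xVal), function(i) {
          segBCE(segmenterForward(state$par, xVal[[i]])$z4[, , 1],
                 tVal[[i]])
        }, numeric(1)))
      } else epLoss / n
      log <- rbind(log, data.frame(epoch = ep, trainLoss = epLoss / n,
                                   valLoss = valLoss))
      if (valLoss < best$loss - 1e-6) {
        best <- list(loss = valLoss, par = state$par, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
    structure(list(spec = modelSpec, par = best$par, log = log,
                   seed = as.integer(seed)),
              class = "crfSegmenter")
  })
}

#' Predict a per-pixel deposit probability map
#'
#' @param model a `crfSegmenter`.
#' @param tileImage H x W x 3 array.
#' @return Probability matrix at the tile resolution (bilinear upsampling
#'   of the network output).
#' @export
predictMask <- function(model, tileImage) {
  stopifnot(inherits(model, "crfSegmenter"))
  x <- centerInput(tileToInput(tileImage, model$spec$inputSize))
  p <- segmenterForward(model$par, x)$p
  clip01(upsampleBilinear(p, dim(tileImage)[1], dim(tileImage)[2]))
}
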