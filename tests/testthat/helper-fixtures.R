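# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale so the whole suite stays fast.

smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(widthPx = 256L, heightPx = 256L, noiseSd = 0.01,
                   seed = 1L)
  do.call(synthSpec, utils::modifyList(defaults, args))
}

# Irregular blob mask for annotation round-trip tests.
blobMask <- function(H = 64, W = 64, cy = 32, cx = 32, r = 12,
                     seed = 1) {
  set.seed(seed)
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  th <- atan2(dy, dx)
  rad <- r * (1 + 0.2 * sin(3 * th + runif(1, 0, 2 * pi)))
  (dy^2 + dx^2) <= rad^2
}

# Tiny labelled tiles: positives carry a bright salmon blob on a pink
# background, negatives are pure background -- linearly separable.
separableTiles <- function(n = 24, size = 64L, seed = 1) {
  set.seed(seed)
  imgs <- list(); masks <- list(); lab <- character(n)
  for (i in seq_len(n)) {
    pos <- i %% 2 == 0
    img <- array(rep(c(0.92, 0.63, 0.70), each = size * size),
                 c(size, size, 3))
    msk <- matrix(0, size, size)
    if (pos) {
      m <- blobMask(size, size, sample(24:40, 1), sample(24:40, 1),
                    r = 16, seed = seed + i)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[m] <- c(0.94, 0.55, 0.42)[ch]
        img[, , ch] <- pl
      }
      msk[m] <- 1
    }
    img <- amyloidCRF:::clip01(img + array(rnorm(size * size * 3, 0, 0.02),
                                           c(size, size, 3)))
    imgs[[i]] <- img; masks[[i]] <- msk
    lab[i] <- if (pos) "positive" else "negative"
  }
  man <- data.frame(
    tileId = sprintf("t%03d", seq_len(n)),
    slideId = sprintf("s%03d", seq_len(n)),
    caseId = sprintf("c%03d", seq_len(n)),
    row = 0L, col = 0L, label = lab, variant = "original",
    slideLabel = lab, stringsAsFactors = FALSE)
  new("TileSet", images = imgs, masks = masks, manifest = man,
      sizePx = as.integer(size), pixelSizeUm = 0.4415)
}

# The separable study cohort used for cross-validation checks.
separableCohortTiles <- function(nCases = 20, seed = 11) {
  cohort <- generateCohort(nCases, 0.5, seed = seed,
                           patterns = c("nodular",
                                        "diffuse_pericellular"),
                           burdenMin = 0.10, burdenMax = 0.35)
  list(cohort = cohort, tiles = tileCohort(cohort))
}
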