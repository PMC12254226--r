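# Nested cross-validation driver: per-fold training, tile- and
# slide-level evaluation, and median/IQR aggregation across folds.

tileMetricReport <- function(probs, labels, fold, split) {
  y <- labels == "positive"
  pred <- probs > 0.5
  cm <- confusionMatrix(sum(pred & y), sum(!pred & !y),
                        sum(pred & !y), sum(!pred & y))
  rep <- classificationMetrics(cm)
  auc <- suppressWarnings(aucROC(probs, y))
  m <- c(metricValues(rep), auc = auc)
  newMetricReport(m, length(probs),
                  provenance = list(fold = fold, split = split,
                                    level = "tile",
                                    counts = counts(cm)))
}

# Slide-level evaluation of one split: mean-probability aggregation at
# the given threshold, compared against the slide truth labels.
slideEval <- function(probs, man, threshold = 0.5) {
  bySlide <- split(seq_along(probs), man$slideId)
  rows <- lapply(names(bySlide), function(sid) {
    idx <- bySlide[[sid]]
    ag <- aggregateSlide(probs[idx], threshold)
    data.frame(slideId = sid, caseId = man$caseId[idx[1]],
               slideProbability = ag$slideProbability,
               predictedLabel = ag$predictedLabel,
               trueLabel = man$slideLabel[idx[1]],
               nTiles = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run case-level nested cross-validation
#'
#' For every fold of the plan: trains the model on the training cases'
#' tiles, early-stops on the validation cases, then evaluates tiles and
#' slides of all three splits. Slide-level predictions use mean-tile-
#' probability aggregation with a strict `> threshold` decision. A
#' leakage assertion re-checks every fold for case overlap between roles
#' before any training happens.
#'
#' @param tileset a [TileSet-class] (all cases).
#' @param plan a [FoldPlan-class].
#' @param task `"classification"` or `"segmentation"`.
#' @param modelSpec [cnnSpec()].
#' @param epochs,lr,batchSize,augment,patience training options passed to
#'   [trainTileClassifier()] / [trainSegmenter()].
#' @param threshold slide-level decision threshold.
#' @param seed integer; fold `i` trains with seed `seed + i`.
#' @return A list of class `nestedCVResult`:
#'   `foldReports` (per fold, per split [MetricReport-class]s),
#'   `aggregate` (data.frame of median and IQR per metric and split),
#'   `slidePredictions` (test-split slide table across all folds),
#'   `slideConfusion` (test-split slide-level [ConfusionMatrix-class]),
#'   `slideMetrics` (metrics derived from it).
#' @export
runNestedCV <- function(tileset, plan, task = c("classification",
                                                "segmentation"),
                        modelSpec = cnnSpec(), epochs = 20L, lr = 3e-3,
                        batchSize = 8L, augment = NULL, patience = 5L,
                        threshold = 0.5, seed = 1L) {
  task <- match.arg(task)
  man <- manifest(tileset)
  validObject(plan)
  # leakage assertion: no case id may appear in two roles of one fold
  for (i in seq_along(folds(plan))) {
    f <- folds(plan)[[i]]
    if (length(intersect(f$train, f$val)) ||
        length(intersect(f$train, f$test)) ||
        length(intersect(f$val, f$test)))
      stop("case leakage detected in fold ", i)
  }
  foldReports <- vector("list", plan@k)
  slideRows <- list()
  tileRows <- list()
  for (i in seq_along(folds(plan))) {
    f <- folds(plan)[[i]]
    sel <- function(ids) which(man$caseId %in% ids)
    trIdx <- sel(f$train); vaIdx <- sel(f$val); teIdx <- sel(f$test)
    trTiles <- subsetTiles(tileset, trIdx)
    vaTiles <- subsetTiles(tileset, vaIdx)
    if (task == "classification") {
      model <- trainTileClassifier(trTiles, vaTiles, modelSpec,
                                   seed = seed + i, epochs = epochs,
                                   lr = lr, batchSize = batchSize,
                                   augment = augment,
                                   patience = patience)
      rep <- list()
      for (split in c("train", "val", "test")) {
        idx <- switch(split, train = trIdx, val = vaIdx, test = teIdx)
        if (!length(idx)) next
        probs <- predictProba(model, subsetTiles(tileset, idx))
        rep[[split]] <- tileMetricReport(probs, man$label[idx], i, split)
        if (split == "test") {
          slideRows[[i]] <- cbind(
            slideEval(probs, man[idx, , drop = FALSE], threshold),
            fold = i)
          tileRows[[i]] <- data.frame(
            tileId = man$tileId[idx], label = man$label[idx],
            prob = probs, fold = i, stringsAsFactors = FALSE)
        }
      }
      foldReports[[i]] <- rep
    } else {
      model <- trainSegmenter(trTiles, vaTiles, modelSpec,
                              seed = seed + i, epochs = epochs, lr = lr,
                              batchSize = batchSize, augment = augment,
                              patience = patience)
      rep <- list()
      for (split in c("train", "val", "test")) {
        idx <- switch(split, train = trIdx, val = vaIdx, test = teIdx)
        if (!length(idx)) next
        ious <- numeric(0); dices <- numeric(0)
        for (j in idx) {
          pm <- predictMask(model, tileset@images[[j]]) > 0.5
          truth <- tileset@masks[[j]] != 0
          ious <- c(ious, as.numeric(iou(pm, truth)))
          dices <- c(dices, as.numeric(dice(pm, truth)))
        }
        m <- c(iou = stats::median(ious), dice = stats::median(dices))
        rep[[split]] <- newMetricReport(
          m, length(idx), provenance = list(fold = i, split = split,
                                            level = "tile"))
      }
      foldReports[[i]] <- rep
    }
  }

  # aggregate: median and IQR of each metric across folds, per split
  aggRows <- list()
  for (split in c("train", "val", "test")) {
    reps <- Filter(Negate(is.null),
                   lapply(foldReports, function(r) r[[split]]))
    if (!length(reps)) next
    mNames <- names(metricValues(reps[[1]]))
    for (nm in mNames) {
      vals <- vapply(reps, function(r) metricValues(r)[nm], numeric(1))
      s <- medianIQR(vals)
      aggRows[[length(aggRows) + 1L]] <- data.frame(
        split = split, metric = nm, median = s["median"], q1 = s["q1"],
        q3 = s["q3"], nFolds = sum(!is.na(vals)), row.names = NULL)
    }
  }
  out <- list(task = task, foldReports = foldReports,
              aggregate = do.call(rbind, aggRows), plan = plan,
              seed = as.integer(seed))
  if (task == "classification" && length(tileRows)) {
    # pooled test-tile predictions: every tile scored once, by the model
    # of the fold that held its case out. Pooled metrics are stabler than
    # per-fold ones when test blocks are small (2 cases can easily be
    # single-class).
    tp <- do.call(rbind, tileRows)
    out$testTilePredictions <- tp
    out$pooledTestAUC <- suppressWarnings(
      aucROC(tp$prob, tp$label == "positive"))
    out$pooledTestAccuracy <- mean((tp$prob > 0.5) ==
                                     (tp$label == "positive"))
  }
  if (task == "classification" && length(slideRows)) {
    sp <- do.call(rbind, slideRows)
    y <- sp$trueLabel == "positive"
    p <- sp$predictedLabel == "positive"
    cmS <- confusionMatrix(sum(p & y), sum(!p & !y), sum(p & !y),
                           sum(!p & y))
    out$slidePredictions <- sp
    out$slideConfusion <- cmS
    out$slideMetrics <- classificationMetrics(cmS)
    # per-fold slide-level test accuracy for the aggregate table
    accs <- vapply(split(sp, sp$fold), function(d)
      mean(d$predictedLabel == d$trueLabel), numeric(1))
    s <- medianIQR(accs)
    out$aggregate <- rbind(out$aggregate, data.frame(
      split = "test", metric = "slideAccuracy", median = s["median"],
      q1 = s["q1"], q3 = s["q3"], nFolds = length(accs),
      row.names = NULL))
  }
  class(out) <- "nestedCVResult"
  out
}

#' @export
print.nestedCVResult <- function(x, ...) {
  cat("Nested cross-validation (", x$task, "), ", x$plan@k,
      " folds\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-5s %-14s %.2f [%.2f-%.2f]\n", agg$split[i],
                agg$metric[i], agg$median[i], agg$q1[i], agg$q3[i]))
  if (!is.null(x$slideConfusion)) {
    cat("  test slides: ")
    show(x$slideConfusion)
  }
  invisible(x)
}
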