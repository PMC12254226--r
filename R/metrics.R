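# Evaluation statistics: confusion-matrix metrics, rank-based AUC, overlap
# metrics, agreement statistics, effect size, and median/IQR summaries.
# Metrics with vanishing denominators are reported as NA with an explicit
# undefined flag, never silently zero.

#' Construct a confusion matrix
#'
#' @param tp,tn,fp,fn nonnegative counts.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(25, 10, 5, 3) # slide-level counts over a 43-slide set
#' @export
confusionMatrix <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' Classification metrics from a confusion matrix
#'
#' Closed forms: accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, NPV `tn/(tn+fn)`,
#' F1 `2tp/(2tp+fp+fn)`.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return A [MetricReport-class]; metrics with zero denominators are NA
#'   and flagged undefined.
#' @examples
#' classificationMetrics(confusionMatrix(25, 10, 5, 3))
#' @export
classificationMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  k <- counts(cm)
  n <- sum(k)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- c(accuracy = div(k["tp"] + k["tn"], n),
         sensitivity = div(k["tp"], k["tp"] + k["fn"]),
         specificity = div(k["tn"], k["tn"] + k["fp"]),
         precision = div(k["tp"], k["tp"] + k["fp"]),
         npv = div(k["tn"], k["tn"] + k["fn"]),
         f1 = div(2 * k["tp"], 2 * k["tp"] + k["fp"] + k["fn"]))
  names(m) <- c("accuracy", "sensitivity", "specificity", "precision",
                "npv", "f1")
  newMetricReport(m, n, provenance = list(counts = k))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midrank tie handling: the probability
#' that a random positive outranks a random negative, counting ties as
#' one half.
#'
#' @param probabilities numeric scores.
#' @param labels logical or "positive"/"negative" or 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` (with a warning) when only one class is
#'   present.
#' @export
aucROC <- function(probabilities, labels) {
  y <- toLogicalLabels(labels)
  stopifnot(length(probabilities) == length(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

toLogicalLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "positive"
}

#' Intersection over union of two binary masks
#'
#' @param pred,truth congruent binary masks.
#' @return `|pred & truth| / |pred | truth|`. When both masks are empty
#'   the value is 1 with attribute `bothEmpty = TRUE` (a correct
#'   all-negative prediction is not penalized, but the case is flagged).
#' @export
iou <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- pred != 0; t <- truth != 0
  u <- sum(p | t)
  if (u == 0L) return(structure(1, bothEmpty = TRUE))
  sum(p & t) / u
}

#' Dice coefficient of two binary masks
#'
#' @param pred,truth congruent binary masks.
#' @return `2 |pred & truth| / (|pred| + |truth|)`; both-empty convention
#'   as in [iou()]. Algebraically `dice = 2 iou / (1 + iou)`.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- pred != 0; t <- truth != 0
  s <- sum(p) + sum(t)
  if (s == 0L) return(structure(1, bothEmpty = TRUE))
  2 * sum(p & t) / s
}

#' Concordance rate between two raters
#'
#' @param a,b equal-length label vectors.
#' @return Fraction of positions where the raters agree.
#' @export
concordanceRate <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 paired reads")
  mean(a == b)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement: `(po - pe) / (1 - pe)` with expected
#' agreement `pe` from the product of the raters' marginal distributions.
#'
#' @param a,b equal-length label vectors.
#' @return Kappa; `NA` with a warning when `pe = 1` (both raters constant
#'   and identical, agreement indistinguishable from chance).
#' @export
cohenKappa <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 paired reads")
  lev <- union(unique(a), unique(b))
  pa <- table(factor(a, lev)) / length(a)
  pb <- table(factor(b, lev)) / length(b)
  po <- mean(a == b)
  pe <- sum(pa * pb)
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Spearman rank correlation
#'
#' Thin wrapper over `stats::cor(..., method = "spearman")` (Pearson on
#' midranks), with an explicit undefined flag for constant input.
#'
#' @param x,y numeric vectors of length >= 3.
#' @return Correlation in \[-1, 1\] or `NA` with a warning.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Cohen's d effect size
#'
#' Difference of group means over the pooled standard deviation.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return d; `NA` with a warning when the pooled sd is zero.
#' @export
cohensD <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    warning("Cohen's d undefined: pooled variance is zero")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation (`stats::quantile` type 7).
#'
#' @param values numeric vector.
#' @return Named vector `c(median, q1, q3)`.
#' @export
medianIQR <- function(values) {
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
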