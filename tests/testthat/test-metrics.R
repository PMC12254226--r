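# Evaluation statistics against independent oracles.

test_that("classification metrics match brute-force formulas on random matrices", {
  set.seed(5)
  for (i in 1:1000) {
    k <- sample(0:30, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    rep <- classificationMetrics(confusionMatrix(k[1], k[2], k[3], k[4]))
    m <- metricValues(rep)
    naive <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_equal(unname(m["accuracy"]), (k[1] + k[2]) / sum(k))
    expect_equal(unname(m["sensitivity"]), naive(k[1], k[1] + k[4]))
    expect_equal(unname(m["specificity"]), naive(k[2], k[2] + k[3]))
    expect_equal(unname(m["precision"]), naive(k[1], k[1] + k[3]))
    expect_equal(unname(m["npv"]), naive(k[2], k[2] + k[4]))
    expect_equal(unname(m["f1"]),
                 naive(2 * k[1], 2 * k[1] + k[3] + k[4]))
  }
})

test_that("undefined metrics are flagged, not zero", {
  rep <- classificationMetrics(confusionMatrix(0, 12, 0, 0))
  m <- metricValues(rep)
  expect_equal(unname(m["specificity"]), 1)
  expect_true(is.na(m["sensitivity"]))
  expect_false(rep@defined["sensitivity"])
  expect_true(rep@defined["specificity"])
  expect_error(confusionMatrix(0, 0, 0, 0) |> validObject(), "empty")
})

test_that("rank AUC equals the all-pairs oracle and pROC", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    p <- round(runif(n), 2) # ties on purpose
    ours <- aucROC(p, y)
    pairs <- 0; tot <- 0
    for (a in which(y)) for (b in which(!y)) {
      tot <- tot + 1
      pairs <- pairs + (p[a] > p[b]) + 0.5 * (p[a] == p[b])
    }
    expect_equal(ours, pairs / tot)
    expect_equal(ours,
                 as.numeric(suppressMessages(pROC::auc(y, p,
                                                       direction = "<"))))
  }
  expect_equal(aucROC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_warning(a <- aucROC(runif(5), rep(TRUE, 5)), "one class")
  expect_true(is.na(a))
  set.seed(7)
  expect_lt(abs(aucROC(runif(1000),
                       sample(c(TRUE, FALSE), 1000, TRUE)) - 0.5), 0.05)
})

test_that("Dice-IoU identity holds to 1e-12 on random masks", {
  set.seed(8)
  for (i in 1:200) {
    a <- matrix(runif(100) > runif(1), 10, 10)
    b <- matrix(runif(100) > runif(1), 10, 10)
    if (!any(a | b)) next
    expect_equal(as.numeric(dice(a, b)),
                 2 * as.numeric(iou(a, b)) / (1 + as.numeric(iou(a, b))),
                 tolerance = 1e-12)
  }
  m <- matrix(c(TRUE, FALSE), 4, 4)
  expect_equal(as.numeric(iou(m, m)), 1)
  expect_equal(as.numeric(dice(m, m)), 1)
  expect_equal(as.numeric(iou(m, !m)), 0)
  e <- matrix(FALSE, 4, 4)
  expect_equal(as.numeric(iou(e, e)), 1)
  expect_true(attr(iou(e, e), "bothEmpty"))
  expect_error(iou(e, matrix(FALSE, 2, 2)), "shape")
})

test_that("agreement statistics: concordance, kappa and its null", {
  a <- rep(c("positive", "negative"), c(28, 15))
  b <- a; b[43] <- "positive" # one discordant read out of 43
  expect_equal(round(concordanceRate(a, b), 2), 0.98)
  expect_equal(cohenKappa(a, a), 1)
  expect_error(concordanceRate(a, b[1:10]), "length")

  # independent cross-check against e1071's kappa on a random table
  set.seed(9)
  x <- sample(0:1, 200, TRUE); y <- ifelse(runif(200) < 0.7, x,
                                           sample(0:1, 200, TRUE))
  expect_equal(cohenKappa(x, y),
               e1071::classAgreement(table(x, y))$kappa)

  set.seed(10)
  r1 <- sample(0:1, 1e4, TRUE); r2 <- sample(0:1, 1e4, TRUE)
  expect_lt(abs(cohenKappa(r1, r2)), 0.05)
  expect_warning(k <- cohenKappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(k))
})

test_that("spearman, Cohen's d and median/IQR behave per definition", {
  expect_equal(spearmanCor(1:10, (1:10)^3), 1)
  expect_equal(spearmanCor(1:10, -(1:10)), -1)
  expect_warning(s <- spearmanCor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s))

  expect_equal(cohensD(c(1, 2, 3), c(2, 1, 3)), 0)
  # hand-computed: means 2 and 4, pooled sd 1 -> d = -2
  expect_equal(cohensD(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_warning(d <- cohensD(rep(2, 4), rep(2, 4)), "undefined")
  expect_true(is.na(d))

  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(unname(medianIQR(v)),
               unname(stats::quantile(v, c(0.5, 0.25, 0.75), type = 7)))
})
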