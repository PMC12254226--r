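# Synthetic slide generator: determinism, burden control, channel
# separability, and the cohort bookkeeping.

test_that("zero target burden gives an empty truth mask and negative label", {
  sl <- generateSlide(smallSpec(targetBurden = 0, pattern = "nodular"))
  expect_equal(sum(truthAmyloid(sl)), 0)
  expect_identical(slideLabel(sl), "negative")
  expect_equal(sl@meta$achievedBurden, 0)
})

test_that("achieved burden is within 10% relative of the target for every pattern", {
  for (p in c("diffuse_pericellular", "discrete_pericellular",
              "nodular", "vascular")) {
    sl <- generateSlide(smallSpec(targetBurden = 0.15, pattern = p,
                                  seed = 7))
    expect_lt(abs(sl@meta$achievedBurden - 0.15) / 0.15, 0.10,
              label = paste("relative burden error for", p))
    expect_true(all(truthAmyloid(sl) <= truthTissue(sl)))
  }
})

test_that("identical spec and seed give bit-identical slides", {
  sp <- smallSpec(targetBurden = 0.12, pattern = "vascular", seed = 42)
  a <- generateSlide(sp); b <- generateSlide(sp)
  expect_identical(serialize(tritc(a), NULL), serialize(tritc(b), NULL))
  expect_identical(scramble(a), scramble(b))
  expect_identical(brightfield(a), brightfield(b))
  expect_identical(truthAmyloid(a), truthAmyloid(b))
})

test_that("noise-free channel difference is positive exactly on amyloid", {
  sl <- generateSlide(smallSpec(targetBurden = 0.15, noiseSd = 0,
                                confounderFraction = 0.08, seed = 3))
  d <- subtractChannels(tritc(sl), scramble(sl))
  amy <- truthAmyloid(sl) > 0
  expect_true(all(d[amy] > 0))
  expect_true(all(d[!amy] <= 0))
})

test_that("confounders defeat single-channel thresholding but not subtraction", {
  sl <- generateSlide(smallSpec(targetBurden = 0.10, pattern = "nodular",
                                confounderFraction = 0.08, seed = 5))
  seg <- segmentSlide(sl)
  thrT <- otsuThreshold(tritc(sl)[seg$tissue])
  naive <- tritc(sl) > thrT & seg$tissue
  truth <- truthAmyloid(sl) > 0
  fpNaive <- sum(naive & !truth)
  fpSubtracted <- sum(seg$amyloid & !truth)
  expect_gt(fpNaive, fpSubtracted)
  expect_gt(fpNaive, 100) # the confounder really is picked up
})

test_that("unachievable burden raises a placement error", {
  expect_error(
    generateSlide(smallSpec(targetBurden = 0.95, pattern = "vascular")),
    "unachievable|exceeds")
})

test_that("cohort label counts, ids and reproducibility", {
  co <- generateCohort(43, 28 / 43, seed = 0,
                       baseSpec = smallSpec(widthPx = 128L,
                                            heightPx = 128L))
  expect_equal(sum(co$cases$label == "positive"), 28)
  expect_equal(sum(co$cases$label == "negative"), 15)
  expect_equal(length(co$slides), 43)
  expect_false(anyDuplicated(co$cases$caseId) > 0)
  for (sl in co$slides) {
    lab <- co$cases$label[match(caseId(sl), co$cases$caseId)]
    expect_identical(slideLabel(sl), lab)
    if (lab == "positive") expect_gt(sum(truthAmyloid(sl)), 0)
    else expect_equal(sum(truthAmyloid(sl)), 0)
  }
  co2 <- generateCohort(43, 28 / 43, seed = 0,
                        baseSpec = smallSpec(widthPx = 128L,
                                             heightPx = 128L))
  expect_identical(tritc(co$slides[[1]]), tritc(co2$slides[[1]]))
})

test_that("degenerate cohorts: all-negative and slide multiplicity", {
  co <- generateCohort(4, 0, slidesPerCase = 2, seed = 1,
                       baseSpec = smallSpec(widthPx = 128L,
                                            heightPx = 128L))
  expect_true(all(co$cases$label == "negative"))
  expect_equal(length(co$slides), 8)
  expect_equal(length(unique(vapply(co$slides, caseId, ""))), 4)
})
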