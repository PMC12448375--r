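test_that("floor-rule split sizes reproduce the published cohort counts", {
  expect_identical(splitSize(23809, 0.8), 19047L)
  expect_identical(splitSize(20072, 0.8), 16057L)
  expect_identical(splitSize(23809, 0.95), 22618L)
})

test_that("splits are seeded partitions with floor-rule train sizes", {
  b <- makeBenchmark(203, 157, seed = 2)
  sp <- splitDatasets(b$tagged, b$untagged, seed = 2)
  expect_identical(ncol(sp$trainMC$tagged), 162L)       # floor(0.8*203)
  expect_identical(ncol(sp$trainMC$untagged), 125L)     # floor(0.8*157)
  expect_identical(ncol(sp$trainAE), 192L)              # floor(0.95*203)
  for (cohort in list(
    list(sp$trainMC$tagged, sp$testMC$tagged, b$tagged),
    list(sp$trainMC$untagged, sp$testMC$untagged, b$untagged),
    list(sp$trainAE, sp$testAE$tagged, b$tagged))) {
    tr <- scanIds(cohort[[1]]); te <- scanIds(cohort[[2]])
    expect_length(intersect(tr, te), 0L)
    expect_setequal(c(tr, te), scanIds(cohort[[3]]))
  }
  sp2 <- splitDatasets(b$tagged, b$untagged, seed = 2)
  expect_identical(scanIds(sp2$trainMC$tagged), scanIds(sp$trainMC$tagged))
})

test_that("the trustworthy test set keeps nCF tags plus rule-verified CF", {
  b <- makeBenchmark(60, 60, cfWeight = 0.4, seed = 4)
  sp <- splitDatasets(b$tagged, b$untagged, seed = 4)
  untag <- sp$testMC$untagged
  truth <- SummarizedExperiment::colData(untag)$truth
  # upstream structure calls flag exactly the true-CF scans
  labels <- data.frame(scan_id = scanIds(untag),
                       label = ifelse(truth == "CF", "CF", "UNLABELED"))
  prime <- buildTestPrime(sp$testMC, labels)
  expect_identical(ncol(prime),
                   ncol(sp$testMC$tagged) + sum(truth == "CF"))
  expect_identical(sum(cfLabels(prime) == "CF"), sum(truth == "CF"))
  # no CF labels at all -> nCF-only evaluation with a warning
  none <- data.frame(scan_id = scanIds(untag), label = "UNLABELED")
  expect_warning(only <- buildTestPrime(sp$testMC, none), "nCF only")
  expect_identical(ncol(only), ncol(sp$testMC$tagged))
})

test_that("metrics follow the confusion-matrix identities", {
  perfect <- evaluateMetrics(c("CF", "nCF", "CF"), c("CF", "nCF", "CF"))
  expect_equal(perfect$overall_acc, 1)
  expect_equal(perfect$f1, 1)
  allN <- evaluateMetrics(rep("nCF", 10), rep(c("CF", "nCF"), 5))
  expect_equal(allN$overall_acc, 0.5)
  expect_equal(allN$cf_acc, 0)
  hand <- evaluateMetrics(
    c(rep("CF", 95), rep("nCF", 105)),
    c(rep("CF", 90), rep("nCF", 5), rep("CF", 10), rep("nCF", 95)))
  expect_identical(c(hand$tp, hand$fp, hand$fn, hand$tn),
                   c(90L, 5L, 10L, 95L))
  expect_equal(hand$cf_acc, 0.90)
  expect_equal(hand$f1, 0.923, tolerance = 1e-3)
  expect_equal(hand$overall_acc, (hand$tp + hand$tn) / 200)
  und <- evaluateMetrics(c("UNDETERMINED", "CF"), c("CF", "CF"))
  expect_identical(und$n_undetermined, 1L)
  expect_equal(und$cf_acc, 1)
})

test_that("robustness grid populates every cell on nested subsets", {
  b <- makeBenchmark(250, 250, seed = 6)
  sp <- splitDatasets(b$tagged, b$untagged, seed = 6)
  test <- sp$testMC$untagged
  truth <- SummarizedExperiment::colData(test)$truth
  res <- robustnessExperiment(sp$trainMC$tagged, sp$trainMC$untagged,
                              test, truth, minCIValues = c(3L, 5L),
                              seed = 6)
  expect_identical(nrow(res), 2L * 2L * 2L)
  expect_false(anyNA(res$overall_acc))
  # training subsets are nested as the CI requirement tightens
  keep <- lapply(c(3L, 4L, 5L, 6L), function(k)
    scanIds(b$tagged)[minCIFilter(b$tagged, k)])
  for (i in 1:3) expect_true(all(keep[[i + 1]] %in% keep[[i]]))
  expect_identical(sum(minCIFilter(b$tagged, 0L)), ncol(b$tagged))
})

test_that("simulate-extract-label-split-train-evaluate is reproducible", {
  runOnce <- function() {
    dir <- tempfile()
    paths <- simulateDataset(dir, nCase = 150, nControl = 120, seed = 31,
                             jitterPpm = 5)
    sp <- readSpectra(paths$mgf)
    psms <- readPSMTable(paths$psm)
    fs <- extractFeatures(sp, psms, minCI = 0L)
    lab <- trustworthyLabel(psms)
    ncf <- scanIds(fs) %in% lab$scan_id[lab$label == "nCF"]
    split <- splitDatasets(fs[, ncf], fs[, !ncf], seed = 31)
    mc <- trainMC(split$trainMC$tagged, split$trainMC$untagged, seed = 31)
    ae <- trainAE(split$trainAE, minTrain = 50L, epochs = 60, seed = 31)
    test <- split$testMC$untagged
    list(mc = predict(mc, test), ae = predict(ae, test),
         w = ae@weights[[1]], n = mc@identifiedCF)
  }
  a <- runOnce(); b <- runOnce()
  expect_identical(a, b)
})
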