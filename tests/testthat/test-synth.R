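test_that("sampled cohorts recover their generating parameters", {
  p <- referenceCohortParams()
  spec <- list(list(name = "nCF", weight = 1, mu = p$case_mu,
                    sigma = p$case_sigma, dropout = rep(0, 10)))
  fs <- sampleFeatureCohort(spec, 50000, seed = 42, normalization = "none")
  raw <- rawIntensity(fs)
  for (i in 1:10) {
    fit <- fitLogGaussian(raw[i, raw[i, ] > 0])
    expect_equal(unname(fit["mu"]), p$case_mu[i], tolerance = 0.012)
    expect_equal(unname(fit["sigma"]), p$case_sigma[i], tolerance = 0.012)
  }
})

test_that("dropout, determinism and input validation", {
  spec <- caseCohortSpec()
  spec[[1]]$dropout[3] <- 1
  fs <- sampleFeatureCohort(spec, 500, seed = 1)
  expect_false(any(matchedMask(fs)[3, ]))
  expect_true(all(rawIntensity(fs)[3, ] == 0))
  a <- sampleFeatureCohort(caseCohortSpec(), 200, seed = 5)
  b <- sampleFeatureCohort(caseCohortSpec(), 200, seed = 5)
  expect_identical(rawIntensity(a), rawIntensity(b))
  expect_error(sampleFeatureCohort(caseCohortSpec(), 0), "positive")
  badW <- caseCohortSpec(); badW[[1]]$weight <- 0.5
  expect_error(sampleFeatureCohort(badW, 10), "sum to 1")
})

test_that("synthetic spectra respect the matcher's tolerance window", {
  x <- c(0.5, 0.3, 0.2, 0, 0, 0.1, 0, 0.05, 0, 0)
  pm <- peptideMonoisotopicMass("SAMPLEK")
  psm <- psmRows("j"); psm$peptide_mass <- pm
  psms <- readPSMTable(writePSMFixture(psm))
  recover <- function(jitter) {
    sp <- synthesizeSpectrum("j", pm, x, noisePeaks = 10,
                             jitterPpm = jitter, guardPpm = 40, seed = 9)
    matchCIPeaks(sp, pm, tolPpm = 20)
  }
  expect_identical(recover(0)$mask, x > 0)
  expect_equal(recover(0)$raw, x, tolerance = 1e-9)
  expect_identical(recover(10)$mask, x > 0)   # 10 ppm inside a 20 ppm window
  expect_false(any(recover(30)$mask))         # 30 ppm outside it
})

test_that("benchmark mixture weights drive the hidden truth", {
  b0 <- makeBenchmark(100, 100, cfWeight = 0, seed = 3)
  expect_true(all(b0$truth == "nCF"))
  b1 <- makeBenchmark(100, 100, cfWeight = 1, seed = 3)
  expect_true(all(b1$truth == "CF"))
  # default benchmark is separable enough for the single-ratio baseline
  b <- makeBenchmark(2000, 2000, seed = 42)
  m <- evaluateMetrics(y1fY1Baseline(b$untagged), b$truth)
  expect_gt((m$cf_acc + m$ncf_acc) / 2, 0.8)
})

test_that("empirical KL converges to the closed form with sample size", {
  p <- referenceCohortParams()
  target <- symmetricKLGaussian(c(p$case_mu[1], p$case_sigma[1]),
                                c(p$control_mu[1], p$control_sigma[1]))
  dev <- vapply(c(1e3, 1e4, 1e5), function(n) {
    set.seed(42)
    ca <- 10^rnorm(n, p$case_mu[1], p$case_sigma[1])
    co <- 10^rnorm(n, p$control_mu[1], p$control_sigma[1])
    abs(symmetricKLGaussian(fitLogGaussian(ca), fitLogGaussian(co)) -
          target)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})

test_that("simulated datasets replay through the whole input path", {
  dir <- tempfile()
  paths <- simulateDataset(dir, nCase = 25, nControl = 25, seed = 17,
                           jitterPpm = 5)
  sp <- readSpectra(paths$mgf)
  psms <- readPSMTable(paths$psm)
  expect_length(sp, 50L)
  fs <- extractFeatures(sp, psms, minCI = 0L)
  expect_identical(ncol(fs), 50L)
  expect_identical(sort(scanIds(fs)), sort(psms$scan_id))
  # trustworthy labels match the simulated truth for the CF component
  lab <- trustworthyLabel(psms)
  truth <- read.delim(paths$truth)
  cfScans <- truth$scan_id[truth$truth == "CF"]
  expect_setequal(lab$scan_id[lab$label == "CF"], cfScans)
})
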