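smallTrain <- function(n = 200L, seed = 8L)
  sampleFeatureCohort(caseCohortSpec(), n, seed = seed)

test_that("alpha always equals mu + k * sigma", {
  ae <- trainAE(smallTrain(), epochs = 30, seed = 1)
  expect_equal(ae@alpha, ae@mu + 0.4 * ae@sigma)
  # formula arithmetic at other k
  ae2 <- setThresholdK(ae, 0)
  expect_equal(ae2@alpha, ae2@mu)
  ae3 <- setThresholdK(ae, 2.5)
  expect_equal(ae3@alpha, ae@mu + 2.5 * ae@sigma)
  # mu = 0.10, sigma = 0.05, k = 0.4 -> alpha = 0.12
  ae@mu <- 0.10; ae@sigma <- 0.05
  expect_equal(setThresholdK(ae, 0.4)@alpha, 0.12)
})

test_that("training reduces reconstruction error below random weights", {
  X <- sampleFeatureCohort(caseCohortSpec(), 5000L, seed = 21)
  trained <- trainAE(X, epochs = 60, seed = 2)
  frozen <- trainAE(X, epochs = 1, learningRate = 0, seed = 2)
  expect_lt(mean(reconstructionError(trained, X)),
            mean(reconstructionError(frozen, X)))
})

test_that("reconstruction error is a non-negative deterministic norm", {
  ae <- trainAE(smallTrain(), epochs = 30, seed = 3)
  X <- t(normIntensity(smallTrain(50, seed = 30)))
  e1 <- reconstructionError(ae, X)
  expect_true(all(e1 >= 0))
  expect_identical(e1, reconstructionError(ae, X))
  # capacity check: a single repeated vector is reconstructed ~perfectly
  v <- sumNormalize(c(0.4, 0.3, 0.1, 0.05, 0.05, 0.02, 0, 0, 0.05, 0.03))
  one <- matrix(v, 200, 10, byrow = TRUE)
  aeOne <- trainAE(one, epochs = 400, patience = 400, seed = 4)
  expect_lt(reconstructionError(aeOne, v), 1e-2)
})

test_that("the CF call uses a strict inequality at alpha", {
  ae <- trainAE(smallTrain(), epochs = 30, seed = 5)
  x <- t(normIntensity(smallTrain(1, seed = 50)))
  err <- reconstructionError(ae, x)
  # place alpha exactly at this vector's error: not strictly above -> nCF
  atErr <- setThresholdK(ae, (err - ae@mu) / ae@sigma)
  expect_equal(atErr@alpha, err, tolerance = 1e-12)
  expect_identical(predict(atErr, x), "nCF")
  expect_identical(predict(setThresholdK(ae, 1e6), x), "nCF")
  expect_identical(predict(setThresholdK(ae, -1e6), x), "CF")
})

test_that("flag rate at k = 0 is a central quantile and decreases with k", {
  X <- smallTrain(1000, seed = 6)
  ae <- trainAE(X, seed = 6)
  err <- reconstructionError(ae, X)
  frac0 <- mean(err > setThresholdK(ae, 0)@alpha)
  expect_gt(frac0, 0.2); expect_lt(frac0, 0.8)
  rates <- vapply(c(0, 0.2, 0.4, 1, 5), function(k)
    mean(predict(setThresholdK(ae, k), X) == "CF"), numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("the detector flags the CF mixture component above held-out nCF", {
  bench <- makeBenchmark(800, 800, cfWeight = 0.3, seed = 13)
  ae <- trainAE(bench$tagged, seed = 13)
  held <- sampleFeatureCohort(caseCohortSpec(), 400, seed = 131)
  pu <- predict(ae, bench$untagged)
  cfRate <- mean(pu[bench$truth == "CF"] == "CF")
  heldRate <- mean(predict(ae, held) == "CF")
  expect_gt(cfRate, heldRate)
})

test_that("training is bit-reproducible under a fixed seed", {
  X <- smallTrain(300, seed = 7)
  a <- trainAE(X, epochs = 40, seed = 77)
  b <- trainAE(X, epochs = 40, seed = 77)
  expect_identical(a@weights, b@weights)
  expect_identical(a@alpha, b@alpha)
})

test_that("invalid training inputs are rejected", {
  X <- smallTrain(200)
  expect_error(trainAE(t(normIntensity(X))[1:50, ]), "at least")
  bad <- t(normIntensity(X)); bad[1, 1] <- 1.5
  expect_error(trainAE(bad), "\\[0,1\\]")
})
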