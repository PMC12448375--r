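#' @include AllClasses.R features.R
NULL

# forward pass: returns list of per-layer activations (input first);
# tanh on every hidden layer and on the output layer
.aeForward <- function(W, b, X) {
  act <- vector("list", length(W) + 1L)
  act[[1L]] <- X
  for (l in seq_along(W))
    act[[l + 1L]] <- tanh(sweep(act[[l]] %*% W[[l]], 2L, b[[l]], `+`))
  act
}

.aeReconstruct <- function(model, X) {
  act <- .aeForward(model@weights, model@biases, X)
  act[[length(act)]]
}

#' Train the autoencoder anomaly detector
#'
#' Fits the fixed 10-9-8-7-8-9-10 fully connected tanh autoencoder to the
#' tagged nCF training vectors by minimising mean squared reconstruction
#' error with the Adam optimiser. After training, the per-vector Euclidean
#' reconstruction errors of the training set give \code{mu} and \code{sigma},
#' and the CF decision threshold is \code{alpha = mu + k * sigma}.
#'
#' @param X Training vectors (tagged nCF): \linkS4class{CIFeatureSet} or
#'   n x 10 matrix of normalised features in [0,1].
#' @param k Threshold multiplier (default 0.4).
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize Minibatch size (default 256).
#' @param epochs Maximum epochs (default 500).
#' @param patience Early-stop patience: stop when the epoch loss has not
#'   improved by \code{tol} for this many epochs (default 20).
#' @param tol Minimum loss improvement counted as progress (default 1e-7).
#' @param minTrain Minimum training-set size (default 100).
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return An \linkS4class{AEModel}.
#' @export
trainAE <- function(X, k = 0.4, learningRate = 1e-3, batchSize = 256L,
                    epochs = 500L, patience = 20L, tol = 1e-7,
                    minTrain = 100L, seed = 42L) {
  X <- .featureMatrix(X)
  if (nrow(X) < minTrain)
    stop("need at least ", minTrain, " training vectors")
  if (any(X < 0 | X > 1))
    stop("training vectors must lie in [0,1]")
  sizes <- c(10L, 9L, 8L, 7L, 8L, 9L, 10L)
  cfg <- list(learningRate = learningRate, batchSize = batchSize,
              epochs = epochs, patience = patience, tol = tol, seed = seed)
  set.seed(seed)
  nL <- length(sizes) - 1L
  W <- b <- mW <- vW <- mb <- vb <- vector("list", nL)
  for (l in seq_len(nL)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))   # Glorot uniform
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
    mW[[l]] <- vW[[l]] <- matrix(0, sizes[l], sizes[l + 1L])
    mb[[l]] <- vb[[l]] <- numeric(sizes[l + 1L])
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X); step <- 0L
  lossHistory <- numeric(); best <- Inf; stall <- 0L
  for (epoch in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = batchSize)
    epochLoss <- 0
    for (s in starts) {
      rows <- idx[s:min(s + batchSize - 1L, n)]
      xb <- X[rows, , drop = FALSE]
      act <- .aeForward(W, b, xb)
      out <- act[[nL + 1L]]
      resid <- out - xb
      epochLoss <- epochLoss + sum(resid^2)
      # backprop: d(mean sq err)/d(out), tanh' = 1 - a^2
      delta <- (2 * resid / (length(rows) * 10)) * (1 - out^2)
      step <- step + 1L
      for (l in rev(seq_len(nL))) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * (1 - act[[l]]^2)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - learningRate * (mW[[l]] / c1) /
          (sqrt(vW[[l]] / c2) + eps)
        b[[l]] <- b[[l]] - learningRate * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + eps)
      }
    }
    epochLoss <- epochLoss / (n * 10)
    if (!is.finite(epochLoss)) {
      stop("autoencoder training diverged (loss not finite); config: ",
           paste(names(cfg), unlist(cfg), sep = "=", collapse = ", "))
    }
    lossHistory <- c(lossHistory, epochLoss)
    if (epochLoss < best - tol) { best <- epochLoss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= patience) break
  }
  model <- new("AEModel", layerSizes = sizes, weights = W, biases = b,
               k = k, mu = 0, sigma = 0, alpha = 0, config = cfg,
               lossHistory = lossHistory)
  err <- reconstructionError(model, X)
  model@mu <- mean(err)
  model@sigma <- stats::sd(err)
  model@alpha <- model@mu + k * model@sigma
  validObject(model)
  model
}

#' Reconstruction error of feature vectors
#'
#' Euclidean norm of \code{X - g(f(X))}, one value per vector.
#'
#' @param model An \linkS4class{AEModel}.
#' @param X \linkS4class{CIFeatureSet} or n x 10 matrix (a length-10 vector
#'   is treated as one sample).
#' @return Non-negative numeric vector of length n.
#' @export
setMethod("reconstructionError", "AEModel", function(model, X) {
  if (is.numeric(X) && is.null(dim(X)) && length(X) == 10L)
    X <- matrix(X, nrow = 1L)
  X <- .featureMatrix(X)
  unname(sqrt(rowSums((X - .aeReconstruct(model, X))^2)))
})

#' Predict CF/nCF with a trained autoencoder model
#'
#' A spectrum is called CF when its reconstruction error strictly exceeds
#' \code{alpha}; an error equal to \code{alpha} is nCF.
#'
#' @param object An \linkS4class{AEModel}.
#' @param newdata \linkS4class{CIFeatureSet} or n x 10 matrix.
#' @param ... Unused.
#' @return Character vector of \code{"CF"} / \code{"nCF"}.
#' @export
setMethod("predict", "AEModel", function(object, newdata, ...) {
  err <- reconstructionError(object, newdata)
  unname(ifelse(err > object@alpha, "CF", "nCF"))
})

#' Re-threshold a trained autoencoder
#'
#' Changes \code{k} (and hence \code{alpha = mu + k * sigma}) without
#' retraining.
#'
#' @param model An \linkS4class{AEModel}.
#' @param k New threshold multiplier.
#' @return The updated model.
#' @export
setThresholdK <- function(model, k) {
  model@k <- k
  model@alpha <- model@mu + k * model@sigma
  validObject(model)
  model
}
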