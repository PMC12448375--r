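#' @include AllClasses.R features.R
NULL

# coerce a CIFeatureSet or matrix to the samples-by-features layout models use
.featureMatrix <- function(x) {
  if (is(x, "CIFeatureSet")) x <- t(normIntensity(x))
  x <- as.matrix(x)
  if (ncol(x) != 10L) stop("feature matrix must have 10 columns (CI1..CI10)")
  x
}

# RBF bandwidth heuristic: 1 / (10 * mean per-feature variance)
.gammaHeuristic <- function(P) {
  v <- mean(apply(P, 2L, stats::var))
  if (!is.finite(v) || v <= 0) 1 / ncol(P) else 1 / (10 * v)
}

#' Train the mapping-convergence (MC) classifier
#'
#' Positive-unlabelled learning in two phases. Mapping: a one-class
#' support-vector boundary (SVDD role) fit on the tagged nCF set \code{P}
#' splits the untagged set \code{U} into an initial negative (CF candidate)
#' set N0 and positive remainder P0. Convergence: repeatedly fit a binary
#' RBF SVM on (P = nCF, N = CF), reclassify the current positive remainder,
#' move its predicted negatives into N, and stop when an iteration finds no
#' new negatives. Returns the final classifier and the identified-CF set N.
#'
#' @param P Tagged nCF vectors: \linkS4class{CIFeatureSet} or n x 10 matrix
#'   of normalised features.
#' @param U Untagged vectors, same layout.
#' @param nu One-class outlier fraction bound (default 0.05).
#' @param cost Binary SVM soft-margin cost (default 1).
#' @param gamma RBF bandwidth; default \code{1/(10 * mean feature variance)}
#'   of \code{P}.
#' @param maxIter Safety cap on convergence iterations (default 100).
#' @param minPos Minimum size of \code{P} (default 10).
#' @param classWeights Optional named class weights (\code{nCF}, \code{CF})
#'   for the binary phase; the literal algorithm uses none.
#' @param seed Seed applied before the (deterministic) solver calls so the
#'   whole run is reproducible.
#' @return An \linkS4class{MCModel}.
#' @export
trainMC <- function(P, U, nu = 0.05, cost = 1, gamma = NULL,
                    maxIter = 100L, minPos = 10L, classWeights = NULL,
                    seed = 42L) {
  P <- .featureMatrix(P)
  if (nrow(P) < minPos)
    stop("need at least ", minPos, " tagged nCF vectors")
  U <- if (is.null(U) || (is.matrix(U) && nrow(U) == 0L)) {
    matrix(numeric(), ncol = 10L)
  } else .featureMatrix(U)
  if (is.null(gamma)) gamma <- .gammaHeuristic(P)
  cfg <- list(nu = nu, cost = cost, gamma = gamma, maxIter = maxIter,
              classWeights = classWeights, seed = seed)
  set.seed(seed)
  h0 <- e1071::svm(P, y = NULL, type = "one-classification",
                   kernel = "radial", nu = nu, gamma = gamma, scale = FALSE)
  if (nrow(U) == 0L)
    return(new("MCModel", h = h0, hType = "one-class",
               identifiedCF = integer(), iterations = 0L, converged = TRUE,
               history = integer(), config = cfg))
  inClass <- as.logical(predict(h0, U))
  N <- which(!inClass)            # mapping-phase negatives N0
  Pi <- which(inClass)            # positive remainder P0
  if (length(N) == 0L) {
    warning("mapping phase found no negatives in U; ",
            "returning the one-class boundary")
    return(new("MCModel", h = h0, hType = "one-class",
               identifiedCF = integer(), iterations = 0L, converged = TRUE,
               history = integer(), config = cfg))
  }
  history <- integer()
  h <- NULL
  iter <- 0L
  converged <- FALSE
  lev <- c("nCF", "CF")
  while (iter < maxIter) {
    iter <- iter + 1L
    x <- rbind(P, U[N, , drop = FALSE])
    y <- factor(rep(lev, c(nrow(P), length(N))), levels = lev)
    h <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    class.weights = classWeights)
    if (length(Pi) == 0L) { converged <- TRUE; break }
    pred <- predict(h, U[Pi, , drop = FALSE])
    newNeg <- Pi[pred == "CF"]
    history <- c(history, length(newNeg))
    if (length(newNeg) == 0L) { converged <- TRUE; break }
    N <- c(N, newNeg)
    Pi <- setdiff(Pi, newNeg)
  }
  if (!converged)
    warning("mapping-convergence hit the iteration cap (", maxIter,
            ") before N stabilised")
  new("MCModel", h = h, hType = "binary", identifiedCF = sort(N),
      iterations = iter, converged = converged, history = history,
      config = cfg)
}

#' Predict CF/nCF with a trained MC model
#'
#' @param object An \linkS4class{MCModel}.
#' @param newdata \linkS4class{CIFeatureSet} or n x 10 matrix of normalised
#'   features.
#' @param ... Unused.
#' @return Character vector of \code{"CF"} / \code{"nCF"}.
#' @export
setMethod("predict", "MCModel", function(object, newdata, ...) {
  X <- .featureMatrix(newdata)
  if (object@hType == "one-class") {
    inClass <- as.logical(predict(object@h, X))
    ifelse(inClass, "nCF", "CF")
  } else {
    as.character(predict(object@h, X))
  }
})
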