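#' @include AllClasses.R features.R labeling.R mcModel.R aeModel.R synth.R
NULL

#' Training-set size under the floor rule
#'
#' @param n Cohort size.
#' @param frac Training fraction in (0,1).
#' @return \code{floor(frac * n)} as integer.
#' @export
splitSize <- function(n, frac) {
  stopifnot(frac > 0, frac < 1)
  as.integer(floor(frac * n))
}

#' Split tagged and untagged cohorts for model training
#'
#' The two cohorts are shuffled and split independently. The
#' mapping-convergence model trains on \code{mcTrainFrac} (default 80\%) of
#' both the tagged and the untagged cohort; the autoencoder trains on
#' \code{aeTrainFrac} (default 95\%) of the tagged cohort only. Test
#' portions are the complements. Train sizes follow the floor rule.
#'
#' @param tagged,untagged \linkS4class{CIFeatureSet}s.
#' @param mcTrainFrac,aeTrainFrac Training fractions.
#' @param seed Seed for the shuffles.
#' @return List with \code{trainMC} (list \code{tagged}, \code{untagged}),
#'   \code{testMC} (ditto), \code{trainAE} (tagged CIFeatureSet) and
#'   \code{testAE} (list \code{tagged}, \code{untagged}).
#' @export
splitDatasets <- function(tagged, untagged, mcTrainFrac = 0.8,
                          aeTrainFrac = 0.95, seed = 42L) {
  stopifnot(ncol(tagged) > 0L)
  set.seed(seed)
  permT <- sample.int(ncol(tagged))
  permU <- if (ncol(untagged)) sample.int(ncol(untagged)) else integer()
  take <- function(perm, k) list(train = sort(perm[seq_len(k)]),
                                 test = sort(perm[-seq_len(k)]))
  mcT <- take(permT, splitSize(ncol(tagged), mcTrainFrac))
  mcU <- take(permU, splitSize(ncol(untagged), mcTrainFrac))
  aeT <- take(permT, splitSize(ncol(tagged), aeTrainFrac))
  aeU <- take(permU, splitSize(ncol(untagged), aeTrainFrac))
  list(
    trainMC = list(tagged = tagged[, mcT$train],
                   untagged = untagged[, mcU$train]),
    testMC  = list(tagged = tagged[, mcT$test],
                   untagged = untagged[, mcU$test]),
    trainAE = tagged[, aeT$train],
    testAE  = list(tagged = tagged[, aeT$test],
                   untagged = untagged[, aeU$test]))
}

# combine two CIFeatureSets by column, keeping raw/mask/labels
.combineFS <- function(a, b) {
  getCol <- function(x, col) {
    cd <- SummarizedExperiment::colData(x)
    if (col %in% colnames(cd)) as.character(cd[[col]])
    else rep(NA_character_, ncol(x))
  }
  norm <- S4Vectors::metadata(a)$normalization
  CIFeatureSet(cbind(rawIntensity(a), rawIntensity(b)),
               mask = cbind(matchedMask(a), matchedMask(b)),
               scanId = c(scanIds(a), scanIds(b)),
               label = c(getCol(a, "label"), getCol(b, "label")),
               sourceTag = c(getCol(a, "source_tag"),
                             getCol(b, "source_tag")),
               truth = c(getCol(a, "truth"), getCol(b, "truth")),
               normalization = norm)
}

#' Assemble the trustworthily labelled test set
#'
#' Test spectra cannot all be used for evaluation: only those with labels
#' unaffected by fucose migration/release count. The tagged test portion
#' (FUT8-knockout) is kept as \code{nCF}; the untagged test portion
#' contributes only spectra whose trustworthy label (core-fucosylated
#' mannose rule) is \code{CF}. Everything else is excluded.
#'
#' @param testSplit List with \code{tagged} and \code{untagged}
#'   \linkS4class{CIFeatureSet}s (as returned in
#'   \code{\link{splitDatasets}}).
#' @param labels data.frame from \code{\link{trustworthyLabel}} covering the
#'   untagged scan ids (unlisted ids count as \code{UNLABELED}).
#' @return A \linkS4class{CIFeatureSet} with a filled \code{label} column.
#' @export
buildTestPrime <- function(testSplit, labels) {
  tagged <- testSplit$tagged
  cfLabels(tagged) <- rep("nCF", ncol(tagged))
  untagged <- testSplit$untagged
  lab <- labels$label[match(scanIds(untagged), labels$scan_id)]
  lab[is.na(lab)] <- "UNLABELED"
  keep <- lab == "CF"
  if (!any(keep)) {
    warning("no trustworthy-CF spectra in the untagged test split; ",
            "evaluation will cover nCF only")
    return(tagged)
  }
  untagged <- untagged[, keep]
  cfLabels(untagged) <- rep("CF", ncol(untagged))
  .combineFS(tagged, untagged)
}

#' Classification metrics with CF as the positive class
#'
#' Per-class recalls, overall accuracy and F1 (CF positive). Predictions of
#' \code{"UNDETERMINED"} are excluded from the denominator and reported
#' separately.
#'
#' @param predictions Character vector of \code{"CF"} / \code{"nCF"} /
#'   \code{"UNDETERMINED"}.
#' @param truth Character vector of \code{"CF"} / \code{"nCF"}, same length.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{tn},
#'   \code{cf_acc}, \code{ncf_acc}, \code{overall_acc}, \code{f1},
#'   \code{n_undetermined}.
#' @examples
#' evaluateMetrics(c("CF", "nCF"), c("CF", "CF"))
#' @export
evaluateMetrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth),
            all(truth %in% c("CF", "nCF")))
  und <- predictions == "UNDETERMINED"
  predictions <- predictions[!und]; truth <- truth[!und]
  tp <- sum(predictions == "CF" & truth == "CF")
  fp <- sum(predictions == "CF" & truth == "nCF")
  fn <- sum(predictions == "nCF" & truth == "CF")
  tn <- sum(predictions == "nCF" & truth == "nCF")
  total <- tp + fp + fn + tn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       cf_acc = if (tp + fn) tp / (tp + fn) else NA_real_,
       ncf_acc = if (tn + fp) tn / (tn + fp) else NA_real_,
       overall_acc = if (total) (tp + tn) / total else NA_real_,
       f1 = if (2 * tp + fp + fn) 2 * tp / (2 * tp + fp + fn)
            else NA_real_,
       n_undetermined = sum(und))
}

#' Rebuild the normalised assay of a feature set
#'
#' @param fs A \linkS4class{CIFeatureSet}.
#' @param normalization \code{"sum"}, \code{"max"} or \code{"none"}.
#' @return A \linkS4class{CIFeatureSet} renormalised from its raw assay.
#' @export
renormalize <- function(fs, normalization = c("sum", "max", "none")) {
  normalization <- match.arg(normalization)
  cd <- SummarizedExperiment::colData(fs)
  CIFeatureSet(rawIntensity(fs), mask = matchedMask(fs),
               scanId = scanIds(fs),
               label = if ("label" %in% colnames(cd)) cd$label,
               sourceTag = if ("source_tag" %in% colnames(cd))
                 cd$source_tag,
               truth = if ("truth" %in% colnames(cd)) cd$truth,
               normalization = normalization)
}

#' Robustness of CFI to missing characteristic ions
#'
#' For each combination of minimum matched-CI count, normalisation and model
#' type, the training pool is filtered to spectra with at least that many
#' matched CIs, the model is retrained and evaluated on a fixed test set.
#'
#' @param tagged,untagged Training-pool \linkS4class{CIFeatureSet}s
#'   (tagged = nCF; untagged = mixture).
#' @param test Test \linkS4class{CIFeatureSet}.
#' @param testTruth Character vector of CF/nCF truth for \code{test}.
#' @param minCIValues Integer vector of minimum matched-CI counts.
#' @param norms Normalisations to compare.
#' @param models Model types, subset of \code{c("mc", "ae")}.
#' @param k Autoencoder threshold multiplier.
#' @param seed Seed threaded to every training run.
#' @param ... Further arguments passed to \code{\link{trainMC}} /
#'   \code{\link{trainAE}}.
#' @return data.frame with one row per (min_ci, norm, model) cell and the
#'   metric columns of \code{\link{evaluateMetrics}}.
#' @export
robustnessExperiment <- function(tagged, untagged, test, testTruth,
                                 minCIValues = c(3L, 4L, 5L, 6L),
                                 norms = c("max", "sum"),
                                 models = c("mc", "ae"), k = 0.4,
                                 seed = 42L, ...) {
  grid <- expand.grid(min_ci = minCIValues, norm = norms, model = models,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    minCI <- grid$min_ci[g]; nrm <- grid$norm[g]; mdl <- grid$model[g]
    tg <- renormalize(tagged[, minCIFilter(tagged, minCI)], nrm)
    ts <- renormalize(test, nrm)
    pred <- if (mdl == "mc") {
      ug <- renormalize(untagged[, minCIFilter(untagged, minCI)], nrm)
      predict(trainMC(tg, ug, seed = seed, ...), ts)
    } else {
      predict(trainAE(tg, k = k, seed = seed, ...), ts)
    }
    m <- evaluateMetrics(pred, testTruth)
    res[[g]] <- cbind(grid[g, , drop = FALSE],
                      as.data.frame(m[c("cf_acc", "ncf_acc", "overall_acc",
                                        "f1")]))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
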