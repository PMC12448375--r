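#' @include AllGenerics.R glycoCore.R
NULL

# ---------------------------------------------------------------------------
# MsSpectrum
# ---------------------------------------------------------------------------

#' A single MS/MS spectrum
#'
#' Minimal container for one centroided tandem mass spectrum: a peak list
#' (m/z, intensity) kept sorted by m/z, with precursor information. Precursor
#' m/z / charge may be NA; such spectra remain usable for characteristic-ion
#' matching when the peptide mass comes from the PSM table.
#'
#' @slot scanId character scalar, scan identifier preserved verbatim.
#' @slot precursorMz numeric scalar (may be NA).
#' @slot precursorCharge integer scalar (may be NA).
#' @slot mz numeric vector of peak m/z values, ascending.
#' @slot intensity numeric vector of peak intensities, >= 0.
#' @export
setClass("MsSpectrum",
  representation(scanId = "character", precursorMz = "numeric",
                 precursorCharge = "integer", mz = "numeric",
                 intensity = "numeric"),
  prototype(precursorMz = NA_real_, precursorCharge = NA_integer_))

setValidity("MsSpectrum", function(object) {
  msg <- character()
  if (length(object@scanId) != 1L || is.na(object@scanId))
    msg <- c(msg, "scanId must be a single non-NA string")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (is.unsorted(object@mz))
    msg <- c(msg, "peaks must be sorted ascending by m/z")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an MsSpectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param scanId Scan identifier.
#' @param mz,intensity Numeric peak vectors of equal length.
#' @param precursorMz,precursorCharge Optional precursor information.
#' @return An \linkS4class{MsSpectrum}.
#' @examples
#' MsSpectrum("s1", mz = c(300, 100), intensity = c(1, 2))
#' @export
MsSpectrum <- function(scanId, mz = numeric(), intensity = numeric(),
                       precursorMz = NA_real_,
                       precursorCharge = NA_integer_) {
  o <- order(mz)
  new("MsSpectrum", scanId = as.character(scanId),
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge))
}

#' @describeIn MsSpectrum number of peaks
#' @param x An MsSpectrum.
#' @export
setMethod("length", "MsSpectrum", function(x) length(x@mz))

#' @export
setMethod("scanIds", "MsSpectrum", function(x) x@scanId)

setMethod("show", "MsSpectrum", function(object) {
  cat("MsSpectrum", object@scanId, "with", length(object@mz), "peaks\n")
  if (!is.na(object@precursorMz))
    cat("  precursor m/z", format(object@precursorMz), "charge",
        object@precursorCharge, "\n")
})

#' Peak list of a spectrum
#' @param spectrum An \linkS4class{MsSpectrum}.
#' @return data.frame with columns \code{mz}, \code{intensity}.
#' @export
peaks <- function(spectrum) {
  data.frame(mz = spectrum@mz, intensity = spectrum@intensity)
}

#' Base-peak intensity of a spectrum
#' @param spectrum An \linkS4class{MsSpectrum}.
#' @return Largest peak intensity (0 for an empty spectrum).
#' @export
basePeakIntensity <- function(spectrum) {
  if (length(spectrum@intensity) == 0L) return(0)
  max(spectrum@intensity)
}

# ---------------------------------------------------------------------------
# CIFeatureSet
# ---------------------------------------------------------------------------

#' Characteristic-ion feature matrix
#'
#' A \linkS4class{SummarizedExperiment} with the ten characteristic ions as
#' rows and spectra as columns. Assays: \code{raw} (base-peak-relative
#' intensities in [0,1], zero where unmatched), \code{norm} (Max- or
#' Sum-normalised features) and \code{mask} (logical, CI matched). Column data
#' carry \code{scan_id}, and optionally \code{label}
#' (\code{"nCF"}/\code{"CF"}/\code{"UNLABELED"}), \code{source_tag} and
#' \code{truth}.
#'
#' @export
setClass("CIFeatureSet", contains = "SummarizedExperiment")

setValidity("CIFeatureSet", function(object) {
  msg <- character()
  if (nrow(object) != 10L)
    msg <- c(msg, "a CIFeatureSet has exactly 10 rows (CI1..CI10)")
  need <- c("raw", "mask")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'raw' and 'mask' are required")
  else {
    raw <- SummarizedExperiment::assay(object, "raw")
    mask <- SummarizedExperiment::assay(object, "mask")
    if (any(raw < 0 | raw > 1, na.rm = TRUE))
      msg <- c(msg, "raw relative intensities must lie in [0,1]")
    if (any(raw[!mask] != 0))
      msg <- c(msg, "raw intensity must be 0 wherever mask is FALSE")
  }
  if (!"scan_id" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain scan_id")
  if (length(msg)) msg else TRUE
})

#' Construct a CIFeatureSet
#'
#' @param raw 10 x n numeric matrix of base-peak-relative CI intensities
#'   (rows CI1..CI10 = Y1..Y5,Y1F..Y5F), zeros where unmatched.
#' @param mask 10 x n logical matrix of matched CIs; defaults to
#'   \code{raw > 0}.
#' @param scanId Character vector of n scan identifiers.
#' @param label Optional character vector (\code{"nCF"}, \code{"CF"},
#'   \code{"UNLABELED"}).
#' @param sourceTag Optional character vector (e.g. \code{"FUT8_KO"},
#'   \code{"WILD_TYPE"}).
#' @param truth Optional hidden ground-truth labels (synthetic benchmarks).
#' @param normalization Normalisation applied to the \code{norm} assay:
#'   \code{"sum"}, \code{"max"} or \code{"none"}.
#' @return A \linkS4class{CIFeatureSet}.
#' @examples
#' raw <- matrix(runif(20, 0.05, 0.6), nrow = 10)
#' fs <- CIFeatureSet(raw, scanId = c("a", "b"))
#' normIntensity(fs)
#' @export
CIFeatureSet <- function(raw, mask = NULL, scanId = NULL, label = NULL,
                         sourceTag = NULL, truth = NULL,
                         normalization = c("sum", "max", "none")) {
  normalization <- match.arg(normalization)
  raw <- as.matrix(raw)
  if (nrow(raw) != 10L) stop("'raw' must have 10 rows (CI1..CI10)")
  if (is.null(mask)) mask <- raw > 0
  if (is.null(scanId)) scanId <- as.character(seq_len(ncol(raw)))
  norm <- switch(normalization,
    sum  = apply(raw, 2L, sumNormalize),
    max  = apply(raw, 2L, maxNormalize),
    none = raw)
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = 10L)
  cd <- S4Vectors::DataFrame(scan_id = as.character(scanId))
  if (!is.null(label)) cd$label <- as.character(label)
  if (!is.null(sourceTag)) cd$source_tag <- as.character(sourceTag)
  if (!is.null(truth)) cd$truth <- as.character(truth)
  dimnames(raw) <- dimnames(norm) <- dimnames(mask) <-
    list(characteristicIons()$label, cd$scan_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw, norm = norm, mask = mask),
    rowData = S4Vectors::DataFrame(characteristicIons()),
    colData = cd,
    metadata = list(normalization = normalization))
  new("CIFeatureSet", se)
}

#' @describeIn CIFeatureSet raw base-peak-relative intensity matrix (10 x n)
#' @param x A CIFeatureSet.
#' @export
setMethod("rawIntensity", "CIFeatureSet", function(x)
  SummarizedExperiment::assay(x, "raw"))

#' @describeIn CIFeatureSet normalised feature matrix (10 x n)
#' @export
setMethod("normIntensity", "CIFeatureSet", function(x)
  SummarizedExperiment::assay(x, "norm"))

#' @describeIn CIFeatureSet logical matched-CI matrix (10 x n)
#' @export
setMethod("matchedMask", "CIFeatureSet", function(x)
  SummarizedExperiment::assay(x, "mask"))

#' @describeIn CIFeatureSet number of matched CIs per spectrum
#' @export
setMethod("nMatched", "CIFeatureSet", function(x)
  colSums(SummarizedExperiment::assay(x, "mask")))

#' @describeIn CIFeatureSet scan identifiers
#' @export
setMethod("scanIds", "CIFeatureSet", function(x)
  SummarizedExperiment::colData(x)$scan_id)

#' @describeIn CIFeatureSet trust labels (NA-filled if absent)
#' @export
setMethod("cfLabels", "CIFeatureSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) cd$label else rep(NA_character_, ncol(x))
})

#' @describeIn CIFeatureSet replace trust labels
#' @param value Character vector of labels.
#' @export
setMethod("cfLabels<-", "CIFeatureSet", function(x, value) {
  SummarizedExperiment::colData(x)$label <- as.character(value)
  validObject(x)
  x
})

setMethod("show", "CIFeatureSet", function(object) {
  callNextMethod()
  cat("normalization:", S4Vectors::metadata(object)$normalization, "\n")
  labs <- cfLabels(object)
  if (!all(is.na(labs)))
    print(table(label = labs, useNA = "ifany"))
})

# ---------------------------------------------------------------------------
# Model classes
# ---------------------------------------------------------------------------

#' Mapping-convergence classifier state
#'
#' Result of \code{\link{trainMC}}: the final decision function \code{h}
#' (a binary SVM, or the initial one-class SVM when no negatives were found),
#' and the set \code{N} of untagged spectra identified as CF.
#'
#' @slot h Fitted classifier used for prediction.
#' @slot hType \code{"binary"} or \code{"one-class"}.
#' @slot identifiedCF Integer indices into the untagged set that ended in N.
#' @slot iterations Number of convergence iterations run.
#' @slot converged Logical; FALSE if the iteration cap was hit.
#' @slot history Integer vector, |N_i| added per iteration.
#' @slot config List of hyperparameters used.
#' @export
setClass("MCModel",
  representation(h = "ANY", hType = "character", identifiedCF = "integer",
                 iterations = "integer", converged = "logical",
                 history = "integer", config = "list"))

setMethod("show", "MCModel", function(object) {
  cat("MCModel (mapping-convergence,", object@hType, "final classifier)\n")
  cat("  identified CF in U:", length(object@identifiedCF),
      "| iterations:", object@iterations,
      "| converged:", object@converged, "\n")
})

#' Autoencoder anomaly-detection model
#'
#' A 10-9-8-7-8-9-10 fully connected tanh autoencoder trained on nCF feature
#' vectors; spectra whose reconstruction error exceeds
#' \code{alpha = mu + k * sigma} are called CF.
#'
#' @slot layerSizes Integer vector, fixed to 10,9,8,7,8,9,10.
#' @slot weights,biases Lists of per-layer parameter matrices/vectors.
#' @slot k Threshold multiplier.
#' @slot mu,sigma Mean and SD of training reconstruction errors.
#' @slot alpha Decision threshold, exactly \code{mu + k * sigma}.
#' @slot config Training hyperparameters.
#' @slot lossHistory Per-epoch mean training loss.
#' @export
setClass("AEModel",
  representation(layerSizes = "integer", weights = "list", biases = "list",
                 k = "numeric", mu = "numeric", sigma = "numeric",
                 alpha = "numeric", config = "list",
                 lossHistory = "numeric"))

setValidity("AEModel", function(object) {
  msg <- character()
  if (!identical(object@layerSizes, c(10L, 9L, 8L, 7L, 8L, 9L, 10L)))
    msg <- c(msg, "layerSizes must be 10,9,8,7,8,9,10")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (abs(object@alpha - (object@mu + object@k * object@sigma)) > 1e-12)
    msg <- c(msg, "alpha must equal mu + k*sigma")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AEModel", function(object) {
  cat("AEModel (tanh autoencoder ",
      paste(object@layerSizes, collapse = "-"), ")\n", sep = "")
  cat(sprintf("  mu = %.5f, sigma = %.5f, k = %.2f -> alpha = %.5f\n",
              object@mu, object@sigma, object@k, object@alpha))
  cat("  trained", length(object@lossHistory), "epochs, final loss",
      format(utils::tail(object@lossHistory, 1L), digits = 5), "\n")
})
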