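#' @include AllClasses.R spectraIO.R
NULL

#' Match characteristic-ion peaks at ppm tolerance
#'
#' For each of the ten CIs and each considered charge state, a peak matches
#' when |observed - theoretical| / theoretical * 1e6 <= \code{tolPpm}; within
#' a window the highest-intensity peak wins (robust to centroiding jitter).
#' A CI's raw intensity is the sum of its per-charge matched intensities, and
#' its mask entry is TRUE if any charge matched.
#'
#' @param spectrum An \linkS4class{MsSpectrum}.
#' @param peptideMass Neutral peptide monoisotopic mass in Da (> 0).
#' @param tolPpm Mass tolerance in ppm (default 20).
#' @param charges Integer charge states to consider (default 1:2).
#' @param masses Constants table, see \code{\link{monosaccharideMasses}}.
#' @return List with \code{raw} (10 summed matched intensities, 0 where
#'   unmatched) and \code{mask} (10 logicals).
#' @export
matchCIPeaks <- function(spectrum, peptideMass, tolPpm = 20,
                         charges = c(1L, 2L),
                         masses = monosaccharideMasses()) {
  stopifnot(peptideMass > 0, tolPpm > 0)
  raw <- numeric(10L); mask <- logical(10L)
  if (length(spectrum) == 0L)
    return(list(raw = raw, mask = mask))
  theo <- ciMzTable(peptideMass, charges, masses)
  mz <- spectrum@mz; int <- spectrum@intensity
  for (r in seq_len(nrow(theo))) {
    tol <- theo$mz[r] * tolPpm * 1e-6
    lo <- findInterval(theo$mz[r] - tol, mz) + 1L
    hi <- findInterval(theo$mz[r] + tol, mz)
    if (hi >= lo) {
      i <- theo$index[r]
      raw[i] <- raw[i] + max(int[lo:hi])
      mask[i] <- TRUE
    }
  }
  list(raw = raw, mask = mask)
}

#' Base-peak-relative intensities
#'
#' Divides matched CI intensities by the reference intensity of the spectrum
#' (base peak by default, total ion current optionally) and clips to [0,1].
#'
#' @param raw Numeric vector of 10 matched intensities.
#' @param spectrum The \linkS4class{MsSpectrum} the intensities came from.
#' @param reference \code{"basepeak"} or \code{"tic"}.
#' @return Numeric vector of 10 relative intensities in [0,1].
#' @export
relativeIntensities <- function(raw, spectrum,
                                reference = c("basepeak", "tic")) {
  reference <- match.arg(reference)
  denom <- switch(reference,
    basepeak = basePeakIntensity(spectrum),
    tic = sum(spectrum@intensity))
  if (!length(spectrum) || denom <= 0)
    stop("spectrum has no positive-intensity peaks")
  pmin(pmax(raw / denom, 0), 1)
}

#' Minimum matched-CI filter
#'
#' Spectra with fewer matched characteristic ions than \code{minMatched}
#' (default 3 of 10) are excluded from model construction.
#'
#' @param fs A \linkS4class{CIFeatureSet} (or a logical mask vector/matrix).
#' @param minMatched Minimum number of matched CIs to keep a spectrum.
#' @return Logical vector, TRUE for spectra passing the filter.
#' @export
minCIFilter <- function(fs, minMatched = 3L) {
  n <- if (is(fs, "CIFeatureSet")) nMatched(fs)
       else if (is.matrix(fs)) colSums(fs)
       else sum(fs)
  n >= minMatched
}

#' Max normalisation
#'
#' \code{X_i = x_i / max_j x_j}; the largest component becomes 1.
#'
#' @param x Numeric vector with \code{max(x) > 0}.
#' @return Normalised vector of the same length.
#' @export
maxNormalize <- function(x) {
  m <- max(x)
  if (m <= 0) stop("max normalisation needs at least one positive entry")
  x / m
}

#' Sum normalisation
#'
#' \code{X_i = x_i / sum_j x_j}; components sum to 1.
#'
#' @param x Numeric vector with \code{sum(x) > 0}.
#' @return Normalised vector of the same length.
#' @export
sumNormalize <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("sum normalisation needs a positive total")
  x / s
}

#' Extract CI features for a set of identified spectra
#'
#' Joins spectra to PSM rows by exact \code{scan_id} match, matches the ten
#' characteristic ions at ppm tolerance, converts to base-peak-relative
#' intensities, applies the minimum-CI filter and normalises. Missing CIs are
#' zero-filled before normalisation.
#'
#' @param spectra Named list of \linkS4class{MsSpectrum} (from
#'   \code{\link{readSpectra}}) or a single \code{MsSpectrum}.
#' @param psms PSM data.frame from \code{\link{readPSMTable}} (needs
#'   \code{scan_id} and \code{peptide_mass}).
#' @param tolPpm,charges Matching parameters, see
#'   \code{\link{matchCIPeaks}}.
#' @param normalization \code{"sum"} (default), \code{"max"} or
#'   \code{"none"}.
#' @param minCI Minimum matched CIs; spectra below are dropped (default 3).
#' @param reference Relative-intensity reference, see
#'   \code{\link{relativeIntensities}}.
#' @return A \linkS4class{CIFeatureSet} for the retained spectra; carries
#'   \code{source_tag} (and label columns when present in \code{psms}).
#' @export
extractFeatures <- function(spectra, psms, tolPpm = 20, charges = c(1L, 2L),
                            normalization = c("sum", "max", "none"),
                            minCI = 3L,
                            reference = c("basepeak", "tic")) {
  normalization <- match.arg(normalization)
  reference <- match.arg(reference)
  if (is(spectra, "MsSpectrum")) spectra <- list(spectra)
  nm <- vapply(spectra, scanIds, character(1L))
  hit <- match(psms$scan_id, nm)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " PSM(s) without a matching spectrum; skipped")
    psms <- psms[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  if (!nrow(psms)) stop("no PSM joins a spectrum")
  raw <- matrix(0, nrow = 10L, ncol = nrow(psms))
  mask <- matrix(FALSE, nrow = 10L, ncol = nrow(psms))
  for (j in seq_len(nrow(psms))) {
    sp <- spectra[[hit[j]]]
    m <- matchCIPeaks(sp, psms$peptide_mass[j], tolPpm, charges)
    raw[, j] <- relativeIntensities(m$raw, sp, reference)
    mask[, j] <- m$mask
  }
  keep <- colSums(mask) >= minCI
  if (!any(keep)) stop("no spectrum passes the minimum-CI filter")
  CIFeatureSet(raw[, keep, drop = FALSE], mask = mask[, keep, drop = FALSE],
               scanId = psms$scan_id[keep],
               label = psms[["label"]][keep],
               sourceTag = psms[["source_tag"]][keep],
               truth = psms[["truth"]][keep],
               normalization = normalization)
}
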