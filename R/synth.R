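#' @include AllClasses.R features.R fmStats.R
NULL

#' Cohort specifications for the synthetic generator
#'
#' A cohort spec is a mixture of components; each component carries per-CI
#' log10-intensity Gaussian parameters (\code{mu}, \code{sigma}), per-CI
#' dropout (missing-peak) probabilities, a mixture \code{weight} and a
#' \code{name} used as ground truth. \code{caseCohortSpec} emulates the
#' FUT8-knockout cohort (pure nCF: YiF signal only via fucose migration,
#' hence high F-series dropout); \code{cfComponentSpec} is the synthetic
#' pure-CF component (genuine core fucose: strong, rarely missing YiF ions)
#' — published control statistics only constrain the CF+nCF mixture, so its
#' F-series means are the control values shifted up by \code{shift} decades;
#' \code{controlCohortSpec} mixes the two with weight \code{cfWeight} on CF.
#'
#' @param dropoutY,dropoutF Per-CI dropout probability for the Y and YiF
#'   series.
#' @param shift Upward shift (log10 decades) of the CF component's F-series
#'   means relative to the published control means.
#' @param cfWeight Mixture weight of the CF component in the control cohort.
#' @return A list of component lists (a cohort spec).
#' @name cohortSpecs
NULL

#' @rdname cohortSpecs
#' @export
caseCohortSpec <- function(dropoutY = 0.1, dropoutF = 0.6) {
  p <- referenceCohortParams()
  list(list(name = "nCF", weight = 1,
            mu = p$case_mu, sigma = p$case_sigma,
            dropout = rep(c(dropoutY, dropoutF), each = 5L)))
}

#' @rdname cohortSpecs
#' @export
cfComponentSpec <- function(shift = 0.8, dropoutY = 0.1, dropoutF = 0.1) {
  p <- referenceCohortParams()
  mu <- p$control_mu
  mu[6:10] <- mu[6:10] + shift
  list(list(name = "CF", weight = 1,
            mu = mu, sigma = p$control_sigma,
            dropout = rep(c(dropoutY, dropoutF), each = 5L)))
}

#' @rdname cohortSpecs
#' @export
controlCohortSpec <- function(cfWeight = 0.3, shift = 0.8,
                              dropoutY = 0.1, dropoutF = 0.6) {
  ncf <- caseCohortSpec(dropoutY, dropoutF)[[1L]]
  cf <- cfComponentSpec(shift, dropoutY)[[1L]]
  ncf$weight <- 1 - cfWeight
  cf$weight <- cfWeight
  list(ncf, cf)
}

.checkSpec <- function(spec) {
  w <- vapply(spec, `[[`, numeric(1L), "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  for (cmp in spec) {
    stopifnot(length(cmp$mu) == 10L, length(cmp$sigma) == 10L,
              length(cmp$dropout) == 10L)
    if (any(cmp$sigma < 0)) stop("sigma must be >= 0")
    if (any(cmp$dropout < 0 | cmp$dropout > 1))
      stop("dropout must be in [0,1]")
  }
  w
}

#' Sample a synthetic feature cohort
#'
#' Draws \code{n} feature vectors from a cohort spec: a mixture component is
#' picked by weight, each CI intensity is sampled as
#' \code{10^N(mu_i, sigma_i)} and clipped to (0,1], then per-CI dropout
#' zeroes the intensity and clears the matched mask. The component name is
#' attached as ground truth. Deterministic under a fixed seed.
#'
#' @param spec Cohort spec, see \link{cohortSpecs}.
#' @param n Number of vectors (> 0).
#' @param seed Random seed.
#' @param normalization Normalisation for the \code{norm} assay.
#' @param scanPrefix Prefix for generated scan ids.
#' @return A \linkS4class{CIFeatureSet} with a \code{truth} column.
#' @export
sampleFeatureCohort <- function(spec, n, seed = 42L,
                                normalization = c("sum", "max", "none"),
                                scanPrefix = "synth") {
  normalization <- match.arg(normalization)
  if (n <= 0) stop("'n' must be positive")
  w <- .checkSpec(spec)
  set.seed(seed)
  comp <- sample.int(length(spec), n, replace = TRUE, prob = w)
  raw <- matrix(0, nrow = 10L, ncol = n)
  mask <- matrix(FALSE, nrow = 10L, ncol = n)
  for (ci in seq_along(spec)) {
    cols <- which(comp == ci)
    if (!length(cols)) next
    cmp <- spec[[ci]]
    for (i in 1:10) {
      v <- 10^stats::rnorm(length(cols), cmp$mu[i], cmp$sigma[i])
      keep <- stats::runif(length(cols)) >= cmp$dropout[i]
      raw[i, cols] <- ifelse(keep, pmin(v, 1), 0)
      mask[i, cols] <- keep
    }
  }
  # a fully dropped-out vector cannot be normalised; keep its Y1 ion
  dead <- colSums(mask) == 0L
  if (any(dead)) {
    for (j in which(dead)) {
      cmp <- spec[[comp[j]]]
      raw[1L, j] <- min(10^stats::rnorm(1L, cmp$mu[1L], cmp$sigma[1L]), 1)
      mask[1L, j] <- TRUE
    }
  }
  CIFeatureSet(raw, mask = mask,
               scanId = sprintf("%s_%06d", scanPrefix, seq_len(n)),
               truth = vapply(spec, `[[`, character(1L), "name")[comp],
               normalization = normalization)
}

#' Synthesize a spectrum carrying prescribed CI intensities
#'
#' Builds a toy centroided spectrum whose extraction recovers a given
#' feature vector: a base peak of intensity 1 at a non-CI m/z, one peak per
#' nonzero CI at its theoretical m/z (charge \code{charges[1]}) perturbed by
#' exactly \code{jitterPpm} with random sign (worst-case placement inside
#' the jitter budget), and \code{noisePeaks} random peaks kept outside every
#' CI matching window.
#'
#'
#' @param scanId Scan identifier for the spectrum.
#' @param peptideMass Neutral peptide mass (Da).
#' @param x Numeric vector of 10 relative intensities in [0,1].
#' @param charges Charge states the downstream matcher will consider; peaks
#'   are placed at the first.
#' @param noisePeaks Number of random non-CI peaks.
#' @param jitterPpm Maximum |mass error| applied to CI peaks (ppm).
#' @param guardPpm Half-width of the exclusion window around CI m/z values
#'   kept free of noise (ppm; default 30).
#' @param seed Random seed.
#' @return An \linkS4class{MsSpectrum}.
#' @export
synthesizeSpectrum <- function(scanId, peptideMass, x, charges = c(1L, 2L),
                               noisePeaks = 20L, jitterPpm = 0,
                               guardPpm = 30, seed = 42L) {
  stopifnot(length(x) == 10L, all(x >= 0), all(x <= 1))
  set.seed(seed)
  theo <- ciMzTable(peptideMass, charges)
  place <- ciMzTable(peptideMass, charges[1L])
  mz <- numeric(); int <- numeric()
  for (i in which(x > 0)) {
    # worst-case placement: exactly jitterPpm off, random sign
    jit <- if (jitterPpm > 0)
      sample(c(-1, 1), 1L) * jitterPpm else 0
    mz <- c(mz, place$mz[i] * (1 + jit * 1e-6))
    int <- c(int, x[i])
  }
  inWindow <- function(m)
    any(abs(m - theo$mz) / theo$mz * 1e6 <= guardPpm)
  bp <- 200.0
  while (inWindow(bp)) bp <- bp + 1
  mz <- c(mz, bp); int <- c(int, 1.0)
  lo <- 150; hi <- max(theo$mz) + 200
  k <- 0L
  while (k < noisePeaks) {
    m <- stats::runif(1L, lo, hi)
    if (!inWindow(m)) {
      mz <- c(mz, m); int <- c(int, stats::runif(1L, 0.001, 0.8))
      k <- k + 1L
    }
  }
  MsSpectrum(scanId, mz, int)
}

#' Build a tagged/untagged synthetic benchmark
#'
#' Emulates the study design: a tagged cohort of FUT8-knockout-like spectra
#' (all truly nCF) and an untagged control cohort mixing nCF with a
#' synthetic pure-CF component whose hidden ground truth is recorded.
#'
#' @param nCase,nControl Cohort sizes.
#' @param cfWeight CF mixture weight in the control cohort (default 0.3).
#' @param shift F-series mean shift of the CF component (decades).
#' @param seed Random seed; the two cohorts use derived sub-seeds.
#' @param normalization Feature normalisation.
#' @return List with \code{tagged} (CIFeatureSet, label \code{"nCF"},
#'   source \code{FUT8_KO}), \code{untagged} (CIFeatureSet, label
#'   \code{"UNLABELED"}, source \code{WILD_TYPE}, hidden \code{truth}
#'   column) and \code{truth} (character vector for the untagged set).
#' @export
makeBenchmark <- function(nCase, nControl, cfWeight = 0.3, shift = 0.8,
                          seed = 42L,
                          normalization = c("sum", "max", "none")) {
  normalization <- match.arg(normalization)
  tagged <- sampleFeatureCohort(caseCohortSpec(), nCase,
                                seed = seed, normalization = normalization,
                                scanPrefix = "case")
  untagged <- sampleFeatureCohort(controlCohortSpec(cfWeight, shift),
                                  nControl, seed = seed + 1L,
                                  normalization = normalization,
                                  scanPrefix = "ctrl")
  SummarizedExperiment::colData(tagged)$label <- "nCF"
  SummarizedExperiment::colData(tagged)$source_tag <- "FUT8_KO"
  SummarizedExperiment::colData(untagged)$label <- "UNLABELED"
  SummarizedExperiment::colData(untagged)$source_tag <- "WILD_TYPE"
  list(tagged = tagged, untagged = untagged,
       truth = SummarizedExperiment::colData(untagged)$truth)
}

#' Write a simulated dataset to disk
#'
#' Materialises a benchmark as files exercising the full input path: an MGF
#' peak-list file (one synthetic spectrum per feature vector), a PSM TSV
#' (shared peptide backbone; composition and structure annotation reflect
#' the hidden truth) and a truth TSV.
#'
#' @param dir Output directory (created if needed).
#' @param nCase,nControl,cfWeight,seed See \code{\link{makeBenchmark}}.
#' @param peptide Peptide backbone for all synthetic PSMs.
#' @param noisePeaks,jitterPpm Spectrum synthesis controls.
#' @return Invisibly, the paths written (\code{mgf}, \code{psm},
#'   \code{truth}).
#' @export
simulateDataset <- function(dir, nCase = 200L, nControl = 200L,
                            cfWeight = 0.3, seed = 42L,
                            peptide = "SAMPLEK", noisePeaks = 10L,
                            jitterPpm = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bench <- makeBenchmark(nCase, nControl, cfWeight, seed = seed,
                         normalization = "none")
  pepMass <- peptideMonoisotopicMass(peptide)
  sets <- list(case = bench$tagged, ctrl = bench$untagged)
  mgf <- file.path(dir, "spectra.mgf")
  con <- file(mgf, "w")
  rows <- list()
  k <- 0L
  for (nm in names(sets)) {
    fs <- sets[[nm]]
    raw <- rawIntensity(fs)
    cd <- SummarizedExperiment::colData(fs)
    for (j in seq_len(ncol(fs))) {
      k <- k + 1L
      sp <- synthesizeSpectrum(cd$scan_id[j], pepMass, raw[, j],
                               noisePeaks = noisePeaks,
                               jitterPpm = jitterPpm, seed = seed + k)
      writeLines(c("BEGIN IONS",
                   paste0("TITLE=", sp@scanId),
                   paste0("SCANS=", sp@scanId),
                   "PEPMASS=0",
                   "CHARGE=2+",
                   sprintf("%.6f %.6g", sp@mz, sp@intensity),
                   "END IONS"), con)
      isCF <- !is.null(cd$truth) && cd$truth[j] == "CF"
      rows[[k]] <- data.frame(
        scan_id = cd$scan_id[j], peptide = peptide,
        peptide_mass = "",
        glycan_composition = if (isCF) "HexNAc2Hex5Fuc1" else "HexNAc2Hex5",
        structure_annotation = if (isCF) "core-fucose" else "",
        source_tag = cd$source_tag[j],
        stringsAsFactors = FALSE)
    }
  }
  close(con)
  psm <- file.path(dir, "psms.tsv")
  utils::write.table(do.call(rbind, rows), psm, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(scan_id = scanIds(bench$untagged), truth = bench$truth),
    truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(mgf = mgf, psm = psm, truth = truthPath))
}
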