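#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Spectrum readers
# ---------------------------------------------------------------------------

#' Read MS/MS spectra from MGF or mzML
#'
#' Reads a peak-list file into a list of \linkS4class{MsSpectrum} objects.
#' MGF is parsed directly; mzML goes through Bioconductor \pkg{mzR}. Peak
#' lists are sorted by m/z on load and scan identifiers preserved verbatim.
#' Spectra without precursor information are kept (with a warning): they stay
#' usable for characteristic-ion matching when the peptide mass comes from
#' the PSM table.
#'
#' @param path Path to an \code{.mgf} or \code{.mzML} file.
#' @param format \code{"auto"} (by extension), \code{"mgf"} or \code{"mzml"}.
#' @return Named list of \linkS4class{MsSpectrum}, names = scan ids.
#' @export
readSpectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  spectra <- switch(format, mgf = .readMGF(path), mzml = .readMzML(path))
  if (any(vapply(spectra, function(s) is.na(s@precursorMz), logical(1L))))
    warning("some spectra lack precursor information")
  stats::setNames(spectra, vapply(spectra, scanIds, character(1L)))
}

.readMGF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^BEGIN IONS\\s*$", lines)
  end <- grep("^END IONS\\s*$", lines)
  if (length(begin) != length(end) || any(end < begin))
    stop("malformed MGF file '", path, "': unbalanced BEGIN/END IONS (",
         length(begin), " BEGIN vs ", length(end), " END)")
  lapply(seq_along(begin), function(i) {
    block <- lines[(begin[i] + 1L):(end[i] - 1L)]
    isKV <- grepl("^[A-Z][A-Z0-9]*=", block)
    kv <- block[isKV]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]+=", "", kv)
    scan <- if ("SCANS" %in% keys) vals[match("SCANS", keys)]
            else if ("TITLE" %in% keys) vals[match("TITLE", keys)]
            else paste0("index=", i)
    pmz <- NA_real_; pz <- NA_integer_
    if ("PEPMASS" %in% keys)
      pmz <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                 "\\s+")[[1L]][1L])
    if ("CHARGE" %in% keys)
      pz <- as.integer(sub("\\+\\s*$", "", vals[match("CHARGE", keys)]))
    pk <- block[!isKV & nzchar(trimws(block))]
    if (length(pk)) {
      fields <- strsplit(trimws(pk), "\\s+")
      mz <- as.numeric(vapply(fields, `[`, character(1L), 1L))
      int <- as.numeric(vapply(fields, `[`, character(1L), 2L))
      if (anyNA(mz) || anyNA(int))
        stop("malformed MGF peak line in block ", i, " of '", path, "'")
    } else mz <- int <- numeric()
    MsSpectrum(scan, mz, int, precursorMz = pmz, precursorCharge = pz)
  })
}

.readMzML <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) return(list())
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hdr)), function(i) {
    id <- if ("spectrumId" %in% names(hdr)) hdr$spectrumId[i]
          else as.character(hdr$acquisitionNum[i])
    MsSpectrum(id, pk[[i]][, 1L], pk[[i]][, 2L],
               precursorMz = if (hdr$precursorMZ[i] > 0) hdr$precursorMZ[i]
                             else NA_real_,
               precursorCharge = if (hdr$precursorCharge[i] > 0)
                 as.integer(hdr$precursorCharge[i]) else NA_integer_)
  })
}

# ---------------------------------------------------------------------------
# PSM tables
# ---------------------------------------------------------------------------

#' Parse a glycan composition string
#'
#' Grammar: concatenated \code{Name count} pairs, count omitted = 1, e.g.
#' \code{"HexNAc2Hex5Fuc1"}. Accepted names: HexNAc, Hex, Fuc, NeuAc, NeuGc.
#'
#' @param x Character vector of composition strings.
#' @return Integer matrix with one row per input and columns HexNAc, Hex,
#'   Fuc, NeuAc, NeuGc (absent names count 0).
#' @examples
#' parseGlycanComposition("HexNAc2Hex5Fuc1")
#' @export
parseGlycanComposition <- function(x) {
  names <- c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc")
  out <- matrix(0L, nrow = length(x), ncol = length(names),
                dimnames = list(NULL, names))
  # longest names first so "HexNAc" is not eaten by "Hex"
  pat <- "(HexNAc|NeuAc|NeuGc|Hex|Fuc)(\\d*)"
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || !nzchar(s)) next
    m <- gregexpr(pat, s, perl = TRUE)
    if (m[[1L]][1L] == -1L ||
        sum(attr(m[[1L]], "match.length")) != nchar(s))
      stop("cannot parse glycan composition: '", s, "'")
    toks <- regmatches(s, m)[[1L]]
    nm <- sub("\\d*$", "", toks)
    ct <- sub("^[A-Za-z]+", "", toks)
    ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
    for (j in seq_along(nm)) out[i, nm[j]] <- out[i, nm[j]] + ct[j]
  }
  out
}

#' Read a glycopeptide-spectrum-match table
#'
#' Tab-separated with header columns \code{scan_id}, \code{peptide},
#' \code{peptide_mass}, \code{glycan_composition}, \code{structure_annotation},
#' \code{source_tag} (extra columns such as \code{id_fdr} or collision energy
#' pass through). Rows lacking both a peptide sequence and an explicit mass
#' are skipped with a warning. An explicit \code{peptide_mass} takes
#' precedence over the sequence-derived mass.
#'
#' @param path Path to the TSV file.
#' @param fixedMods Fixed modifications for sequence-derived masses, see
#'   \code{\link{peptideMonoisotopicMass}}.
#' @return data.frame with one row per kept PSM: the input columns plus
#'   parsed composition counts (\code{HexNAc}, \code{Hex}, \code{Fuc},
#'   \code{NeuAc}, \code{NeuGc}) and a resolved \code{peptide_mass}.
#' @export
readPSMTable <- function(path, fixedMods = c(C = 57.021464)) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  need <- c("scan_id", "glycan_composition", "source_tag")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("PSM table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!"peptide" %in% names(df)) df$peptide <- NA_character_
  if (!"peptide_mass" %in% names(df)) df$peptide_mass <- NA_character_
  if (!"structure_annotation" %in% names(df))
    df$structure_annotation <- NA_character_
  df$peptide[!nzchar(trimws(df$peptide))] <- NA_character_
  df$peptide_mass <- suppressWarnings(as.numeric(df$peptide_mass))
  bad <- is.na(df$peptide) & is.na(df$peptide_mass)
  if (any(bad)) {
    warning(sum(bad), " PSM row(s) lack both peptide and peptide_mass; ",
            "skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df$scan_id))
    warning("duplicate scan_id values in PSM table; all rows kept")
  derive <- is.na(df$peptide_mass)
  if (any(derive))
    df$peptide_mass[derive] <- vapply(df$peptide[derive],
      peptideMonoisotopicMass, numeric(1L), fixedMods = fixedMods)
  comp <- parseGlycanComposition(df$glycan_composition)
  df <- cbind(df, as.data.frame(comp))
  rownames(df) <- NULL
  df
}

# ---------------------------------------------------------------------------
# Feature tables and predictions
# ---------------------------------------------------------------------------

#' Write a CIFeatureSet to TSV
#'
#' One row per spectrum: \code{scan_id}, ten raw relative intensities
#' (\code{raw_Y1}..\code{raw_Y5F}), ten normalised values
#' (\code{norm_Y1}..), the matched mask as a 10-character 0/1 string, and
#' label / source / truth columns when present. A \code{# normalization=}
#' comment line preserves the normalisation mode so that
#' \code{\link{readFeatureTable}} round-trips losslessly.
#'
#' @param fs A \linkS4class{CIFeatureSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(fs, path) {
  ci <- characteristicIons()$label
  raw <- t(rawIntensity(fs)); norm <- t(normIntensity(fs))
  colnames(raw) <- paste0("raw_", ci); colnames(norm) <- paste0("norm_", ci)
  mask <- apply(matchedMask(fs), 2L, function(m)
    paste(as.integer(m), collapse = ""))
  df <- data.frame(scan_id = scanIds(fs), raw, norm,
                   matched_mask = mask, stringsAsFactors = FALSE,
                   check.names = FALSE)
  cd <- SummarizedExperiment::colData(fs)
  for (col in intersect(c("label", "source_tag", "truth"), colnames(cd)))
    df[[col]] <- cd[[col]]
  stopifnot(!anyNA(raw), !anyNA(norm))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# normalization=",
                    S4Vectors::metadata(fs)$normalization), con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by writeFeatureTable
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{CIFeatureSet}.
#' @export
readFeatureTable <- function(path) {
  first <- readLines(path, n = 1L)
  normMode <- if (grepl("^# normalization=", first))
    sub("^# normalization=", "", first) else "none"
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(matched_mask = "character"))
  ci <- characteristicIons()$label
  raw <- t(as.matrix(df[, paste0("raw_", ci)]))
  mask <- do.call(cbind, lapply(strsplit(df$matched_mask, ""),
                                function(b) as.logical(as.integer(b))))
  if (is.null(dim(mask))) mask <- matrix(logical(), nrow = 10L)
  CIFeatureSet(raw, mask = mask, scanId = df$scan_id,
               label = df[["label"]], sourceTag = df[["source_tag"]],
               truth = df[["truth"]], normalization = normMode)
}

#' Write predictions to TSV
#'
#' @param scanId Character vector of scan ids.
#' @param prediction Character vector of calls (\code{"CF"}, \code{"nCF"},
#'   \code{"UNDETERMINED"}).
#' @param path Output path.
#' @param score Optional numeric score column (decision value or
#'   reconstruction error).
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(scanId, prediction, path, score = NULL) {
  df <- data.frame(scan_id = scanId, prediction = prediction,
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- score
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
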