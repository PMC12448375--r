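#' @include AllClasses.R
NULL

#' Trustworthy CF/nCF labels from PSM annotations
#'
#' Two rules yield labels unaffected by fucose migration (FM) and fucose
#' release (FR): (i) spectra from FUT8-knockout material cannot carry core
#' fucose and are labelled \code{nCF}; (ii) core-fucosylated (pauci/high-)
#' mannose glycans — composition HexNAc2 Hex>=3 Fuc1 with no sialic acid and
#' an upstream structure call flagging core fucose — cannot arise by FM
#' (there is no antennary fucose to migrate) and are labelled \code{CF}.
#' Everything else is \code{UNLABELED}.
#'
#' @param psms PSM data.frame from \code{\link{readPSMTable}} (needs
#'   \code{source_tag} and parsed composition counts).
#' @param coreFucPattern Regular expression matched (case-insensitively)
#'   against \code{structure_annotation} to detect an upstream core-fucose
#'   structure call.
#' @param fdrCutoff Optional cutoff applied to a pass-through \code{id_fdr}
#'   column before the CF rule fires (upstream identifications are assumed
#'   already FDR-filtered; this is a belt-and-braces option).
#' @return data.frame with columns \code{scan_id}, \code{label}
#'   (\code{nCF}/\code{CF}/\code{UNLABELED}) and \code{provenance}
#'   (\code{FUT8_KO_rule}/\code{core_fuc_mannose_rule}/\code{none}).
#' @export
trustworthyLabel <- function(psms, coreFucPattern = "core[-_ ]?fuc",
                             fdrCutoff = NULL) {
  need <- c("scan_id", "source_tag", "HexNAc", "Hex", "Fuc", "NeuAc",
            "NeuGc")
  stopifnot(all(need %in% names(psms)))
  label <- rep("UNLABELED", nrow(psms))
  provenance <- rep("none", nrow(psms))
  ko <- psms$source_tag == "FUT8_KO"
  label[ko] <- "nCF"
  provenance[ko] <- "FUT8_KO_rule"
  ann <- psms$structure_annotation
  hasCoreFlag <- !is.na(ann) &
    grepl(coreFucPattern, ann, ignore.case = TRUE)
  cf <- !ko & hasCoreFlag &
    psms$HexNAc == 2L & psms$Hex >= 3L & psms$Fuc == 1L &
    psms$NeuAc == 0L & psms$NeuGc == 0L
  if (!is.null(fdrCutoff) && "id_fdr" %in% names(psms))
    cf <- cf & suppressWarnings(as.numeric(psms$id_fdr)) < fdrCutoff
  label[cf] <- "CF"
  provenance[cf] <- "core_fuc_mannose_rule"
  data.frame(scan_id = psms$scan_id, label = label,
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Y1F/Y1 ratio baseline classifier
#'
#' The single-feature thresholding baseline: call CF when the
#' Y1F/Y1 intensity ratio exceeds \code{threshold} (default 0.1). The ratio
#' of two components is invariant to Max/Sum normalisation, so raw relative
#' intensities are used. Spectra with no matched Y1 are
#' \code{UNDETERMINED}.
#'
#' @param fs A \linkS4class{CIFeatureSet}, or a numeric vector of 10 raw
#'   intensities.
#' @param threshold Decision threshold on the ratio (default 0.1).
#' @return Character vector of \code{"CF"} / \code{"nCF"} /
#'   \code{"UNDETERMINED"} per spectrum.
#' @export
y1fY1Baseline <- function(fs, threshold = 0.1) {
  x <- if (is(fs, "CIFeatureSet")) rawIntensity(fs)
       else matrix(fs, nrow = 10L)
  y1 <- x[1L, ]; y1f <- x[6L, ]
  out <- rep("UNDETERMINED", length(y1))
  ok <- y1 > 0
  out[ok] <- ifelse(y1f[ok] / y1[ok] > threshold, "CF", "nCF")
  out
}
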