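#' Monosaccharide and physical constants
#'
#' Monoisotopic residue masses (Da) of the monosaccharides occurring in the
#' pentasaccharide-core Y-ion series, plus the proton mass. Returned as a
#' plain named list so alternate mass conventions can be injected into any
#' function that takes a \code{masses} argument.
#'
#' @return Named list with elements \code{residues} (named numeric vector:
#'   HexNAc, Hex, Fuc, NeuAc, NeuGc), \code{proton} and \code{water} (Da).
#' @examples
#' monosaccharideMasses()$residues[["Fuc"]]
#' @export
monosaccharideMasses <- function() {
  list(
    residues = c(
      HexNAc = 203.079373,
      Hex    = 162.052824,
      Fuc    = 146.057909,
      NeuAc  = 291.095417,
      NeuGc  = 307.090331
    ),
    proton = 1.007276467,
    water  = 18.010565
  )
}

# monoisotopic residue masses of the 20 standard amino acids (Da, without water)
.AA_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Characteristic-ion definition table
#'
#' The ten Y-type characteristic ions (CIs) of the N-glycan pentasaccharide
#' core used as classification features: Y1..Y5 carry the peptide plus a
#' growing HexNAc/Hex core, Y1F..Y5F additionally retain one fucose. CI index
#' 1..10 corresponds to Y1,Y2,Y3,Y4,Y5,Y1F,Y2F,Y3F,Y4F,Y5F.
#'
#' @return A data.frame with columns \code{index}, \code{label},
#'   \code{HexNAc}, \code{Hex}, \code{Fuc} (monosaccharide counts retained on
#'   the peptide).
#' @examples
#' characteristicIons()
#' @export
characteristicIons <- function() {
  core <- data.frame(
    label  = c("Y1", "Y2", "Y3", "Y4", "Y5"),
    HexNAc = c(1L, 2L, 2L, 2L, 2L),
    Hex    = c(0L, 0L, 1L, 2L, 3L),
    Fuc    = 0L,
    stringsAsFactors = FALSE
  )
  fuc <- transform(core, label = paste0(label, "F"), Fuc = 1L)
  out <- rbind(core, fuc)
  out <- cbind(index = seq_len(10L), out)
  rownames(out) <- out$label
  out
}

#' Monoisotopic mass of a peptide
#'
#' Neutral monoisotopic mass of a peptide from its one-letter sequence,
#' including the terminating water and any configured fixed modifications.
#'
#' @param sequence Character scalar, standard one-letter amino-acid codes.
#' @param fixedMods Named numeric vector of per-residue fixed-modification
#'   mass shifts in Da. The default is carbamidomethylation of cysteine.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideMonoisotopicMass("G")   # 75.03203
#' peptideMonoisotopicMass("PEPTIDE")
#' @export
peptideMonoisotopicMass <- function(sequence,
                                    fixedMods = c(C = 57.021464)) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("'sequence' must be a non-empty character scalar")
  aa <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- setdiff(unique(aa), names(.AA_RESIDUE_MASS))
  if (length(unknown))
    stop("unknown amino-acid residue(s): ", paste(unknown, collapse = ", "))
  mass <- sum(.AA_RESIDUE_MASS[aa]) + monosaccharideMasses()$water
  if (length(fixedMods)) {
    hits <- table(factor(aa, levels = names(fixedMods)))
    mass <- mass + sum(hits * fixedMods)
  }
  unname(mass)
}

#' Neutral mass of a characteristic ion
#'
#' Adds the retained glycan residues of one CI to the neutral peptide mass.
#'
#' @param peptideMass Neutral peptide monoisotopic mass (Da), > 0.
#' @param ci One row of \code{\link{characteristicIons}()}, or a CI label
#'   such as \code{"Y1F"}.
#' @param masses Constants table, see \code{\link{monosaccharideMasses}}.
#' @return Neutral ion mass in Da.
#' @examples
#' ciNeutralMass(1000, "Y1")    # 1000 + HexNAc
#' @export
ciNeutralMass <- function(peptideMass, ci, masses = monosaccharideMasses()) {
  stopifnot(is.numeric(peptideMass), all(peptideMass > 0))
  if (is.character(ci)) {
    tab <- characteristicIons()
    if (!ci %in% tab$label) stop("unknown CI label: ", ci)
    ci <- tab[ci, ]
  }
  r <- masses$residues
  peptideMass + ci$HexNAc * r[["HexNAc"]] + ci$Hex * r[["Hex"]] +
    ci$Fuc * r[["Fuc"]]
}

#' m/z of an ion at a given charge
#'
#' @param neutralMass Neutral mass in Da (>= 0).
#' @param charge Positive integer charge state.
#' @param masses Constants table, see \code{\link{monosaccharideMasses}}.
#' @return m/z value \code{(neutralMass + charge * proton) / charge}.
#' @examples
#' ciMz(1203.079373, 1)
#' ciMz(1203.079373, 2)
#' @export
ciMz <- function(neutralMass, charge, masses = monosaccharideMasses()) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("'charge' must be a positive integer")
  (neutralMass + charge * masses$proton) / charge
}

#' Theoretical m/z table for all ten CIs of one peptide
#'
#' @param peptideMass Neutral peptide monoisotopic mass (Da).
#' @param charges Integer vector of charge states to tabulate.
#' @param masses Constants table.
#' @return data.frame with one row per (CI, charge): \code{index},
#'   \code{label}, \code{charge}, \code{mz}.
#' @export
ciMzTable <- function(peptideMass, charges = c(1L, 2L),
                      masses = monosaccharideMasses()) {
  tab <- characteristicIons()
  neutral <- vapply(seq_len(nrow(tab)), function(i)
    ciNeutralMass(peptideMass, tab[i, ], masses), numeric(1L))
  out <- expand.grid(index = tab$index, charge = as.integer(charges),
                     KEEP.OUT.ATTRS = FALSE)
  out$label <- tab$label[out$index]
  out$mz <- ciMz(neutral[out$index], out$charge, masses)
  out[, c("index", "label", "charge", "mz")]
}
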