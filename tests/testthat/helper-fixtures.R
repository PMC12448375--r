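# fixtures are built in code at test time; nothing binary ships with the tests

# minimal MGF text for a list of spectra given as list(list(id=, mz=, int=,
# pepmass=, charge=))
writeMGFFixture <- function(specs, path = tempfile(fileext = ".mgf")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in specs) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(paste0("SCANS=", s$id), con)
    if (!is.null(s$pepmass)) writeLines(paste0("PEPMASS=", s$pepmass), con)
    if (!is.null(s$charge)) writeLines(paste0("CHARGE=", s$charge, "+"), con)
    if (length(s$mz)) writeLines(sprintf("%.6f %.6g", s$mz, s$int), con)
    writeLines("END IONS", con)
  }
  path
}

writePSMFixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# PSM table data.frame with sensible defaults
psmRows <- function(scan_id, peptide = "SAMPLEK", peptide_mass = "",
                    glycan_composition = "HexNAc2Hex5",
                    structure_annotation = "", source_tag = "FUT8_KO") {
  data.frame(scan_id = scan_id, peptide = peptide,
             peptide_mass = peptide_mass,
             glycan_composition = glycan_composition,
             structure_annotation = structure_annotation,
             source_tag = source_tag, stringsAsFactors = FALSE)
}

# a small valid feature set with known content
toyFeatureSet <- function(n = 3L, seed = 1L, normalization = "sum") {
  set.seed(seed)
  raw <- matrix(round(runif(10 * n, 0.05, 0.9), 3), nrow = 10L)
  CIFeatureSet(raw, scanId = paste0("s", seq_len(n)),
               normalization = normalization)
}

# numeric KL(P||Q) between two Gaussians by quadrature (independent oracle)
numericKLGaussian <- function(p, q) {
  f <- function(x) {
    lp <- dnorm(x, p[1], p[2], log = TRUE)
    lq <- dnorm(x, q[1], q[2], log = TRUE)
    exp(lp) * (lp - lq)
  }
  lims <- range(p[1] - 8 * p[2], p[1] + 8 * p[2],
                q[1] - 8 * q[2], q[1] + 8 * q[2])
  integrate(f, lims[1], lims[2], rel.tol = 1e-10)$value
}
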