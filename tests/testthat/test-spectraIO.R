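test_that("MGF reading preserves scan ids and sorts peaks", {
  path <- writeMGFFixture(list(
    list(id = "scan_A", mz = c(300.1, 100.2, 200.3), int = c(1, 2, 3),
         pepmass = 500.25, charge = 2)))
  sp <- readSpectra(path)
  expect_length(sp, 1L)
  expect_identical(names(sp), "scan_A")
  pk <- peaks(sp[[1]])
  expect_identical(pk$mz, sort(pk$mz))
  expect_equal(pk$intensity, c(2, 3, 1))
  expect_equal(sp[[1]]@precursorMz, 500.25)
  expect_identical(sp[[1]]@precursorCharge, 2L)
})

test_that("empty MGF gives an empty list, malformed MGF is rejected", {
  empty <- tempfile(fileext = ".mgf"); file.create(empty)
  expect_length(readSpectra(empty), 0L)
  bad <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100 1"), bad)
  expect_error(readSpectra(bad), "unbalanced")
  expect_warning(
    readSpectra(writeMGFFixture(list(list(id = "s", mz = 100, int = 1)))),
    "precursor")
})

test_that("mzML spectra read through the same interface", {
  pks <- list(cbind(mz = c(100.5, 200.25, 300.75), intensity = c(10, 20, 5)))
  hdr <- data.frame(seqNum = 1L, acquisitionNum = 1L, msLevel = 2L,
    polarity = 1L, peaksCount = 3L, totIonCurrent = 35, retentionTime = 1,
    basePeakMZ = 200.25, basePeakIntensity = 20, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 100.5, highMZ = 300.75,
    precursorScanNum = 0L, precursorMZ = 500.1, precursorCharge = 2L,
    precursorIntensity = 100, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "f", spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = 500.1, isolationWindowLowerOffset = 1,
    isolationWindowUpperOffset = 1, scanWindowLowerLimit = 100,
    scanWindowUpperLimit = 1000, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, path, header = hdr)
  sp <- readSpectra(path)
  expect_length(sp, 1L)
  expect_equal(peaks(sp[[1]])$mz, c(100.5, 200.25, 300.75))
  expect_equal(sp[[1]]@precursorMz, 500.1)
})

test_that("glycan composition grammar parses counts with omitted = 1", {
  cmp <- parseGlycanComposition(c("HexNAc2Hex5Fuc1", "HexNAc2Hex3",
                                  "Hex", "HexNAc4Hex5Fuc1NeuAc1"))
  expect_identical(unname(cmp[1, "Hex"]), 5L)
  expect_identical(unname(cmp[1, "Fuc"]), 1L)
  expect_identical(unname(cmp[2, "Fuc"]), 0L)
  expect_identical(unname(cmp[3, "Hex"]), 1L)
  expect_identical(unname(cmp[4, "NeuAc"]), 1L)
  expect_error(parseGlycanComposition("Pent2Hex1"), "cannot parse")
})

test_that("PSM table resolves masses, skips massless rows, keeps duplicates", {
  df <- psmRows(c("s1", "s2", "s3", "s3"))
  df$peptide[2] <- ""
  df$peptide_mass <- c("", "1234.5", "", "")
  path <- writePSMFixture(df)
  expect_warning(psms <- readPSMTable(path), "duplicate scan_id")
  expect_identical(nrow(psms), 4L)
  # explicit mass column wins over the sequence
  expect_equal(psms$peptide_mass[2], 1234.5)
  expect_equal(psms$peptide_mass[1], peptideMonoisotopicMass("SAMPLEK"))
  df2 <- psmRows("s1"); df2$peptide <- ""; df2$peptide_mass <- ""
  expect_warning(out <- readPSMTable(writePSMFixture(df2)),
                 "lack both peptide and peptide_mass")
  expect_identical(nrow(out), 0L)
})

test_that("feature tables round-trip losslessly", {
  fs <- toyFeatureSet(3L)
  cfLabels(fs) <- c("nCF", "CF", "UNLABELED")
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(fs, path)
  back <- readFeatureTable(path)
  expect_equal(rawIntensity(back), rawIntensity(fs), tolerance = 1e-10)
  expect_equal(normIntensity(back), normIntensity(fs), tolerance = 1e-10)
  expect_identical(matchedMask(back), matchedMask(fs))
  expect_identical(cfLabels(back), cfLabels(fs))
  expect_identical(S4Vectors::metadata(back)$normalization, "sum")
  # a second round trip is exact on the text representation
  path2 <- tempfile(fileext = ".tsv")
  writeFeatureTable(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
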