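Package: CoreFucID
Title: Core-Fucosylation Identification from Intact Glycopeptide MS/MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies core-fucosylated (CF) versus non-core-fucosylated (nCF)
    intact glycopeptides from tandem mass spectra in the presence of fucose
    migration and fucose release rearrangements. Extracts a 10-dimensional
    feature vector of relative intensities of the ten pentasaccharide-core
    Y-type characteristic ions (Y1-Y5, Y1F-Y5F) at ppm tolerance, and
    classifies spectra with a semisupervised mapping-convergence model
    (one-class SVM initialisation refined by binary SVM iterations) and a
    self-supervised tanh autoencoder anomaly detector with reconstruction-error
    threshold alpha = mu + k*sigma. Includes case/control statistics of the
    log10 characteristic-ion intensities (Gaussian fits, symmetric
    Kullback-Leibler distances, fucose-migration ratios), a synthetic cohort
    and spectrum generator for benchmarking, split/evaluation protocols, and a
    Y1F/Y1-ratio baseline classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'glycoCore.R'
    'AllGenerics.R'
    'AllClasses.R'
    'spectraIO.R'
    'features.R'
    'aeModel.R'
    'fmStats.R'
    'synth.R'
    'mcModel.R'
    'labeling.R'
    'evaluate.R'
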