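# CoreFucID

Identification of core fucosylation from intact-glycopeptide MS/MS spectra,
in the presence of fucose rearrangement.

## The problem

Core fucosylation — an α1,6 fucose on the innermost GlcNAc of the N-glycan
pentasaccharide core — matters for antibody effector function, EGFR
signalling and disease biomarkers. Calling it from tandem mass spectra looks
easy: a core-fucosylated (CF) glycopeptide should produce Y-type fragments
that retain the fucose (Y1F–Y5F), a non-core-fucosylated (nCF) one should
not. Two gas-phase rearrangements break this logic:

* **Fucose migration (FM):** an antennary fucose migrates onto the core
  during fragmentation, producing YiF ions from nCF precursors.
* **Fucose release (FR):** the core fucose is lost during fragmentation,
  producing plain Yi ions from CF precursors.

In FUT8-knockout material (no core fucose possible at all), YiF signal is
still abundant: the most-popular YiF intensity runs from ~11% (i = 1) to
~51% (i = 5) of the corresponding Yi. A simple Y1F/Y1 > 0.1 threshold is
therefore unreliable at higher collision energies.

## The method

`CoreFucID` treats CF identification as a classification problem on a
10-dimensional feature vector **x** = (x₁,…,x₁₀): base-peak-relative
intensities of the ten pentasaccharide-core characteristic ions (CIs)
Y1–Y5, Y1F–Y5F, matched at 20 ppm, Max- or Sum-normalised, for spectra with
at least 3 of 10 CIs present. Two classifiers are trained without any
manually labelled CF spectra:

* **MC model** (semisupervised, positive–unlabelled): a one-class
  support-vector boundary fit on trusted nCF spectra (FUT8-knockout) splits
  the untagged wild-type set into candidate CF / nCF; a binary RBF SVM is
  then refit iteratively, moving newly identified negatives into the CF set
  N until no more are found (mapping–convergence).
* **AE model** (self-supervised): a 10-9-8-7-8-9-10 tanh autoencoder
  trained on trusted nCF vectors; a spectrum is called CF when its
  reconstruction error ‖x − g(f(x))‖ exceeds α = μ + kσ (k = 0.4), with μ,
  σ from the training errors.

Trustworthy labels come from two rules immune to FM/FR: FUT8-knockout →
nCF, and core-fucosylated (pauci/high-)mannose (HexNAc₂Hex≥₃Fuc₁, no sialic
acid, upstream core-fucose structure call) → CF.

The statistics module fits per-CI Gaussians to log₁₀ relative intensities
of case (knockout) vs control (wild-type) cohorts, scores the separation
with the symmetric Kullback–Leibler distance
D(P,Q) = (KL(P‖Q) + KL(Q‖P))/2, and quantifies FM via the ratio
100·10^(μ_YiF − μ_Yi). A synthetic generator reproduces the published
cohort statistics so the whole pipeline is testable without the original
raw data.

## Worked example

```r
library(CoreFucID)

bench <- makeBenchmark(nCase = 2000, nControl = 2000, cfWeight = 0.3, seed = 1)
split <- splitDatasets(bench$tagged, bench$untagged, seed = 1)

mc <- trainMC(split$trainMC$tagged, split$trainMC$untagged, seed = 1)
mc
#> MCModel (mapping-convergence, binary final classifier)
#>   identified CF in U: 570 | iterations: 1 | converged: TRUE

test  <- split$testMC$untagged
truth <- SummarizedExperiment::colData(test)$truth
round(unlist(evaluateMetrics(predict(mc, test), truth)[
  c("cf_acc", "ncf_acc", "overall_acc", "f1")]), 4)
#>      cf_acc     ncf_acc overall_acc          f1
#>      1.0000      0.9888      0.9925      0.9887

ae <- trainAE(split$trainAE, k = 0.4, seed = 1)
ae
#> AEModel (tanh autoencoder 10-9-8-7-8-9-10)
#>   mu = 0.03802, sigma = 0.02216, k = 0.40 -> alpha = 0.04689
#>   trained 500 epochs, final loss 0.0001947
```

The MC model recovers the hidden CF component of the untagged mixture at
100% recall with 98.9% specificity; the AE threshold α is the mean training
reconstruction error plus 0.4 standard deviations.

The case/control statistics on the same benchmark (excerpt):

```r
rep <- buildKLReport(bench$tagged, bench$untagged)
rep$table[c(1, 2, 6, 7), ]
#>  label case_mu case_sigma control_mu control_sigma    kl
#>     Y1  -0.782      0.258     -0.851         0.299 0.054
#>     Y2  -1.056      0.244     -1.103         0.262 0.022
#>    Y1F  -1.704      0.160     -1.043         0.677 8.562
#>    Y2F  -1.858      0.230     -1.294         0.621 3.069
rep$fm
#>  i ratio_pct
#>  1     11.95
#>  2     15.76
#>  3     30.38
#>  4     40.80
#>  5     50.47
```

The F-series ions separate the cohorts most strongly (large KL for Y1F,
Y2F), and the FM ratios — YiF intensity as a percentage of Yi in a cohort
that cannot contain core fucose — grow from ~12% to ~50% with core size,
which is the fingerprint of fucose migration.

A thin CLI over the same functions is installed at
`inst/cli/corefucid` (`simulate`, `extract-features`, `label`, `train-mc`,
`train-ae`, `predict`, `baseline`, `kl-report`, `evaluate`, `robustness`).

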