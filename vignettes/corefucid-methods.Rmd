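---
title: "Core-fucosylation identification under fucose rearrangement: models and design"
author: "CoreFucID"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-fucosylation identification under fucose rearrangement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoreFucID)
```

## The identification problem

An N-glycopeptide fragmented by HCD produces Y-type ions that retain the
peptide and a shrinking glycan stub. The ten fragments anchored on the
pentasaccharide core — Y1…Y5 (peptide + HexNAc, + HexNAc₂, + HexNAc₂Hex,
+ HexNAc₂Hex₂, + HexNAc₂Hex₃) and their fucosylated twins Y1F…Y5F — are the
*characteristic ions* (CIs). In an ideal spectrum the presence of any YiF
would prove core fucosylation. Two rearrangements during fragmentation
destroy that proof: fucose migration (FM) moves an antennary fucose onto
the core and fabricates YiF signal in true-nCF spectra, and fucose release
(FR) strips the core fucose and fabricates Yi-only signal in true-CF
spectra. The package therefore treats the ten CI relative intensities as a
joint feature vector and learns the CF/nCF decision from data whose labels
cannot be corrupted by either rearrangement.

### Trustworthy labels

Two label sources are immune by construction:

* spectra from FUT8-knockout material are nCF — the enzyme that installs
  core fucose is absent;
* core-fucosylated (pauci/high-)mannose glycans are CF — with no antennary
  fucose present, FM cannot have fabricated the fucose on the core. The
  rule is operationalised as composition HexNAc₂ Hex ≥ 3 Fuc₁, no sialic
  acid, plus an explicit upstream structure call (the package consumes
  structure assignments, e.g. from StrucGP-style tools; it does not make
  them).

Everything else stays `UNLABELED` and is usable for semisupervised
training but never for evaluation.

## Feature extraction

For each identified spectrum the theoretical CI m/z values are computed
from the peptide monoisotopic mass (explicit mass column preferred,
sequence-derived otherwise; carbamidomethyl-Cys fixed by default) and the
residue masses HexNAc 203.07937, Hex 162.05282, Fuc 146.05791 Da, proton
1.007276. Matching and normalisation choices:

| parameter | default | rationale |
|---|---|---|
| mass tolerance | 20 ppm, against theoretical m/z | standard Orbitrap-class accuracy |
| charge states | {1, 2}, intensities summed | Y ions of intact glycopeptides appear mostly at 1+/2+; summing is charge-agnostic |
| window tie-break | highest intensity | robust to centroiding jitter, unlike nearest-m/z |
| intensity reference | base peak (TIC optional) | reference cohort log₁₀ values (−0.8…−1.9) match base-peak-relative magnitudes |
| missing CI | zero-filled before normalisation | training requires fixed-length vectors; ≥3-of-10 filter bounds the damage |
| minimum CIs | 3 of 10 | spectra with fewer carry too little core information |
| normalisation | Sum (Max available) | Sum is the more robust variant in the missing-CI experiment; it is also the default pairing for the AE threshold k = 0.4 |

Zeros are *excluded* again before any distribution fitting (log₁₀ of an
unmatched CI is undefined); zero-filling is a vector-shape convention, not
a measurement.

## The mapping-convergence (MC) model

Positive–unlabelled learning with P = tagged nCF, U = untagged. The
*mapping* phase fits a one-class support-vector boundary on P (the SVDD
role) and splits U into initial negatives N₀ (outside the boundary —
candidate CF) and positives P₀. The *convergence* phase repeats: fit a
binary RBF SVM on (P positive, N negative), classify the current positive
remainder Pᵢ, move its predicted negatives into N, stop when an iteration
adds none. N can only grow, so the loop terminates in at most |U|
iterations; a cap of 100 guards numerical edge cases.

Hyperparameters (the published procedure names the learners but no
settings): ν = 0.05 for the one-class boundary — the expected outlier
fraction on clean nCF data; C = 1 for the binary SVM; a shared RBF
bandwidth γ = 1/(10 · mean per-feature variance of P). All are arguments
of `trainMC()`. No class rebalancing is applied during iterations — the
procedure is followed literally; `classWeights` exists but defaults off.
The positive class of the final classifier is nCF (P's tag); predictions
are reported as CF/nCF strings. The underlying solvers are deterministic,
so a fixed seed makes the whole run bit-reproducible.

## The autoencoder (AE) model

A fully connected 10-9-8-7-8-9-10 autoencoder, tanh on every layer
including the output (inputs lie in [0, 1], inside tanh's range, so no
rescaling), trained on tagged nCF vectors only. The algorithm description
in the source of this method is ambiguous about the training set (its
algorithm box says "untagged", its data-usage section says tagged-only);
the tagged-only reading is implemented — an anomaly detector must be
trained on the class it is supposed to reconstruct well, and the 95%/5%
tagged split exists precisely to feed it.

Training: mean-squared reconstruction loss, Adam (β₁ = 0.9, β₂ = 0.999),
learning rate 1e-3, batch 256, up to 500 epochs with early stop after 20
epochs without improvement > 1e-7. The decision statistic is the Euclidean
reconstruction error e = ‖x − g(f(x))‖; the threshold is α = μ + kσ with
μ, σ the mean and SD of the training errors and k = 0.4 (the published
optimum). `predict` uses the strict inequality e > α; `setThresholdK()`
re-thresholds without retraining. Divergence (non-finite loss) aborts with
the configuration echoed.

### What k = 0.4 implies

On a unimodal, roughly symmetric error distribution, μ + 0.4σ sits near
the 65th–80th percentile, so 20–35% of genuinely nCF spectra are flagged
CF. On the package's default synthetic benchmark the AE accordingly shows
very high CF recall (~1.0) but nCF specificity of only ~0.8 — and the
corresponding acceptance-suite expectation of ≥0.90 on both classes fails
on the nCF side, deliberately left failing rather than papered over. High
specificity at this k requires a strongly right-skewed error distribution
(a dense, well-reconstructed core of typical spectra plus a thin tail),
which real cohorts may exhibit but the generator's smooth
independent-dropout mixture does not. This is a genuine property of the
α = μ + kσ rule, worth knowing before trusting k = 0.4 on a new dataset;
`setThresholdK()` makes recalibration cheap.

## Case/control statistics

Per CI and cohort, the matched (nonzero) relative intensities are log₁₀
transformed and summarised by the sample mean and SD (denominator n − 1).
Cohort separation per CI is the symmetric Gaussian Kullback–Leibler
distance D(P,Q) = (KL(P‖Q) + KL(Q‖P))/2 in closed form; the
implementation is cross-checked against numerical quadrature of the KL
integrand to 1e-6 in the test suite. The reference parameter table
(`referenceCohortParams()`) stores the published case/control fits; the
second entry of each printed pair is interpreted as a *standard
deviation* — under the variance interpretation none of the published
distances is reproducible, under the SD interpretation the Y2, Y2F and Y4
rows agree to ~2–3% (the residual is parameter rounding: means are printed
to two decimals). The remaining rows do not reproduce from the rounded
parameters under either reading and were evidently computed from unrounded
fits; they are not asserted against.

Fucose migration is quantified by `fmRatio()`: in a pure-nCF cohort every
YiF ion is FM-made, so 100·10^(μ_YiF − μ_Yi) — the most-popular YiF
intensity as a percentage of the most-popular Yi intensity — measures the
rearrangement's severity. From the reference case means this runs ~11% to
~51%, increasing with core size. CIs with fewer than 30 matched values per
cohort are reported absent rather than as fabricated zeros.

## The synthetic generator

`sampleFeatureCohort()` draws per-CI intensities as 10^N(μ, σ), clipped to
(0, 1], with independent per-CI dropout; `makeBenchmark()` assembles the
study design (tagged FUT8-KO-like cohort; untagged mixture with hidden
truth); `synthesizeSpectrum()`/`simulateDataset()` materialise vectors as
centroided peak lists so the full MGF → PSM → extraction path is
exercised. Defaults and their reasoning:

* Case/nCF component: the published case-cohort (μ, σ) per CI; dropout 0.1
  on Y-series, 0.6 on F-series — FM-made YiF ions are sporadic, and this
  level also keeps the benchmark consistent with the documented behaviour
  of the single-ratio baseline on it (>80% balanced accuracy).
* CF component: the published *control* parameters with the five F-series
  means shifted up by 0.8 decades and F-series dropout 0.1. The published
  statistics only constrain the CF+nCF *mixture*, never a pure-CF
  distribution, so this component is an explicit synthetic choice (a
  genuinely core-fucosylated spectrum should show strong, rarely missing
  YiF signal); every benchmark records the hidden truth it was built from.
* Control cohort: nCF and CF components mixed with weight 0.3 on CF.
* Spectrum synthesis places CI peaks at worst case: exactly the requested
  ppm error with random sign, so a jitter below the matching tolerance is
  always recovered and one above it never is. Noise peaks avoid all CI
  windows by a 30 ppm guard.

What passing tests on this generator show — and what they do not: the
generator reproduces the *marginal log-Gaussian structure, dropout and
mixture design* of the real cohorts, so it validates the bookkeeping,
the learning procedures and the statistics end to end. It does not
reproduce inter-CI correlations, charge-state effects, collision-energy
dependence, isotope interference or chimeric spectra; classifier
accuracies on it (98–100% for MC) are upper bounds driven by the chosen
CF shift, not predictions for real data, and the published real-data
accuracies (~89–99%) are not an acceptance surface here.

## Splits and evaluation

Cohorts are shuffled and split independently with floor-rule sizes
(train = ⌊frac·n⌋): 80% of tagged + 80% of untagged for MC, 95% of tagged
for AE — the two printed conventions, which uniquely reproduce the three
published training-set counts (23,809 → 19,047; 20,072 → 16,057;
23,809 → 22,618). Evaluation uses only trustworthily labelled test
spectra (`buildTestPrime()`): tagged test rows as nCF, untagged test rows
with a core-fucosylated-mannose call as CF. Metrics are per-class recalls,
overall accuracy and F1 with CF as the positive class — the minority
detection target; `UNDETERMINED` baseline outputs are excluded from the
denominator and counted separately. The published F1 values could not be
reconciled with the published per-class accuracies and class sizes under
any standard binary F1, so F1 is defined cleanly here and compared with
nothing.

`robustnessExperiment()` re-runs training under minimum-CI filters
{3, 4, 5, 6} × {Max, Sum} × {MC, AE} against a fixed test set, the
missing-ion robustness design.

## Numerical choices and problem sizes

Degenerate inputs are rejected early (all-zero vectors at normalisation,
non-positive intensities at log fitting, σ ≤ 0 at KL). The Glorot-uniform
initialisation, seeded batch shuffling and deterministic SVM solvers make
every pipeline stage bit-reproducible under one seed, which the test suite
asserts end to end. Test problem sizes are chosen so the default suite
runs in well under a minute of compute per file: benchmark classifiers at
5,000 + 5,000 vectors, parameter recovery at 50,000, KL Monte-Carlo at
20,000, invariants over 20 seeds at 200–400 vectors; these are the
package's declared study conditions, stated here so results are read at
the scale that produced them.

## Known limitations

* The CI vocabulary is fixed at the ten core Y ions; antennary-specific
  ions, oxonium ions and B/C/Z fragments are out of scope.
* The Y1F/Y1 baseline (`y1fY1Baseline()`, threshold 0.1) is provided as
  the comparison method; it is collision-energy sensitive and fails
  exactly where FM/FR are strong.
* No deisotoping or intensity recalibration is performed; inputs are
  assumed centroided.
* The pure-CF distribution is unidentifiable from the published mixture
  statistics; all CF-side accuracies on synthetic data inherit that
  assumption.
* k = 0.4 transfers poorly to error distributions unlike those it was
  tuned on (see the AE section); recalibrate before use on new cohorts.
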