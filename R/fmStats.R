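#' @include AllClasses.R
NULL

#' Reference case/control Gaussian parameters
#'
#' Published per-characteristic-ion Gaussian parameters of log10 relative
#' intensity for the FUT8-knockout mouse-brain case cohort (pure nCF) and the
#' wild-type control cohort (CF + nCF mixture). The second entry of each pair
#' is the standard deviation of the log10 intensities. These parameters
#' drive the default synthetic cohorts and the fucose-migration diagnostics.
#'
#' @return data.frame with one row per CI: \code{index}, \code{label},
#'   \code{case_mu}, \code{case_sigma}, \code{control_mu},
#'   \code{control_sigma}.
#' @examples
#' referenceCohortParams()
#' @export
referenceCohortParams <- function() {
  data.frame(
    index = 1:10,
    label = characteristicIons()$label,
    case_mu       = c(-0.78, -1.05, -1.17, -1.04, -1.06,
                      -1.72, -1.86, -1.69, -1.43, -1.35),
    case_sigma    = c(0.25, 0.25, 0.23, 0.20, 0.30,
                      0.16, 0.24, 0.24, 0.19, 0.22),
    control_mu    = c(-1.04, -1.25, -1.37, -1.37, -1.53,
                      -1.19, -1.51, -1.74, -1.52, -1.53),
    control_sigma = c(0.30, 0.24, 0.23, 0.24, 0.30,
                      0.16, 0.18, 0.14, 0.17, 0.23),
    stringsAsFactors = FALSE
  )
}

#' Fit a Gaussian to log10 intensities
#'
#' Sample mean and standard deviation (denominator n-1) of
#' \code{log10(intensities)}. Zeros encode unmatched CIs and must be removed
#' before calling; any non-positive value is an error.
#'
#' @param intensities Numeric vector of relative intensities, all > 0,
#'   length >= 2.
#' @return Named numeric vector \code{c(mu =, sigma =)}.
#' @examples
#' fitLogGaussian(c(0.1, 0.1, 0.1))   # mu -1, sigma 0
#' @export
fitLogGaussian <- function(intensities) {
  if (length(intensities) < 2L)
    stop("need at least 2 values to fit a Gaussian")
  if (any(intensities <= 0))
    stop("all intensities must be > 0 (filter unmatched zeros first)")
  lg <- log10(intensities)
  c(mu = mean(lg), sigma = stats::sd(lg))
}

#' Kullback-Leibler divergence between two Gaussians (closed form)
#'
#' @param p,q Numeric pairs \code{(mean, sd)}, sd > 0.
#' @return \code{KL(p || q)} in nats.
#' @export
klGaussian <- function(p, q) {
  if (p[2L] <= 0 || q[2L] <= 0) stop("standard deviations must be > 0")
  log(q[2L] / p[2L]) + (p[2L]^2 + (p[1L] - q[1L])^2) / (2 * q[2L]^2) - 0.5
}

#' Symmetrised Gaussian KL distance
#'
#' \code{(KL(p||q) + KL(q||p)) / 2}, used as the case/control distribution
#' distance per characteristic ion.
#'
#' @param p,q Numeric pairs \code{(mean, sd)}, sd > 0.
#' @return Non-negative scalar.
#' @examples
#' symmetricKLGaussian(c(0, 1), c(1, 1))   # 0.5
#' @export
symmetricKLGaussian <- function(p, q) {
  unname((klGaussian(p, q) + klGaussian(q, p)) / 2)
}

#' Fucose-migration intensity ratio
#'
#' Ratio (percent) of the most-popular relative intensity of YiF to that of
#' Yi, \code{100 * 10^(muYiF - muYi)}, using the Gaussian means of the log10
#' relative intensities. In a pure-nCF cohort any YiF signal stems from
#' fucose migration, so this ratio measures how serious FM is.
#'
#' @param muYiF,muYi Gaussian means of log10 relative intensity for YiF and
#'   Yi.
#' @return Percentage.
#' @examples
#' fmRatio(-2, -1)    # 10
#' @export
fmRatio <- function(muYiF, muYi) {
  100 * 10^(muYiF - muYi)
}

#' Case/control KL report over all characteristic ions
#'
#' Fits per-CI Gaussians to the log10 relative intensities of a case and a
#' control cohort (zeros, i.e. unmatched CIs, excluded), computes the
#' symmetrised KL distance per CI, and the per-core-size fucose-migration
#' ratios from the case means. CIs with fewer than \code{minN} matched
#' values in either cohort are reported as NA.
#'
#' @param case,control \linkS4class{CIFeatureSet}s (raw intensities are
#'   used) or 10 x n matrices.
#' @param minN Minimum matched values per CI per cohort (default 30).
#' @return List with \code{table} (per-CI fits and KL distances) and
#'   \code{fm} (data.frame of FM ratios for i = 1..5, from case means).
#' @export
buildKLReport <- function(case, control, minN = 30L) {
  getRaw <- function(x) if (is(x, "CIFeatureSet")) rawIntensity(x)
                        else as.matrix(x)
  case <- getRaw(case); control <- getRaw(control)
  if (ncol(case) == 0L || ncol(control) == 0L)
    stop("both cohorts must be non-empty")
  fitRow <- function(v) {
    v <- v[v > 0]
    if (length(v) < minN) c(mu = NA_real_, sigma = NA_real_, n = length(v))
    else c(fitLogGaussian(v), n = length(v))
  }
  fc <- t(apply(case, 1L, fitRow))
  fq <- t(apply(control, 1L, fitRow))
  D <- vapply(1:10, function(i) {
    if (anyNA(c(fc[i, 1:2], fq[i, 1:2])) || fc[i, 2L] <= 0 ||
        fq[i, 2L] <= 0) NA_real_
    else symmetricKLGaussian(fc[i, 1:2], fq[i, 1:2])
  }, numeric(1L))
  tab <- data.frame(
    index = 1:10, label = characteristicIons()$label,
    case_mu = fc[, "mu"], case_sigma = fc[, "sigma"],
    case_n = as.integer(fc[, "n"]),
    control_mu = fq[, "mu"], control_sigma = fq[, "sigma"],
    control_n = as.integer(fq[, "n"]),
    kl = D, stringsAsFactors = FALSE)
  fm <- data.frame(
    i = 1:5,
    ratio_pct = fmRatio(tab$case_mu[6:10], tab$case_mu[1:5]))
  list(table = tab, fm = fm)
}
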