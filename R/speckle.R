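#' Envelope histogram of a speckle patch
#'
#' Density-normalized histogram computed on the envelope (pre-log) image,
#' the domain in which fully developed speckle is Rayleigh distributed.
#'
#' @param patch numeric matrix/vector of envelope amplitudes.
#' @param n_bins number of bins (>= 2).
#' @param breaks optional explicit bin edges (overrides `n_bins`); use the
#'   same edges to make two histograms comparable.
#' @return list with `breaks`, `density`, `counts`.
#' @export
speckle_histogram <- function(patch, n_bins = 50, breaks = NULL) {
  x <- as.numeric(patch)
  if (length(x) == 0) stop("empty patch")
  if (is.null(breaks)) {
    if (n_bins < 2) stop("n_bins must be >= 2")
    breaks <- seq(min(x), max(x), length.out = n_bins + 1)
    if (breaks[1] == breaks[length(breaks)])
      breaks <- breaks[1] + seq(-0.5, 0.5, length.out = n_bins + 1)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, density = h$density, counts = h$counts)
}

#' Overlap of two speckle histograms
#'
#' Histogram intersection: sum over bins of the pointwise minimum density
#' times the bin width.  1 means identical distributions, 0 disjoint
#' support.  Both histograms must share bin edges; use
#' [speckle_histogram()] with a common `breaks`.
#'
#' @param h1,h2 histograms from [speckle_histogram()] on identical breaks.
#' @return overlap in `[0, 1]`.
#' @export
histogram_overlap <- function(h1, h2) {
  if (!isTRUE(all.equal(h1$breaks, h2$breaks)))
    stop("histograms must share bin edges")
  widths <- diff(h1$breaks)
  sum(pmin(h1$density, h2$density) * widths)
}

## Linear (zero-padded) 2-D autocorrelation of a mean-subtracted patch,
## normalized to 1 at zero lag.  FFT-based; padding to >= 2N-1 avoids the
## circular wrap-around that biases FWHM estimates.
speckle_autocorr <- function(patch) {
  x <- patch - mean(patch)
  n <- nrow(x); m <- ncol(x)
  P <- 2^ceiling(log2(2 * max(n, m) - 1))
  xp <- matrix(0, P, P); xp[1:n, 1:m] <- x
  F <- stats::fft(xp)
  ac <- Re(stats::fft(F * Conj(F), inverse = TRUE)) / length(F)
  if (ac[1, 1] <= 0) stop("zero-variance patch")
  ac <- ac / ac[1, 1]
  # re-centre: lags -(n-1)..(n-1)
  list(ac = ac, P = P)
}

## FWHM of a symmetric profile through lag 0, linear interpolation between
## the two lags bracketing the half-maximum.
fwhm_profile <- function(prof) {
  # prof[1] = 1 at lag 0, prof[k] at lag k-1
  below <- which(prof < 0.5)
  if (length(below) == 0)
    stop("autocorrelation never falls below 0.5: patch too small")
  k <- below[1]                       # first lag strictly below half max
  hi <- prof[k - 1]; lo <- prof[k]
  lag_half <- (k - 2) + (hi - 0.5) / (hi - lo)
  2 * lag_half                        # symmetric: full width = 2 x half lag
}

#' Speckle size via autocorrelation FWHM
#'
#' The full width at half maximum of the (linear, normalized) 2-D
#' autocorrelation of the envelope patch, measured along each image axis
#' through the zero-lag peak, with sub-pixel linear interpolation.  The
#' FWHM is the conventional proxy for speckle-cell size, hence for the
#' point-spread-function extent along each axis.
#'
#' @param patch envelope-domain matrix (mean is subtracted internally).
#' @return named numeric: `fwhm_axis0` (rows/axial), `fwhm_axis1`
#'   (cols/lateral), in pixels.
#' @export
speckle_size <- function(patch) {
  a <- speckle_autocorr(patch)
  n <- nrow(patch); m <- ncol(patch)
  prof0 <- a$ac[1:n, 1]               # lags 0..n-1 along axis 0
  prof1 <- a$ac[1, 1:m]
  c(fwhm_axis0 = fwhm_profile(prof0), fwhm_axis1 = fwhm_profile(prof1))
}

#' Ellipse eccentricity of the speckle cell
#'
#' `sqrt(b^2 - a^2) / b` with `a` the shortest and `b` the longest axis;
#' the arguments are ordered canonically, so the result is invariant under
#' swapping.  0 means isotropic resolution; values near 1 mean strongly
#' anisotropic speckle.
#'
#' @param fwhm_a,fwhm_b speckle FWHM along the two axes (any order), > 0.
#' @return eccentricity in `[0, 1)`.
#' @export
eccentricity <- function(fwhm_a, fwhm_b) {
  if (fwhm_a <= 0 || fwhm_b <= 0) stop("FWHM values must be positive")
  b <- max(fwhm_a, fwhm_b); a <- min(fwhm_a, fwhm_b)
  sqrt(b^2 - a^2) / b
}

#' Speckle statistics of an image stack over a fixed region
#'
#' Applies [speckle_size()] and [eccentricity()] to the same rectangular
#' region of every frame and aggregates mean +/- sd, the frame-averaging
#' convention used when comparing band-limited, enhanced and full-bandwidth
#' stacks.
#'
#' @param stack 3-D array (H x W x N) of envelope images.
#' @param region integer vector `c(r0, c0, r1, c1)` (inclusive).
#' @return data.frame with per-frame fwhm/eccentricity plus attribute
#'   `summary` (mean and sd).
#' @export
speckle_report <- function(stack, region) {
  stopifnot(length(dim(stack)) == 3, length(region) == 4)
  rows <- lapply(seq_len(dim(stack)[3]), function(i) {
    p <- stack[region[1]:region[3], region[2]:region[4], i]
    s <- speckle_size(p)
    data.frame(frame = i, fwhm_axial = s[["fwhm_axis0"]],
               fwhm_lateral = s[["fwhm_axis1"]],
               eccentricity = eccentricity(s[[1]], s[[2]]))
  })
  d <- do.call(rbind, rows)
  attr(d, "summary") <- c(ecc_mean = mean(d$eccentricity),
                          ecc_sd = stats::sd(d$eccentricity))
  d
}
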