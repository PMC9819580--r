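#' Synthetic speckle phantoms
#'
#' Generates random scatterer fields emulating gelatin phantoms doped with
#' silicon-carbide scatterers at different concentrations: a diffuse
#' background plus embedded inclusions (rectangles or disks) whose relative
#' echogenicity is controlled per region.  Convolving such a field with a
#' band-limited pulse (see [simulate_rf()]) yields fully developed speckle,
#' the statistical regime conventional B-mode imaging assumes.
#'
#' @param shape integer vector `c(depth_px, lateral_px)`.
#' @param density expected scatterers per pixel, in (0, 1]. `0` is allowed
#'   and produces an empty field.
#' @param contrast_levels numeric vector of per-region echogenicity
#'   multipliers; element 1 is the background, element `k + 1` applies to
#'   inclusion `k`.
#' @param inclusion_specs list of inclusion geometries, each a list with
#'   `type` (`"rect"` or `"circle"`) and, for rectangles,
#'   `r0, c0, r1, c1` (inclusive pixel bounds) or, for circles,
#'   `center = c(r, c)`, `radius` (pixels).
#' @param seed integer seed; the same seed reproduces the field bit for bit.
#' @return An object of class `scatterer_field`: list with `amplitudes`
#'   (depth x lateral matrix), `region_labels` (integer matrix, 0 =
#'   background), `pixel_spacing` (mm, axial/lateral), `seed`.
#' @examples
#' f <- make_scatterer_field(c(128, 64), density = 0.08, seed = 1)
#' mean(f$amplitudes != 0)
#' @export
make_scatterer_field <- function(shape, density = 0.05,
                                 contrast_levels = 1,
                                 inclusion_specs = list(),
                                 pixel_spacing = c(0.05, 0.1),
                                 seed) {
  if (length(shape) != 2 || any(shape < 1)) stop("shape must be two positive integers")
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (length(contrast_levels) < length(inclusion_specs) + 1)
    stop("need one contrast level for the background plus one per inclusion")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])

  labels <- matrix(0L, H, W)
  for (k in seq_along(inclusion_specs)) {
    sp <- inclusion_specs[[k]]
    if (identical(sp$type, "rect")) {
      if (sp$r0 < 1 || sp$c0 < 1 || sp$r1 > H || sp$c1 > W || sp$r0 > sp$r1 || sp$c0 > sp$c1)
        stop("inclusion ", k, " (rect) lies outside the ", H, "x", W, " grid")
      labels[sp$r0:sp$r1, sp$c0:sp$c1] <- k
    } else if (identical(sp$type, "circle")) {
      ctr <- sp$center; rad <- sp$radius
      if (ctr[1] - rad < 1 || ctr[1] + rad > H || ctr[2] - rad < 1 || ctr[2] + rad > W)
        stop("inclusion ", k, " (circle) lies outside the ", H, "x", W, " grid")
      rr <- row(labels) - ctr[1]; cc <- col(labels) - ctr[2]
      labels[rr^2 + cc^2 <= rad^2] <- k
    } else stop("unknown inclusion type: ", sp$type)
  }

  set.seed(seed)
  amp <- matrix(0, H, W)
  if (density > 0) {
    occupied <- matrix(stats::runif(H * W) < density, H, W)
    # signed zero-mean amplitudes, then per-region contrast scaling
    amp[occupied] <- stats::runif(sum(occupied), -1, 1)
    amp <- amp * matrix(contrast_levels[labels + 1L], H, W)
  } else {
    labels <- matrix(0L, H, W)   # empty field carries an empty label map
  }
  structure(list(amplitudes = amp, region_labels = labels,
                 pixel_spacing = pixel_spacing, seed = as.integer(seed)),
            class = "scatterer_field")
}

#' Imaging pulse description
#'
#' The separable point-spread function used by [simulate_rf()]: axially a
#' carrier cosine at `center_frequency` under a Gaussian envelope whose
#' -6 dB (half-amplitude) spectral full width equals `passband_width`;
#' laterally a Gaussian beam profile.
#'
#' @param center_frequency carrier frequency in Hz.
#' @param passband_width full -6 dB passband width in Hz (default 3.04 MHz).
#' @param axial_sampling_frequency RF sampling rate in Hz.
#' @param lateral_beamwidth Gaussian sigma of the lateral PSF, in pixels.
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency = 7.8e6,
                       passband_width = 3.04e6,
                       axial_sampling_frequency = 31.25e6,
                       lateral_beamwidth = 1.5) {
  if (passband_width <= 0 || passband_width >= axial_sampling_frequency)
    stop("need 0 < passband_width < axial_sampling_frequency")
  if (center_frequency <= passband_width / 2)
    stop("center_frequency must exceed half the passband width")
  if (center_frequency + passband_width / 2 > axial_sampling_frequency / 2)
    stop("passband extends beyond Nyquist")
  structure(list(center_frequency = center_frequency,
                 passband_width = passband_width,
                 axial_sampling_frequency = axial_sampling_frequency,
                 lateral_beamwidth = lateral_beamwidth),
            class = "pulse_spec")
}

## Gaussian sigma (seconds) whose magnitude spectrum has -6 dB full width W Hz:
## |H(f)| = exp(-(f-fc)^2 / (2 sf^2)), half amplitude at |f-fc| = sf*sqrt(2 log 2)
## so W = 2 sf sqrt(2 log 2) and sigma_t = 1 / (2 pi sf).
pulse_sigma_t <- function(pulse) {
  sf <- pulse$passband_width / (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sf)
}

#' Axial/lateral PSF kernels of a pulse
#' @keywords internal
pulse_psf <- function(pulse, n_sigma = 4) {
  fs <- pulse$axial_sampling_frequency
  st <- pulse_sigma_t(pulse)                       # seconds
  half <- max(1L, ceiling(n_sigma * st * fs))
  t <- (-half:half) / fs
  axial <- cos(2 * pi * pulse$center_frequency * t) * exp(-t^2 / (2 * st^2))
  sl <- pulse$lateral_beamwidth
  halfl <- max(1L, ceiling(n_sigma * sl))
  u <- -halfl:halfl
  lateral <- exp(-u^2 / (2 * sl^2))
  list(axial = axial, lateral = lateral)
}

## FFT-based 1-D "same" convolution applied down the columns (axial axis) or
## across rows (lateral), zero-padded so the convolution is linear.
conv_same_axis <- function(x, kern, axis) {
  if (axis == 2) return(t(conv_same_axis(t(x), kern, 1)))
  n <- nrow(x); m <- length(kern)
  if (m > n) stop("PSF longer than image along the convolved axis")
  L <- n + m - 1
  K <- stats::fft(c(kern, rep(0, L - m)))
  X <- stats::mvfft(rbind(x, matrix(0, L - n, ncol(x))))
  full <- Re(stats::mvfft(X * K, inverse = TRUE)) / L
  off <- (m - 1) %/% 2
  full[(off + 1):(off + n), , drop = FALSE]
}

#' Simulate a beamformed RF image from a scatterer field
#'
#' Linear convolution model: the RF image is the 2-D "same" convolution of
#' the reflectivity map with a separable PSF (axial Gabor pulse x lateral
#' Gaussian).  This produces fully developed speckle with the axial spectrum
#' concentrated in the pulse passband.
#'
#' @param field a `scatterer_field`.
#' @param pulse a `pulse_spec`.
#' @return object of class `rf_image`: list with `samples` (matrix),
#'   `axial_sampling_frequency`, `pulse`.
#' @export
simulate_rf <- function(field, pulse = pulse_spec()) {
  stopifnot(inherits(field, "scatterer_field"), inherits(pulse, "pulse_spec"))
  x <- field$amplitudes
  if (length(x) == 0) stop("empty scatterer field")
  psf <- pulse_psf(pulse)
  y <- conv_same_axis(x, psf$axial, 1)
  y <- conv_same_axis(y, psf$lateral, 2)
  structure(list(samples = y,
                 axial_sampling_frequency = pulse$axial_sampling_frequency,
                 pulse = pulse),
            class = "rf_image")
}

#' Simulate a batch of paired speckle phantoms
#'
#' Convenience generator for studies: each image gets a random set of
#' inclusions (rectangles/disks at echogenicity levels emulating low,
#' medium and high scatterer concentrations) and is rendered to RF.
#'
#' @param n number of images.
#' @param shape image size `c(depth_px, lateral_px)` (study default
#'   `c(801, 401)`; tests use smaller sizes).
#' @param density scatterers per pixel.
#' @param pulse a `pulse_spec`.
#' @param contrast_levels echogenicity multipliers to sample inclusions from.
#' @param seed integer seed.
#' @return list of `rf_image` objects.
#' @export
simulate_phantom_batch <- function(n, shape = c(256, 256), density = 0.08,
                                   pulse = pulse_spec(),
                                   contrast_levels = c(1, 0.25, 2, 4),
                                   seed) {
  if (missing(seed)) stop("a seed is required")
  lapply(seq_len(n), function(i) {
    si <- seed + i - 1L
    set.seed(si)
    n_inc <- sample(1:3, 1)
    specs <- vector("list", n_inc)
    levels <- c(contrast_levels[1], numeric(n_inc))
    for (k in seq_len(n_inc)) {
      levels[k + 1] <- sample(contrast_levels[-1], 1)
      if (stats::runif(1) < 0.5) {
        h <- sample(round(shape[1] / 8):round(shape[1] / 3), 1)
        w <- sample(round(shape[2] / 8):round(shape[2] / 3), 1)
        r0 <- sample(1:(shape[1] - h), 1); c0 <- sample(1:(shape[2] - w), 1)
        specs[[k]] <- list(type = "rect", r0 = r0, c0 = c0, r1 = r0 + h, c1 = c0 + w)
      } else {
        rad <- sample(round(min(shape) / 10):round(min(shape) / 4), 1)
        ctr <- c(sample((rad + 1):(shape[1] - rad), 1),
                 sample((rad + 1):(shape[2] - rad), 1))
        specs[[k]] <- list(type = "circle", center = ctr, radius = rad)
      }
    }
    f <- make_scatterer_field(shape, density = density,
                              contrast_levels = levels,
                              inclusion_specs = specs, seed = si + 10000L)
    simulate_rf(f, pulse)
  })
}
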