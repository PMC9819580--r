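#' Fractional-bandwidth limitation of RF data
#'
#' Band-pass filters the RF image along the axial (depth) axis, retaining a
#' passband of width `fraction * pulse$passband_width` centred on the pulse
#' centre frequency.  The default realization is a zero-phase FFT brick-wall
#' mask, which makes the fractional-bandwidth definition exact; a zero-phase
#' Butterworth (forward-backward) variant is offered as a dialect.
#'
#' @param rf an `rf_image`.
#' @param fraction retained fraction of the full passband, in (0, 1].
#' @param filter_kind `"brickwall_fft"` (default) or `"butterworth"`.
#' @param order Butterworth order (only for `filter_kind = "butterworth"`).
#' @return an `rf_image` of identical shape.
#' @export
band_limit <- function(rf, fraction, filter_kind = c("brickwall_fft", "butterworth"),
                       order = 4L) {
  stopifnot(inherits(rf, "rf_image"))
  filter_kind <- match.arg(filter_kind)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  fs <- rf$axial_sampling_frequency
  fc <- rf$pulse$center_frequency
  bw <- fraction * rf$pulse$passband_width
  lo <- fc - bw / 2; hi <- fc + bw / 2
  if (hi > fs / 2) stop("reduced passband extends beyond Nyquist")
  x <- rf$samples
  n <- nrow(x)
  if (filter_kind == "brickwall_fft") {
    freqs <- (seq_len(n) - 1) / n * fs
    freqs <- ifelse(freqs > fs / 2, freqs - fs, freqs)   # signed frequencies
    mask <- (abs(freqs) >= lo) & (abs(freqs) <= hi)
    if (!any(mask)) stop("passband collapses below one frequency bin")
    X <- stats::mvfft(x)
    y <- Re(stats::mvfft(X * mask, inverse = TRUE)) / n
  } else {
    wlo <- lo / (fs / 2); whi <- hi / (fs / 2)
    bf <- signal::butter(order, c(wlo, whi), type = "pass")
    y <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  }
  structure(list(samples = y, axial_sampling_frequency = fs, pulse = rf$pulse),
            class = "rf_image")
}

## Analytic signal (axial axis) via the frequency-domain Hilbert construction.
analytic_axial <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Envelope detection
#'
#' Magnitude of the axial analytic signal: removes the carrier oscillation,
#' leaving the echo amplitude.
#'
#' @param rf an `rf_image` (or a plain matrix).
#' @return matrix of non-negative envelope amplitudes.
#' @export
envelope <- function(rf) {
  x <- if (inherits(rf, "rf_image")) rf$samples else rf
  Mod(analytic_axial(x))
}

#' B-mode formation: envelope detection, log compression, normalization
#'
#' The envelope is log-compressed as `20*log10(env / ref)`, clipped to
#' `[-dynamic_range_db, 0]` and affinely mapped to `[0, 1]`.  By default the
#' reference is the envelope maximum of the image itself; pass `ref` to put
#' several images (e.g. a band-limited/full-bandwidth pair) on one intensity
#' scale.
#'
#' @param rf an `rf_image`.
#' @param dynamic_range_db displayed dynamic range in dB (default 60).
#' @param ref normalization reference amplitude; default `max(envelope)`.
#' @param provenance tag describing how the image was produced.
#' @return object of class `bmode_image`: list with `pixels` in `[0,1]`,
#'   `dynamic_range_db`, `provenance`.
#' @export
to_bmode <- function(rf, dynamic_range_db = 60, ref = NULL,
                     provenance = "full_bandwidth") {
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be positive")
  env <- envelope(rf)
  if (all(env == 0)) stop("all-zero RF image: normalization undefined")
  if (is.null(ref)) ref <- max(env)
  db <- 20 * log10(pmax(env, .Machine$double.xmin) / ref)
  db <- pmin(pmax(db, -dynamic_range_db), 0)
  px <- (db + dynamic_range_db) / dynamic_range_db
  structure(list(pixels = px, dynamic_range_db = dynamic_range_db,
                 provenance = provenance),
            class = "bmode_image")
}

#' Paired band-limited / full-bandwidth B-mode images
#'
#' Forms the training pair for one RF frame: the input is the band-limited
#' reconstruction, the target the full-bandwidth one.  Both are normalized
#' by the full-bandwidth envelope maximum so the pair shares one intensity
#' scale (required for RMSE/PSNR comparability).
#'
#' @param rf an `rf_image`.
#' @inheritParams band_limit
#' @inheritParams to_bmode
#' @return list with elements `input` and `target`, both `bmode_image`s.
#' @export
make_pair <- function(rf, fraction, dynamic_range_db = 60,
                      filter_kind = "brickwall_fft") {
  ref <- max(envelope(rf))
  bl <- band_limit(rf, fraction, filter_kind)
  list(input = to_bmode(bl, dynamic_range_db, ref = ref,
                        provenance = sprintf("band_limited(%.2f)", fraction)),
       target = to_bmode(rf, dynamic_range_db, ref = ref,
                         provenance = "full_bandwidth"))
}

#' Build a paired dataset from a list of RF images
#'
#' @param rf_list list of `rf_image` objects.
#' @inheritParams make_pair
#' @return object of class `paired_dataset`: list with `input`, `target`
#'   (arrays H x W x N), `fraction`, `dynamic_range_db`.
#' @export
make_paired_dataset <- function(rf_list, fraction, dynamic_range_db = 60) {
  pairs <- lapply(rf_list, make_pair, fraction = fraction,
                  dynamic_range_db = dynamic_range_db)
  d <- dim(pairs[[1]]$input$pixels)
  inp <- array(0, c(d, length(pairs)))
  tgt <- array(0, c(d, length(pairs)))
  for (i in seq_along(pairs)) {
    inp[, , i] <- pairs[[i]]$input$pixels
    tgt[, , i] <- pairs[[i]]$target$pixels
  }
  structure(list(input = inp, target = tgt, fraction = fraction,
                 dynamic_range_db = dynamic_range_db),
            class = "paired_dataset")
}
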