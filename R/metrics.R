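#' Root-mean-square error between two images
#'
#' @param y_model image produced by a method (matrix or `bmode_image`).
#' @param y_fb full-bandwidth reference image.
#' @return non-negative scalar.
#' @export
rmse <- function(y_model, y_fb) {
  a <- as_pixels(y_model); b <- as_pixels(y_fb)
  check_same_shape(a, b)
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10*log10(Imax^2 / MSE)` where `Imax` is the maximum pixel of the
#' full-bandwidth reference (not of the model output): PSNR is therefore not
#' symmetric in its arguments.
#'
#' @inheritParams rmse
#' @return PSNR in dB; `Inf` when the images are identical (excluded from
#'   aggregates by [evaluate_dataset()] with a warning).
#' @export
psnr <- function(y_model, y_fb) {
  a <- as_pixels(y_model); b <- as_pixels(y_fb)
  check_same_shape(a, b)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  imax <- max(b)
  10 * log10(imax^2 / mse)
}

#' Pearson correlation of Fourier amplitude spectra
#'
#' Measures how much of the reference's spatial-frequency content a
#' reconstruction recovers: both images are transformed with an (unshifted,
#' unwindowed) 2-D DFT, the amplitude spectra are flattened and their
#' Pearson correlation returned.
#'
#' @inheritParams rmse
#' @param axis `"2d"` (default) correlates full 2-D spectra; `"axial"`
#'   correlates the mean 1-D axial (column-wise) amplitude spectra.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_freq_corr <- function(y_model, y_fb, axis = c("2d", "axial")) {
  axis <- match.arg(axis)
  a <- as_pixels(y_model); b <- as_pixels(y_fb)
  check_same_shape(a, b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant image: spectral correlation undefined")
  amp <- function(x) {
    if (axis == "2d") as.vector(Mod(stats::fft(x)))
    else rowMeans(Mod(stats::mvfft(x)))
  }
  sa <- amp(a); sb <- amp(b)
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0)
    stop("constant image: amplitude spectrum has zero variance")
  stats::cor(sb, sa)
}

#' Signed error map
#'
#' @inheritParams rmse
#' @return list with `map` (elementwise `y_model - y_fb`) and `range`.
#' @export
error_map <- function(y_model, y_fb) {
  a <- as_pixels(y_model); b <- as_pixels(y_fb)
  check_same_shape(a, b)
  m <- a - b
  list(map = m, range = range(m))
}

#' Mean 1-D axial amplitude spectrum of an image
#'
#' Companion diagnostic for frequency-domain comparisons.
#' @param img matrix or `bmode_image`.
#' @return data.frame with `frequency_bin` and `amplitude`.
#' @export
amplitude_spectrum <- function(img) {
  x <- as_pixels(img)
  data.frame(frequency_bin = seq_len(nrow(x)) - 1L,
             amplitude = rowMeans(Mod(stats::mvfft(x))))
}

#' Evaluate enhancement methods on a paired dataset
#'
#' Computes RMSE, PSNR and the spectral Pearson correlation per image and
#' method, plus the untouched band-limited input as its own row
#' (`"band_limited"`), and aggregates mean +/- sd per method.
#'
#' @param pairs a `paired_dataset`.
#' @param methods named list of functions `f(matrix) -> matrix`, each mapping
#'   a band-limited image to an enhanced image.  May be empty.
#' @return object of class `metric_report`: list with `per_image`
#'   (data.frame: image, method, rmse, psnr_db, pc) and `aggregate`
#'   (data.frame: method, metric means and sds).
#' @export
evaluate_dataset <- function(pairs, methods = list()) {
  stopifnot(inherits(pairs, "paired_dataset"))
  n <- dim(pairs$input)[3]
  if (is.null(n) || n < 1) stop("empty dataset")
  all_methods <- c(list(band_limited = identity), methods)
  rows <- list()
  for (i in seq_len(n)) {
    x <- pairs$input[, , i]; y <- pairs$target[, , i]
    for (m in names(all_methods)) {
      z <- all_methods[[m]](x)
      rows[[length(rows) + 1]] <- data.frame(
        image = i, method = m,
        rmse = rmse(z, y), psnr_db = psnr(z, y),
        pc = pearson_freq_corr(z, y))
    }
  }
  per_image <- do.call(rbind, rows)
  if (any(!is.finite(per_image$psnr_db)))
    warning("infinite PSNR (identical images) excluded from aggregates")
  agg <- do.call(rbind, lapply(split(per_image, per_image$method), function(d) {
    fin <- is.finite(d$psnr_db)
    data.frame(method = d$method[1],
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               psnr_mean = mean(d$psnr_db[fin]), psnr_sd = stats::sd(d$psnr_db[fin]),
               pc_mean = mean(d$pc), pc_sd = stats::sd(d$pc))
  }))
  rownames(agg) <- NULL
  structure(list(per_image = per_image, aggregate = agg,
                 n_pixels = prod(dim(pairs$input)[1:2])),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report over", length(unique(x$per_image$image)), "image pair(s)\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-14s RMSE %.3f +/- %.3f  PSNR %6.3f +/- %.3f dB  PC %.3f +/- %.3f\n",
                a$method[i], a$rmse_mean[i], a$rmse_sd[i],
                a$psnr_mean[i], a$psnr_sd[i], a$pc_mean[i], a$pc_sd[i]))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "bmode_image")) x$pixels else as.matrix(x)
}
check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("image shapes differ")
  invisible(TRUE)
}
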