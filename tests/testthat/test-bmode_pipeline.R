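test_that("fraction-1 brickwall filtering is the identity on in-band signals", {
  rf <- tiny_rf(c(128, 16), seed = 7)
  out <- band_limit(rf, 1.0)
  ## the simulated RF has (Gaussian) tails slightly outside the passband, so
  ## compare after one filtering: filtering twice equals filtering once
  out2 <- band_limit(out, 1.0)
  expect_lt(max(abs(out2$samples - out$samples)) / max(abs(out$samples)), 1e-10)
})

test_that("brickwall band-limiting suppresses out-of-band energy", {
  set.seed(8)
  pulse <- pulse_spec()
  rf <- structure(list(samples = matrix(rnorm(512 * 8), 512, 8),
                       axial_sampling_frequency = pulse$axial_sampling_frequency,
                       pulse = pulse), class = "rf_image")
  bl <- band_limit(rf, 0.2)
  n <- 512; fs <- pulse$axial_sampling_frequency
  freqs <- (seq_len(n) - 1) / n * fs
  freqs <- ifelse(freqs > fs / 2, freqs - fs, freqs)
  spec <- Mod(stats::mvfft(bl$samples))^2
  bw <- 0.2 * pulse$passband_width
  inband <- abs(abs(freqs) - pulse$center_frequency) <= bw / 2
  out_of_band_max <- max(spec[!inband, ])
  in_band_mean <- mean(spec[inband, ])
  expect_lt(out_of_band_max / in_band_mean, 1e-10)

  ## retained width: fraction x 3.04 MHz = 0.608 MHz worth of bins
  kept_bins <- sum(inband & freqs > 0)
  bin <- fs / n
  expect_equal(kept_bins * bin, 0.608e6, tolerance = 2 * bin / 0.608e6)
})

test_that("band_limit validates fraction and passband", {
  rf <- tiny_rf(c(64, 16))
  expect_error(band_limit(rf, 0), "fraction")
  expect_error(band_limit(rf, 1.5), "fraction")
  pulse <- pulse_spec()
  rf2 <- structure(list(samples = matrix(rnorm(32), 8, 4),
                        axial_sampling_frequency = pulse$axial_sampling_frequency,
                        pulse = pulse), class = "rf_image")
  expect_error(band_limit(rf2, 0.001), "below one frequency bin|collapses")
})

test_that("butterworth dialect concentrates energy like the brickwall", {
  rf <- tiny_rf(c(256, 16), seed = 12)
  bb <- band_limit(rf, 0.4, "brickwall_fft")
  bw <- band_limit(rf, 0.4, "butterworth")
  ## same image structure: high correlation between the two filtrations
  expect_gt(cor(as.vector(bb$samples), as.vector(bw$samples)), 0.9)
})

test_that("envelope of a pure sinusoid is its amplitude", {
  ## carrier at exactly fs/4 so the finite record holds whole periods and
  ## boundary ripple vanishes
  fs <- pulse_spec()$axial_sampling_frequency
  pulse <- pulse_spec(center_frequency = fs / 4)
  t <- (0:511) / fs
  A <- 0.7
  rf <- structure(list(samples = matrix(A * cos(2 * pi * pulse$center_frequency * t),
                                        ncol = 1),
                       axial_sampling_frequency = fs, pulse = pulse),
                  class = "rf_image")
  env <- envelope(rf)
  core <- env[50:462, 1]          # away from boundaries
  expect_lt(max(abs(core - A)) / A, 1e-3)
  bm <- to_bmode(rf)
  expect_equal(max(bm$pixels), 1.0)
  expect_gte(min(bm$pixels), 0)
})

test_that("envelope of a Gabor pulse recovers its Gaussian modulation", {
  pulse <- pulse_spec()
  fs <- pulse$axial_sampling_frequency
  st <- usbwx:::pulse_sigma_t(pulse)
  t <- ((0:511) - 256) / fs
  gauss <- exp(-t^2 / (2 * st^2))
  rf <- structure(list(samples = matrix(cos(2 * pi * pulse$center_frequency * t) * gauss,
                                        ncol = 1),
                       axial_sampling_frequency = fs, pulse = pulse),
                  class = "rf_image")
  env <- envelope(rf)[, 1]
  sel <- gauss > 0.5              # the peak half
  expect_lt(max(abs(env[sel] - gauss[sel]) / gauss[sel]), 0.01)
})

test_that("to_bmode contract: [0,1] range, max exactly 1, monotone mapping", {
  rf <- tiny_rf(c(128, 32), seed = 31)
  bm <- to_bmode(rf, 60)
  expect_equal(max(bm$pixels), 1.0)
  expect_gte(min(bm$pixels), 0)
  ## log compression preserves envelope ordering above the clip floor
  env <- envelope(rf)
  keep <- bm$pixels > 0 & bm$pixels < 1
  o <- order(env[keep])
  expect_true(all(diff(bm$pixels[keep][o]) >= 0))
  expect_error(to_bmode(structure(list(samples = matrix(0, 8, 4),
                                       axial_sampling_frequency = 1,
                                       pulse = NULL), class = "rf_image")),
               "all-zero")
})

test_that("pairs share a scale; degenerate fraction gives near-equal pair", {
  rf <- tiny_rf(c(128, 64), seed = 17)
  pr <- make_pair(rf, 1.0)
  pr2 <- make_pair(rf, 0.2)
  ## fraction 1 removes only the Gaussian tails beyond the -6 dB passband:
  ## far smaller residual than a true 20% limitation, but not zero
  expect_gt(rmse(pr2$input, pr2$target), 0)
  expect_lt(rmse(pr$input, pr$target), 0.5 * rmse(pr2$input, pr2$target))
})

test_that("pair RMSE decreases strictly as the retained fraction grows", {
  ## the ordering of the band-limited rows across 20/40/60% bandwidth
  rms <- sapply(1:10, function(i) {
    rf <- tiny_rf(c(128, 64), seed = 100 + i)
    sapply(c(0.2, 0.4, 0.6), function(f) {
      p <- make_pair(rf, f)
      rmse(p$input, p$target)
    })
  })
  m <- rowMeans(rms)
  expect_true(m[1] > m[2] && m[2] > m[3])
})
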