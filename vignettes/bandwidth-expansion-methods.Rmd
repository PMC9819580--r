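---
title: "Bandwidth expansion for B-mode ultrasound: models, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bandwidth expansion for B-mode ultrasound: models, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A B-mode image is formed from radio-frequency (RF) echo data: the received
signal oscillates at the transducer's centre frequency, and its *temporal
bandwidth* — the width of the spectral band the transducer can transmit and
receive — bounds the axial resolution of the final image. Band-limiting the
RF spectrum to a fraction of the available passband (here 20%, 40% or 60%)
produces the familiar degradation of cheap or narrow-band probes: axially
stretched speckle, smeared interfaces, lost detail.

`usbwx` treats recovery from that degradation as a supervised
image-restoration problem. Because both members of a training pair can be
computed from the *same* RF frame — once band-limited, once at full
bandwidth — ground truth is available by construction, and a convolutional
network can be trained to map one onto the other.

## The simulation model and what it does (not) capture

Real paired data in this problem comes from plane-wave acquisitions of
physical phantoms. The package instead generates fully developed speckle
with a standard convolution model: a sparse random reflectivity map is
convolved with a separable point-spread function,

* axially a cosine carrier at `center_frequency` under a Gaussian envelope
  whose −6 dB spectral full width equals `passband_width` (default
  3.04 MHz, the full passband the pipeline later fractions),
* laterally a Gaussian beam profile (`lateral_beamwidth` pixels).

Scatterer amplitudes are drawn uniformly on [−1, 1] (zero mean), so the
envelope in the dense-scatterer limit is Rayleigh distributed — the
statistical regime the speckle metrics assume. Inclusions (rectangles and
disks) multiply regional amplitudes by configurable echogenicity contrasts,
emulating stiff/scattering inserts of different scatterer concentrations.

Defaults worth knowing: the full-scale default image is 801×401 pixels; the
tests and the acceptance run use 256×256 for time. The default centre frequency
(7.8 MHz) and axial sampling rate (31.25 MHz) are plausible for a 5–11 MHz
linear array but are *placeholders*, not measured values; every pulse
parameter is configurable. Scatterer density defaults to 0.08 per pixel —
dense enough for fully developed speckle at the default pulse size.

What the simulator deliberately omits: wave propagation and beamforming
(no per-angle plane-wave compounding), attenuation and time-gain
compensation, grating lobes, and any tissue-specific structure. Passing
tests on synthetic data therefore demonstrates that the pipeline,
networks, and metrics behave as specified on speckle with the right
first-order statistics — not that a network trained here transfers to
in-vivo data.

## Image formation

`band_limit()` filters the RF image along the axial axis only. The default
realization is a zero-phase FFT brick-wall mask retaining
`fraction × passband_width` centred on the carrier — chosen because it makes
the fractional-bandwidth definition exact and testable (idempotence,
out-of-band suppression below 1e-10). A forward–backward Butterworth is
available as a dialect for users who prefer smooth transition bands.
Fractional bandwidth is defined relative to the full *passband width*, not
the centre frequency.

`to_bmode()` computes the magnitude of the axial analytic signal, log
compresses as `20·log10(env/ref)`, clips to a 60 dB dynamic range (display
convention; configurable) and maps affinely to [0, 1]. Within a pair, both
members are normalized by the full-bandwidth envelope maximum so they share
one intensity scale — required for RMSE and PSNR to be comparable across
methods. Whether per-pair or per-dataset normalization is the better
convention is genuinely open; per-pair is the package default and is
recorded in every run config.

## The three networks

Parameter counts are computed by exact summation over layers and are the
package's architectural ground truth:

| model | total | trainable | non-trainable |
|---|---|---|---|
| `srcnn` | 85,889 | 85,889 | 0 |
| `unet` | 2,164,433 | 2,161,489 | 2,944 |
| `rednet` | 65,633 | 65,313 | 320 |

* **SRCNN** is the 9-3-5 kernel variant with 128-64-1 filters (the
  canonical 9-5-5 / 64-32-1 network, 57,281 parameters, ships as
  `srcnn_classic` for reference).
* **U-Net** uses base 16 filters, four pooling levels, two 3×3
  convolutions + batch normalization per block, 3×3 stride-2 transposed
  convolutions and a 3×3 output convolution. The 2,944 non-trainable
  parameters are exactly the batch-norm moving statistics. The sigmoid
  usually found at a U-Net output is replaced by ReLU: the target is an
  unbounded-above intensity map, not a probability.
* **REDNet** is the package's primary model: a frozen bank of 32 oriented
  Sobel kernels (3×3 rotations of the classic gradient pair — 320
  parameters that never train) is concatenated with the input; seven
  32-filter 3×3 convolutions with dilation schedule 1-2-3-4-3-2-1 widen the
  receptive field without extra parameters; dropout 0.05 follows each
  dilated stage; a final 3×3 convolution predicts a residual that is added
  to the input before the output ReLU. The residual form means an untrained
  REDNet is the identity map — training can only move it away from the
  band-limited input in the direction the loss rewards, which also makes
  short desk-scale runs meaningful.

The layer widths live in `model_spec()` as data, not constants, so any
width schedule can be substituted and the parameter accounting re-examined
layer by layer.

All forward/backward passes (im2col + GEMM convolutions, transposed
convolutions as zero-stuffed convolutions, max pooling, batch normalization,
dropout) and the Adam optimizer are implemented in the package and verified
against finite-difference gradients in the test suite.

## Losses

**PL1** is `τ·MSE` with τ = 1000 by default. τ is a free scaling
parameter: its role is to keep early-training gradients of [0, 1]-valued
images well above float underflow (the vanishing-gradient motivation), and
under Adam — which normalizes updates by gradient magnitude — its exact
value is essentially inconsequential; 1000 simply makes reported losses
O(10) instead of O(0.01).

**PL2** mixes a pixel term and a perceptual term 30:70 (pixel:perceptual;
the textual order of the ratio is ambiguous, so the weights are
configurable). The pixel term defaults to MSE with RMSE available by flag —
both conventions appear in the field. The perceptual term is the mean
squared difference of activations from a *frozen* convolutional feature
extractor. Large pretrained extractors (VGG-style) cannot be bundled, so the
default extractor is a seeded, fixed random-projection convolutional network:
fixed random convolutional features are a recognized basis for perceptual
comparison, and the loss contract (frozen weights, determinism, zero at
identical inputs) is identical. Externally trained weights can be installed
with `load_extractor_weights()`; if no extractor is configured, PL2 errors
loudly rather than silently falling back.

## Training protocol

`extract_patches()` draws 64 random overlapping 128×128 patches per image
(patches are drawn once, not re-drawn per epoch, matching the fixed patch
totals of 64 × images). `train_model()` runs mini-batch Adam (batch 16,
lr 1e-4, β₁ 0.9, β₂ 0.999) for up to 300 epochs, stopping when the
validation loss has not improved for `early_stop_patience` epochs
(default 20, a common convention; the stopping criterion itself is the
stated protocol, the patience value is not) and restoring the
best-validation weights. Epoch shuffling uses a seed derived from the run
seed and epoch index, so runs are exactly reproducible.

## Evaluation

RMSE and PSNR are standard; PSNR takes `Imax` from the full-bandwidth
reference, so it is deliberately asymmetric (asserted in the tests). The
spectral Pearson correlation (PC) measures frequency-content recovery: both
images are 2-D Fourier transformed (unshifted, unwindowed — the simplest
faithful reading; a windowing hook and a 1-D axial variant exist as
options), amplitude spectra are flattened, and their Pearson correlation is
returned. Identical PSNR pairs produce an `Inf` sentinel that is excluded
from aggregates with a warning. Aggregation is arithmetic mean ± sample
standard deviation across test images.

Speckle statistics operate on the *envelope* (pre-log) image: histograms
with shared bin edges and their intersection-overlap; speckle-cell size as
the FWHM of the zero-padded (linear, not circular — circular wrap-around
biases the width) normalized autocorrelation, measured along each axis with
linear interpolation between the bracketing lags; and the ellipse
eccentricity `sqrt(b²−a²)/b` of the two FWHM axes, canonically ordered.
The evaluation region is an explicit user input since no canonical patch
location exists.

## Numerical choices and degenerate inputs

* All-zero RF frames are rejected at B-mode formation (normalization
  undefined); constant images are rejected by the spectral correlation and
  returned unchanged (with a warning) by histogram equalization.
* CLAHE clip-and-redistribute runs a single redistribution pass; the small
  residual excess is tolerated and bounded in the tests. With one tile and
  no clipping CLAHE reduces exactly to global equalization.
* The brick-wall filter errors when the requested passband collapses below
  one FFT bin; the Butterworth dialect errors when its band edges leave
  (0, Nyquist).
* PSNR's `MSE = 0` case yields `+Inf` and is excluded from means.
* Weight initialization is seeded Glorot-uniform; the final convolution of
  residual models starts at zero so training begins from the identity.
* Tiled inference trims half the overlap from interior tile borders, so
  retained pixels see the same receptive field as whole-image inference.

## Problem sizes used by the tests and the acceptance run

The packaged experiments are sized for a single CPU: 50 simulated 256×256
phantoms (40 train / 10 held out), 2,560 training patches of 32×32, three
epochs of REDNet-PL1. Under these conditions the held-out RMSE against the
full-bandwidth target drops by roughly 20–25% relative to the band-limited
input and the spectral correlation rises — the same direction, at smaller
magnitude, as full-scale training. The numbers printed by
`scripts/acceptance.R` are recomputed from scratch on every run; nothing in
the package stores empirical results.

## Known limitations

* The simulator's speckle is stationary within regions; real phantoms add
  depth-dependent attenuation, focusing artifacts and reverberation that
  the networks here never see.
* The default perceptual extractor is untrained; with it, PL2 behaves as a
  structured multi-scale pixel loss rather than a semantics-aware one.
* REDNet's published parameter total could not be reproduced from the
  textual description alone (the non-trainable Sobel share matches
  exactly; the trainable share does not for any conventional width
  schedule). The implemented schedule is the faithful reading of the
  description, and the builder reports its counts so the discrepancy is
  visible rather than absorbed.
* Training at the full 300-epoch, 25,600-patch scale is supported but slow
  in this implementation; the package targets method study, not production
  training throughput.
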