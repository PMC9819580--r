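## Shared fixtures: everything is generated in code under fixed seeds.

tiny_rf <- function(shape = c(96, 48), seed = 42L, density = 0.1,
                    pulse = pulse_spec()) {
  f <- make_scatterer_field(shape, density = density, seed = seed)
  simulate_rf(f, pulse)
}

tiny_pairs <- function(n = 2, shape = c(96, 64), fraction = 0.2, seed = 11L) {
  rfs <- simulate_phantom_batch(n, shape = shape, seed = seed)
  make_paired_dataset(rfs, fraction)
}

## naive O(n^2 k^2) same-padded dilated convolution, independent of the
## compiled path
naive_conv2d <- function(x, W, b, dilation = 1L) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  pad <- ((k - 1) * dilation) %/% 2
  y <- array(0, c(H, Wd, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, Wd)
    for (ci in seq_len(cin)) for (a in seq_len(k)) for (bb in seq_len(k)) {
      oa <- (a - 1) * dilation - pad; ob <- (bb - 1) * dilation - pad
      for (i in seq_len(H)) for (j in seq_len(Wd)) {
        si <- i + oa; sj <- j + ob
        if (si >= 1 && si <= H && sj >= 1 && sj <= Wd)
          acc[i, j] <- acc[i, j] + W[a, bb, ci, co] * x[si, sj, ci]
      }
    }
    y[, , co] <- acc
  }
  y
}

## flatten/unflatten a nested parameter list (for finite differences)
flatten_params <- function(params) {
  unlist(params, use.names = TRUE)
}
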