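brute_rmse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("rmse/psnr/pearson agree with brute-force oracles on random pairs", {
  set.seed(42)
  worst <- 0
  for (rep in 1:100) {
    a <- matrix(runif(256), 16, 16)
    b <- matrix(runif(256), 16, 16)
    worst <- max(worst,
      abs(rmse(a, b) - brute_rmse(as.vector(a), as.vector(b))),
      abs(psnr(a, b) - 10 * log10(max(b)^2 / brute_rmse(as.vector(a), as.vector(b))^2)),
      abs(pearson_freq_corr(a, b) -
            brute_pearson(as.vector(Mod(fft(b))), as.vector(Mod(fft(a))))))
  }
  expect_lt(worst, 1e-10)
})

test_that("metric closed forms", {
  a <- matrix(0, 8, 8); b <- matrix(1, 8, 8)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, b), 1.0)
  ## Imax = 1, RMSE = 0.1 -> 20 dB; RMSE = 0.5 -> ~6.0206 dB
  b1 <- matrix(1, 10, 10)
  a1 <- b1 - 0.1
  expect_equal(psnr(a1, b1), 20, tolerance = 1e-12)
  a2 <- b1 - 0.5
  expect_equal(psnr(a2, b1), 20 * log10(2), tolerance = 1e-12)
  ## algebraic identity psnr = 20 log10(Imax) - 20 log10(rmse)
  set.seed(1)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  expect_equal(psnr(x, y), 20 * log10(max(y)) - 20 * log10(rmse(x, y)),
               tolerance = 1e-10)
})

test_that("rmse is symmetric, psnr is not", {
  set.seed(3)
  a <- matrix(runif(64), 8, 8); b <- matrix(0.5 * runif(64), 8, 8)
  expect_equal(rmse(a, b), rmse(b, a))
  expect_false(isTRUE(all.equal(psnr(a, b), psnr(b, a))))
})

test_that("pearson_freq_corr self- and scale-invariance", {
  set.seed(4)
  a <- matrix(runif(100), 10, 10)
  expect_equal(pearson_freq_corr(a, a), 1.0)
  expect_equal(pearson_freq_corr(2.5 * a, a), 1.0, tolerance = 1e-12)
  expect_error(pearson_freq_corr(matrix(0.5, 10, 10), a), "constant")
})

test_that("error maps report the signed difference and its range", {
  set.seed(5)
  a <- matrix(runif(36), 6, 6)
  em0 <- error_map(a, a)
  expect_true(all(em0$map == 0))
  expect_equal(em0$range, c(0, 0))
  em <- error_map(a + 0.1, a)
  expect_equal(em$map, matrix(0.1, 6, 6), tolerance = 1e-12)
  b <- matrix(runif(36), 6, 6)
  em2 <- error_map(a, b)
  expect_equal(max(abs(em2$range)), max(abs(a - b)))
  expect_error(error_map(a, matrix(0, 3, 3)), "shape")
})

test_that("evaluate_dataset aggregates are recomputable from per-image rows", {
  pairs <- tiny_pairs(n = 3, shape = c(64, 48), seed = 19)
  rep <- evaluate_dataset(pairs, methods = list(he = hist_eq))
  expect_s3_class(rep, "metric_report")
  per <- rep$per_image
  for (m in unique(per$method)) {
    sub <- per[per$method == m, ]
    agg <- rep$aggregate[rep$aggregate$method == m, ]
    expect_equal(agg$rmse_mean, mean(sub$rmse))
    expect_equal(agg$pc_sd, sd(sub$pc))
  }
  ## identity-on-target method: rmse 0, pc 1 (and a warning on infinite PSNR)
  one <- tiny_pairs(n = 1, shape = c(64, 48), seed = 23)
  one$input <- one$target
  expect_warning(rep2 <- evaluate_dataset(one), "PSNR")
  bl <- rep2$per_image[rep2$per_image$method == "band_limited", ]
  expect_equal(bl$rmse, 0)
  expect_equal(bl$pc, 1)
})

test_that("hand-set constant differences average as expected", {
  tgt <- array(runif(32 * 32 * 2), c(32, 32, 2))
  inp <- tgt
  inp[, , 1] <- pmax(tgt[, , 1] - 0.1, 0); tgt[, , 1] <- inp[, , 1] + 0.1
  inp[, , 2] <- pmax(tgt[, , 2] - 0.3, 0); tgt[, , 2] <- inp[, , 2] + 0.3
  pairs <- structure(list(input = inp, target = tgt, fraction = 0.2,
                          dynamic_range_db = 60), class = "paired_dataset")
  rep <- evaluate_dataset(pairs)
  agg <- rep$aggregate[rep$aggregate$method == "band_limited", ]
  expect_equal(agg$rmse_mean, 0.2, tolerance = 1e-12)
})

test_that("fraction sweep: PC rises while RMSE falls (qualitative law)", {
  rf <- tiny_rf(c(128, 64), seed = 201)
  res <- sapply(c(0.2, 0.4, 0.6), function(f) {
    p <- make_pair(rf, f)
    c(rmse(p$input, p$target),
      pearson_freq_corr(p$input$pixels, p$target$pixels))
  })
  expect_true(all(diff(res[1, ]) < 0))   # RMSE decreases
  expect_true(all(diff(res[2, ]) > 0))   # PC increases
})
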