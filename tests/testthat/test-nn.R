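test_that("compiled convolution matches a naive R oracle, incl. dilation", {
  set.seed(1)
  for (dil in c(1L, 2L, 3L)) {
    x <- array(rnorm(9 * 8 * 2 * 2), c(9, 8, 2, 2))
    W <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    b <- rnorm(3)
    y <- usbwx:::.conv2d_fwd(x, dim(x), W, 3L, 2L, 3L, b, dil)
    for (n in 1:2) {
      expect_equal(y[, , , n], naive_conv2d(x[, , , n, drop = TRUE], W, b, dil),
                   tolerance = 1e-12)
    }
  }
})

test_that("conv backward passes a finite-difference check", {
  set.seed(2)
  x <- array(rnorm(6 * 5 * 1 * 2), c(6, 5, 1, 2))
  W <- array(rnorm(3 * 3 * 1 * 2), c(3, 3, 1, 2))
  b <- rnorm(2)
  loss <- function(W, b, x) {
    y <- usbwx:::.conv2d_fwd(x, dim(x), W, 3L, 1L, 2L, b, 1L)
    sum(y^2) / 2
  }
  y <- usbwx:::.conv2d_fwd(x, dim(x), W, 3L, 1L, 2L, b, 1L)
  g <- usbwx:::.conv2d_bwd(x, dim(x), W, 3L, 1L, 2L, y, 1L, TRUE, TRUE)
  eps <- 1e-6
  for (i in sample(length(W), 5)) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    expect_equal(g$dw[i], (loss(Wp, b, x) - loss(Wm, b, x)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in sample(length(x), 5)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(g$dx[i], (loss(W, b, xp) - loss(W, b, xm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("whole-graph backward agrees with finite differences", {
  ## small conv-relu-conv graph with a concat and residual add exercises
  ## every backward rule used by the real models except pooling
  nodes <- list(
    usbwx:::nn_node("in", "input"),
    usbwx:::nn_node("c1", "conv", "in", k = 3, cin = 1, cout = 2),
    usbwx:::nn_node("r1", "relu", "c1"),
    usbwx:::nn_node("cat", "concat", list("r1", "in")),
    usbwx:::nn_node("c2", "conv", "cat", k = 3, cin = 3, cout = 1),
    usbwx:::nn_node("add", "add", list("c2", "in")))
  g <- usbwx:::nn_graph(nodes)
  params <- usbwx:::nn_init(g, seed = 4)
  x <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  lossf <- function(params) {
    out <- usbwx:::nn_forward(g, params, x)$out
    sum(out^2) / 2
  }
  fw <- usbwx:::nn_forward(g, params, x)
  pg <- usbwx:::nn_backward(g, params, fw, fw$out)
  eps <- 1e-6
  for (nd in c("c1", "c2")) {
    for (i in sample(length(params[[nd]]$W), 4)) {
      pp <- params; pp[[nd]]$W[i] <- pp[[nd]]$W[i] + eps
      pm <- params; pm[[nd]]$W[i] <- pm[[nd]]$W[i] - eps
      expect_equal(pg[[nd]]$W[i], (lossf(pp) - lossf(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("batch norm and max pooling backward pass finite differences", {
  nodes <- list(
    usbwx:::nn_node("in", "input"),
    usbwx:::nn_node("c1", "conv", "in", k = 3, cin = 1, cout = 2),
    usbwx:::nn_node("b1", "bn", "c1", channels = 2),
    usbwx:::nn_node("r1", "relu", "b1"),
    usbwx:::nn_node("p1", "maxpool", "r1"),
    usbwx:::nn_node("c2", "conv", "p1", k = 3, cin = 2, cout = 1))
  g <- usbwx:::nn_graph(nodes)
  params <- usbwx:::nn_init(g, seed = 5)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  lossf <- function(params) {
    out <- usbwx:::nn_forward(g, params, x, training = TRUE)$out
    sum(out^2) / 2
  }
  fw <- usbwx:::nn_forward(g, params, x, training = TRUE)
  pg <- usbwx:::nn_backward(g, params, fw, fw$out)
  eps <- 1e-6
  for (slot in c("gamma", "beta")) {
    for (i in 1:2) {
      pp <- params; pp$b1[[slot]][i] <- pp$b1[[slot]][i] + eps
      pm <- params; pm$b1[[slot]][i] <- pm$b1[[slot]][i] - eps
      expect_equal(pg$b1[[slot]][i], (lossf(pp) - lossf(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  for (i in sample(length(params$c1$W), 4)) {
    pp <- params; pp$c1$W[i] <- pp$c1$W[i] + eps
    pm <- params; pm$c1$W[i] <- pm$c1$W[i] - eps
    expect_equal(pg$c1$W[i], (lossf(pp) - lossf(pm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("transposed convolution upsamples by 2 and backprops correctly", {
  nodes <- list(
    usbwx:::nn_node("in", "input"),
    usbwx:::nn_node("t1", "tconv", "in", k = 3, cin = 1, cout = 1))
  g <- usbwx:::nn_graph(nodes)
  params <- usbwx:::nn_init(g, seed = 6)
  x <- array(rnorm(4 * 3), c(4, 3, 1, 1))
  fw <- usbwx:::nn_forward(g, params, x)
  expect_identical(dim(fw$out)[1:2], c(8L, 6L))
  lossf <- function(params) sum(usbwx:::nn_forward(g, params, x)$out^2) / 2
  pg <- usbwx:::nn_backward(g, params, fw, fw$out)
  eps <- 1e-6
  for (i in seq_len(9)) {
    pp <- params; pp$t1$W[i] <- pp$t1$W[i] + eps
    pm <- params; pm$t1$W[i] <- pm$t1$W[i] - eps
    expect_equal(pg$t1$W[i], (lossf(pp) - lossf(pm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})
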