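#' Model specifications
#'
#' Layer widths, kernel sizes and dilation schedules are stored as data in
#' the spec (not hard-coded in the builder) so that parameter accounting is
#' diagnosable layer by layer and widths can be overridden.
#'
#' Available models:
#' \describe{
#'   \item{`srcnn`}{Three-layer super-resolution CNN, kernels 9-3-5 with
#'     128-64-1 filters (85,889 parameters, all trainable).}
#'   \item{`srcnn_classic`}{The canonical 9-5-5 / 64-32-1 variant (57,281
#'     parameters), provided for reference.}
#'   \item{`unet`}{Encoder-decoder with skip concatenations: base 16
#'     filters, 4 pooling levels, two 3x3 conv + batch-norm layers per
#'     block, 3x3 stride-2 transposed convs, final 3x3 conv; ReLU (not
#'     sigmoid) output. 2,164,433 parameters of which 2,944 (batch-norm
#'     moving statistics) are non-trainable.}
#'   \item{`rednet`}{Residual encoder-decoder: a frozen bank of 32 oriented
#'     Sobel edge kernels concatenated with the input, seven 32-filter 3x3
#'     dilated convolutions (schedule 1-2-3-4-3-2-1) with 0.05 dropout, a
#'     3x3 conv to one channel, residual addition of the input, ReLU.
#'     65,633 parameters of which 320 (the Sobel bank) are non-trainable.}
#' }
#'
#' @param name one of `"srcnn"`, `"srcnn_classic"`, `"unet"`, `"rednet"`.
#' @param ... overrides: `filters_per_layer`, `kernel_sizes`,
#'   `dilation_rates`, `dropout_rate`, `base_filters`, `depth`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name = c("srcnn", "srcnn_classic", "unet", "rednet"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    srcnn = list(filters_per_layer = c(128, 64, 1), kernel_sizes = c(9, 3, 5)),
    srcnn_classic = list(filters_per_layer = c(64, 32, 1), kernel_sizes = c(9, 5, 5)),
    unet = list(base_filters = 16, depth = 4, up_kernel = 3, final_kernel = 3),
    rednet = list(filters_per_layer = rep(32, 7), kernel_sizes = rep(3, 7),
                  dilation_rates = c(1, 2, 3, 4, 3, 2, 1),
                  dropout_rate = 0.05, n_sobel = 32))
  over <- list(...)
  spec[names(over)] <- over
  structure(c(list(name = name, final_activation = "relu"), spec),
            class = "model_spec")
}

## Bank of oriented Sobel kernels: rotations of the classic x/y pair.
sobel_bank <- function(n = 32) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/d(row)
  sy <- t(sx)
  W <- array(0, c(3, 3, 1, n))
  th <- (seq_len(n) - 1) * 2 * pi / n
  for (i in seq_len(n)) W[, , 1, i] <- cos(th[i]) * sx + sin(th[i]) * sy
  W
}

graph_srcnn <- function(ks, fs) {
  cin <- c(1, fs[-length(fs)])
  nodes <- list(nn_node("in", "input"))
  prev <- "in"
  for (i in seq_along(fs)) {
    cv <- paste0("conv", i)
    nodes <- c(nodes, list(
      nn_node(cv, "conv", prev, k = ks[i], cin = cin[i], cout = fs[i]),
      nn_node(paste0("relu", i), "relu", cv)))
    prev <- paste0("relu", i)
  }
  nn_graph(nodes)
}

graph_unet <- function(base = 16, depth = 4, up_kernel = 3, final_kernel = 3) {
  nodes <- list(nn_node("in", "input"))
  prev <- "in"; cin <- 1
  fs <- base * 2^(seq_len(depth) - 1)
  skips <- character(depth)
  cblock <- function(nm, prev, cin, f) {
    list(nn_node(paste0(nm, "_c1"), "conv", prev, k = 3, cin = cin, cout = f),
         nn_node(paste0(nm, "_bn1"), "bn", paste0(nm, "_c1"), channels = f),
         nn_node(paste0(nm, "_r1"), "relu", paste0(nm, "_bn1")),
         nn_node(paste0(nm, "_c2"), "conv", paste0(nm, "_r1"), k = 3, cin = f, cout = f),
         nn_node(paste0(nm, "_bn2"), "bn", paste0(nm, "_c2"), channels = f),
         nn_node(paste0(nm, "_r2"), "relu", paste0(nm, "_bn2")))
  }
  for (i in seq_len(depth)) {
    nm <- paste0("enc", i)
    nodes <- c(nodes, cblock(nm, prev, cin, fs[i]))
    skips[i] <- paste0(nm, "_r2")
    nodes <- c(nodes, list(nn_node(paste0("pool", i), "maxpool", skips[i])))
    prev <- paste0("pool", i); cin <- fs[i]
  }
  fb <- base * 2^depth
  nodes <- c(nodes, cblock("bott", prev, cin, fb))
  prev <- "bott_r2"; cin <- fb
  for (i in rev(seq_len(depth))) {
    nm <- paste0("dec", i)
    up <- paste0(nm, "_up")
    nodes <- c(nodes, list(
      nn_node(up, "tconv", prev, k = up_kernel, cin = cin, cout = fs[i]),
      nn_node(paste0(nm, "_cat"), "concat", list(up, skips[i]))))
    nodes <- c(nodes, cblock(nm, paste0(nm, "_cat"), 2 * fs[i], fs[i]))
    prev <- paste0(nm, "_r2"); cin <- fs[i]
  }
  nodes <- c(nodes, list(
    nn_node("out_conv", "conv", prev, k = final_kernel, cin = cin, cout = 1),
    nn_node("out_relu", "relu", "out_conv")))
  nn_graph(nodes)
}

graph_rednet <- function(fs, ks, dil, dropout_rate = 0.05, n_sobel = 32) {
  nodes <- list(
    nn_node("in", "input"),
    nn_node("sobel", "conv", "in", k = 3, cin = 1, cout = n_sobel,
            trainable = FALSE, weights = sobel_bank(n_sobel)),
    nn_node("cat0", "concat", list("in", "sobel")))
  prev <- "cat0"; cin <- 1 + n_sobel
  for (i in seq_along(fs)) {
    cv <- paste0("dconv", i)
    nodes <- c(nodes, list(
      nn_node(cv, "conv", prev, k = ks[i], cin = cin, cout = fs[i],
              dilation = dil[i]),
      nn_node(paste0("relu", i), "relu", cv),
      nn_node(paste0("drop", i), "dropout", paste0("relu", i), rate = dropout_rate)))
    prev <- paste0("drop", i); cin <- fs[i]
  }
  nodes <- c(nodes, list(
    nn_node("out_conv", "conv", prev, k = 3, cin = cin, cout = 1),
    nn_node("res_add", "add", list("out_conv", "in")),
    nn_node("out_relu", "relu", "res_add")))
  nn_graph(nodes)
}

#' Build a model
#'
#' Constructs the network graph, initializes parameters (Glorot-uniform,
#' seeded; the last convolution of residual models starts at zero so the
#' untrained network is the identity) and reports exact parameter counts by
#' summation over layers.
#'
#' @param spec a `model_spec` (or a model name string).
#' @param patch_size training patch edge length; for U-Net it must be
#'   divisible by `2^depth` (the total downsampling factor).
#' @param seed seed for weight initialization.
#' @return object of class `us_model`: list with `spec`, `graph`, `params`,
#'   `param_counts` (total, trainable, non_trainable), `patch_size`.
#' @examples
#' m <- build_model("srcnn", 128)
#' m$param_counts$total   # 85889
#' @export
build_model <- function(spec, patch_size = 128L, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  graph <- switch(spec$name,
    srcnn = ,
    srcnn_classic = graph_srcnn(spec$kernel_sizes, spec$filters_per_layer),
    unet = {
      ds <- 2^spec$depth
      if (patch_size %% ds != 0)
        stop("patch_size must be divisible by the U-Net downsampling factor ", ds)
      graph_unet(spec$base_filters, spec$depth, spec$up_kernel, spec$final_kernel)
    },
    rednet = graph_rednet(spec$filters_per_layer, spec$kernel_sizes,
                          spec$dilation_rates, spec$dropout_rate, spec$n_sobel))
  params <- nn_init(graph, seed = seed,
                    final_zero = spec$name %in% c("rednet"))
  structure(list(spec = spec, graph = graph, params = params,
                 param_counts = nn_count_params(graph),
                 patch_size = as.integer(patch_size)),
            class = "us_model")
}

#' @export
print.us_model <- function(x, ...) {
  pc <- x$param_counts
  cat(sprintf("%s: %s total parameters (%s trainable, %s non-trainable)\n",
              x$spec$name, format(pc$total, big.mark = ","),
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  invisible(x)
}

## pad a matrix by edge replication to a multiple of m in both dims
pad_to_multiple <- function(x, m) {
  H <- nrow(x); W <- ncol(x)
  Hp <- ceiling(H / m) * m; Wp <- ceiling(W / m) * m
  if (Hp > H) x <- rbind(x, x[rep(H, Hp - H), , drop = FALSE])
  if (Wp > W) x <- cbind(x, x[, rep(W, Wp - W), drop = FALSE])
  x
}

#' Run a model on an image
#'
#' Inference wrapper: the networks are fully convolutional, so an image of
#' any size can be processed whole (`tiling = "none"`, the default) or by
#' overlapping tiles whose predictions are averaged on the seams
#' (`tiling = "overlap"`), which bounds memory on large images.  For U-Net
#' the image is edge-padded to a multiple of its downsampling factor and
#' cropped back.
#'
#' @param object a `us_model`.
#' @param image matrix in `[0,1]` or a `bmode_image`.
#' @param tiling `"none"` or `"overlap"`.
#' @param tile_size,overlap tile geometry for `tiling = "overlap"`.
#' @param ... unused.
#' @return matrix of the same shape; all values >= 0 (final ReLU).
#' @export
predict.us_model <- function(object, image, tiling = c("none", "overlap"),
                             tile_size = 128L, overlap = 32L, ...) {
  tiling <- match.arg(tiling)
  x <- as_pixels(image)
  H <- nrow(x); W <- ncol(x)
  ds <- if (object$spec$name == "unet") 2^object$spec$depth else 1L
  if (min(H, W) < 3) stop("image smaller than the network's receptive support")
  run <- function(m) {
    mp <- pad_to_multiple(m, ds)
    xb <- array(mp, c(nrow(mp), ncol(mp), 1, 1))
    y <- nn_forward(object$graph, object$params, xb, training = FALSE)$out
    matrix(y[, , 1, 1], nrow(mp), ncol(mp))[seq_len(nrow(m)), seq_len(ncol(m))]
  }
  if (tiling == "none") return(run(x))
  ## a margin of half the overlap is trimmed from interior tile borders so
  ## retained pixels see the same receptive field as whole-image inference
  step <- tile_size - overlap
  margin <- overlap %/% 2L
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  r0s <- unique(pmin(seq(1, max(H - tile_size + 1, 1), step), max(H - tile_size + 1, 1)))
  c0s <- unique(pmin(seq(1, max(W - tile_size + 1, 1), step), max(W - tile_size + 1, 1)))
  for (r0 in r0s) for (c0 in c0s) {
    r1 <- min(r0 + tile_size - 1, H); c1 <- min(c0 + tile_size - 1, W)
    yt <- run(x[r0:r1, c0:c1, drop = FALSE])
    vr0 <- if (r0 > 1) r0 + margin else r0
    vr1 <- if (r1 < H) r1 - margin else r1
    vc0 <- if (c0 > 1) c0 + margin else c0
    vc1 <- if (c1 < W) c1 - margin else c1
    if (vr0 > vr1 || vc0 > vc1) next
    lr <- (vr0:vr1) - r0 + 1; lc <- (vc0:vc1) - c0 + 1
    acc[vr0:vr1, vc0:vc1] <- acc[vr0:vr1, vc0:vc1] + yt[lr, lc]
    wt[vr0:vr1, vc0:vc1] <- wt[vr0:vr1, vc0:vc1] + 1
  }
  if (any(wt == 0)) stop("tiling left uncovered pixels; increase overlap")
  acc / wt
}

#' Enhance every image of a paired dataset with a trained model
#'
#' @param model a `us_model`.
#' @param pairs a `paired_dataset`.
#' @return array of enhanced images, same shape as `pairs$input`.
#' @export
enhance_dataset <- function(model, pairs) {
  out <- pairs$input
  for (i in seq_len(dim(out)[3]))
    out[, , i] <- predict(model, pairs$input[, , i])
  out
}
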