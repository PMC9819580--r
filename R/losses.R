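#' Loss configuration
#'
#' Two training losses are provided.  PL1 is a scaled mean-square error
#' `tau * MSE`, the scaling keeping early-training gradients well away from
#' float underflow on `[0,1]` images (the vanishing-gradient motivation).
#' PL2 mixes a pixel term with a perceptual term computed from the
#' activations of a frozen convolutional feature extractor, in a 30:70
#' pixel:perceptual ratio by default.
#'
#' @param kind `"pl1"` or `"pl2"`.
#' @param tau positive scaling factor for PL1 (default 1000).
#' @param mix_weights `c(w_pixel, w_perceptual)`, non-negative, summing to 1
#'   (PL2; default `c(0.3, 0.7)`).
#' @param pixel_term `"mse"` (default) or `"rmse"` for PL2's pixel part.
#' @param feature_extractor a frozen extractor from
#'   [perceptual_extractor()]; built on first use when `NULL`.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(kind = c("pl1", "pl2"), tau = 1000,
                        mix_weights = c(0.3, 0.7),
                        pixel_term = c("mse", "rmse"),
                        feature_extractor = NULL) {
  kind <- match.arg(kind)
  pixel_term <- match.arg(pixel_term)
  if (tau <= 0) stop("tau must be positive")
  if (length(mix_weights) != 2 || any(mix_weights < 0) ||
      abs(sum(mix_weights) - 1) > 1e-8)
    stop("mix_weights must be two non-negative numbers summing to 1")
  structure(list(kind = kind, tau = tau, mix_weights = mix_weights,
                 pixel_term = pixel_term, feature_extractor = feature_extractor),
            class = "loss_config")
}

#' Scaled mean-square-error loss (PL1)
#'
#' `L = tau * mean((y_model - y_fb)^2)`, the mean taken over every element
#' of the batch.
#'
#' @param y_model,y_fb arrays of identical shape.
#' @param tau positive scaling factor.
#' @return non-negative scalar.
#' @export
pl1_loss <- function(y_model, y_fb, tau = 1000) {
  if (!identical(dim(y_model), dim(y_fb)) ||
      length(y_model) != length(y_fb)) stop("shape mismatch")
  tau * mean((y_model - y_fb)^2)
}

pl1_grad <- function(y_model, y_fb, tau = 1000) {
  array(2 * tau * (y_model - y_fb) / length(y_model), dim(y_model))
}

#' Frozen convolutional feature extractor for the perceptual loss
#'
#' A fixed (never-trained) three-stage convolutional network whose weights
#' are drawn once from a seeded Glorot distribution: a random-projection
#' feature bank.  Fixed random convolutional features preserve image
#' structure differences in their activation space, which is what the
#' perceptual term compares; externally trained weights (e.g. a VGG-style
#' extractor exported to the package's parameter format via
#' [load_extractor_weights()]) can be substituted.
#'
#' @param n_filters filters per stage.
#' @param seed seed fixing the (frozen) weights.
#' @param feature_layer index (1-based) of the stage whose activations are
#'   compared; defaults to the middle stage.
#' @return object of class `perceptual_extractor`.
#' @export
perceptual_extractor <- function(n_filters = c(16, 32, 32), seed = 77L,
                                 feature_layer = 2L) {
  cin <- c(1, n_filters[-length(n_filters)])
  nodes <- list(nn_node("in", "input"))
  prev <- "in"
  for (i in seq_along(n_filters)) {
    cv <- paste0("fconv", i)
    nodes <- c(nodes, list(
      nn_node(cv, "conv", prev, k = 3, cin = cin[i], cout = n_filters[i],
              trainable = FALSE),
      nn_node(paste0("frelu", i), "relu", cv)))
    prev <- paste0("frelu", i)
  }
  graph <- nn_graph(nodes)
  structure(list(graph = graph, params = nn_init(graph, seed = seed),
                 feature_layer = as.integer(feature_layer),
                 out_node = paste0("frelu", feature_layer)),
            class = "perceptual_extractor")
}

#' Replace extractor weights with externally supplied ones
#' @param extractor a `perceptual_extractor`.
#' @param weights named list matching the extractor's conv nodes, each with
#'   `W` (k x k x cin x cout array) and `b`.
#' @export
load_extractor_weights <- function(extractor, weights) {
  for (nm in names(weights)) {
    if (is.null(extractor$params[[nm]]))
      stop("no such extractor layer: ", nm)
    extractor$params[[nm]] <- weights[[nm]]
  }
  extractor
}

extractor_features <- function(extractor, x) {
  fw <- nn_forward(extractor$graph, extractor$params, x, training = FALSE)
  list(feat = fw$acts[[extractor$out_node]], fw = fw)
}

#' Combined pixel + perceptual loss (PL2)
#'
#' `L = w_pixel * pixel(y_model, y_fb) + w_perceptual * mean((phi(y_model)
#' - phi(y_fb))^2)` where `phi` is the frozen extractor's feature map.
#' Deterministic given the extractor's fixed weights.
#'
#' @inheritParams pl1_loss
#' @param config a `loss_config` of kind `"pl2"`.
#' @return non-negative scalar.
#' @export
pl2_loss <- function(y_model, y_fb, config = loss_config("pl2")) {
  if (!identical(dim(y_model), dim(y_fb))) stop("shape mismatch")
  w <- config$mix_weights
  px_mse <- mean((y_model - y_fb)^2)
  px <- if (config$pixel_term == "rmse") sqrt(px_mse) else px_mse
  perc <- 0
  if (w[2] > 0) {
    ex <- config$feature_extractor
    if (is.null(ex))
      stop("no feature extractor configured: build one with perceptual_extractor() ",
           "or install external weights via load_extractor_weights()")
    fa <- extractor_features(ex, as_batch4(y_model))$feat
    fb <- extractor_features(ex, as_batch4(y_fb))$feat
    perc <- mean((fa - fb)^2)
  }
  w[1] * px + w[2] * perc
}

## gradient of pl2 w.r.t. y_model
pl2_grad <- function(y_model, y_fb, config) {
  w <- config$mix_weights
  px_mse <- mean((y_model - y_fb)^2)
  gpx <- if (config$pixel_term == "rmse") {
    if (px_mse == 0) array(0, dim(y_model))
    else (y_model - y_fb) / (length(y_model) * sqrt(px_mse))
  } else 2 * (y_model - y_fb) / length(y_model)
  g <- w[1] * gpx
  if (w[2] > 0) {
    ex <- config$feature_extractor
    if (is.null(ex)) stop("no feature extractor configured")
    ya <- as_batch4(y_model); yb <- as_batch4(y_fb)
    ra <- extractor_features(ex, ya)
    rb <- extractor_features(ex, yb)
    dfeat <- 2 * (ra$feat - rb$feat) / length(ra$feat)
    ## backprop the feature difference through the frozen extractor; the
    ## extractor output node is its last node, so feed dfeat there only if
    ## feature_layer is the last stage -- otherwise run a truncated backward.
    dx <- extractor_backward_to_input(ex, ra$fw, dfeat)
    g <- g + w[2] * array(dx, dim(y_model))
  }
  array(g, dim(y_model))
}

## backward pass through the extractor from its feature node to the input
extractor_backward_to_input <- function(ex, fw, dfeat) {
  graph <- ex$graph
  nodes <- graph$nodes
  grads_out <- list()
  grads_out[[ex$out_node]] <- dfeat
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- grads_out[[nd$name]]
    if (is.null(dy)) next
    if (nd$type == "input") next
    ins <- nd$inputs
    g <- switch(nd$type,
      conv = {
        p <- ex$params[[nd$name]]
        x <- fw$acts[[ins[[1]]]]
        .conv2d_bwd(x, dim(x), p$W, nd$k, nd$cin, nd$cout, dy, 1L, TRUE, FALSE)$dx
      },
      relu = dy * fw$cache[[nd$name]]$mask)
    nm <- ins[[1]]
    grads_out[[nm]] <- if (is.null(grads_out[[nm]])) g else grads_out[[nm]] + g
  }
  grads_out[["in"]]
}

#' Evaluate a configured loss (and its gradient)
#' @keywords internal
loss_value <- function(config, y_model, y_fb) {
  if (config$kind == "pl1") pl1_loss(y_model, y_fb, config$tau)
  else pl2_loss(y_model, y_fb, config)
}
loss_grad <- function(config, y_model, y_fb) {
  if (config$kind == "pl1") pl1_grad(y_model, y_fb, config$tau)
  else pl2_grad(y_model, y_fb, config)
}

as_batch4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2) array(x, c(d, 1, 1))
  else if (length(d) == 3) array(x, c(d[1], d[2], 1, d[3]))
  else x
}
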