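#' Training configuration
#'
#' Defaults follow the training protocol: batch size 16, Adam with
#' learning rate 1e-4, beta1 0.9, beta2 0.999, up to 300 epochs with early
#' stopping on the validation loss.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param max_epochs maximum number of epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (0 disables early stopping); best-validation weights are
#'   restored.
#' @param loss a `loss_config`.
#' @param seed integer seed for shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         max_epochs = 300L, early_stop_patience = 20L,
                         loss = loss_config("pl1"), seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

#' Extract random overlapping patches from a paired dataset
#'
#' Draws `per_image` uniformly random top-left corners per image (overlap
#' allowed, fixed once — patches are not redrawn between epochs) and cuts
#' input and target at identical coordinates.
#'
#' @param pairs a `paired_dataset`.
#' @param per_image patches per image (default 64).
#' @param size square patch edge (default 128).
#' @param seed integer seed.
#' @return object of class `patch_set`: list with `inputs`, `targets`
#'   (size x size x 1 x N arrays), `source_indices`, `seed`.
#' @export
extract_patches <- function(pairs, per_image = 64L, size = 128L, seed) {
  stopifnot(inherits(pairs, "paired_dataset"))
  if (missing(seed)) stop("a seed is required")
  d <- dim(pairs$input)
  H <- d[1]; W <- d[2]; n_img <- d[3]
  if (H < size || W < size)
    stop(sprintf("images are %dx%d: smaller than the %dx%d patch size",
                 H, W, size, size))
  set.seed(seed)
  N <- per_image * n_img
  inputs <- array(0, c(size, size, 1, N))
  targets <- array(0, c(size, size, 1, N))
  src <- integer(N)
  p <- 0L
  for (i in seq_len(n_img)) {
    r0 <- sample.int(H - size + 1L, per_image, replace = TRUE)
    c0 <- sample.int(W - size + 1L, per_image, replace = TRUE)
    for (j in seq_len(per_image)) {
      p <- p + 1L
      rows <- r0[j]:(r0[j] + size - 1L); cols <- c0[j]:(c0[j] + size - 1L)
      inputs[, , 1, p] <- pairs$input[rows, cols, i]
      targets[, , 1, p] <- pairs$target[rows, cols, i]
      src[p] <- i
    }
  }
  structure(list(inputs = inputs, targets = targets, source_indices = src,
                 seed = as.integer(seed)),
            class = "patch_set")
}

## ---- Adam optimizer over the nested parameter list ----

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "replace", classes = "ANY")
}

## flatten helpers: gradients arrive as pgrads[[node]][[slot]]
adam_step <- function(params, pgrads, state, t, cfg, frozen) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$learning_rate; eps <- cfg$epsilon
  for (nd in names(pgrads)) {
    if (nd %in% frozen) next
    for (slot in names(pgrads[[nd]])) {
      g <- pgrads[[nd]][[slot]]
      st <- state[[nd]][[slot]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[nd]][[slot]] <- params[[nd]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nd]][[slot]] <- st
    }
  }
  list(params = params, state = state)
}

frozen_nodes <- function(graph) {
  names(graph$nodes)[vapply(graph$nodes, function(nd) isFALSE(nd$trainable), TRUE)]
}

eval_loss_on <- function(model, cfg, inputs, targets, batch_size = 16L) {
  N <- dim(inputs)[4]
  tot <- 0
  for (b0 in seq(1, N, batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, N)
    xb <- inputs[, , , idx, drop = FALSE]
    yb <- targets[, , , idx, drop = FALSE]
    out <- nn_forward(model$graph, model$params, xb, training = FALSE)$out
    tot <- tot + loss_value(cfg$loss, out, yb) * length(idx)
  }
  tot / N
}

#' Train a model on patch sets
#'
#' Mini-batch Adam on the configured loss, with per-epoch reshuffling (seed
#' derived from `config$seed` and the epoch index), early stopping on the
#' validation loss and restoration of the best-validation weights.
#'
#' @param model a `us_model` from [build_model()].
#' @param train_patches,val_patches `patch_set`s; `val_patches` may be
#'   `NULL`, in which case the training loss drives early stopping.
#' @param config a `train_config`.
#' @param verbose print per-epoch losses.
#' @return the trained `us_model`, with a `history` data.frame (epoch,
#'   train_loss, val_loss) attached.
#' @export
train_model <- function(model, train_patches, val_patches = NULL,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "us_model"), inherits(train_patches, "patch_set"))
  cfg <- config
  X <- train_patches$inputs; Y <- train_patches$targets
  N <- dim(X)[4]
  state <- adam_init(model$params)
  frozen <- frozen_nodes(model$graph)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best_val <- Inf; best_params <- model$params; wait <- 0L; t <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    set.seed(cfg$seed + 1000L * epoch)
    ord <- sample.int(N)
    ep_loss <- 0
    for (b0 in seq(1, N, cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, N)]
      xb <- X[, , , idx, drop = FALSE]
      yb <- Y[, , , idx, drop = FALSE]
      fw <- nn_forward(model$graph, model$params, xb, training = TRUE)
      model$params <- nn_update_bn_stats(model$graph, model$params, fw)
      l <- loss_value(cfg$loss, fw$out, yb)
      if (!is.finite(l))
        stop(sprintf("non-finite loss at epoch %d (loss=%g, lr=%g%s): aborting",
                     epoch, l, cfg$learning_rate,
                     if (cfg$loss$kind == "pl1")
                       sprintf(", tau=%g", cfg$loss$tau) else ""))
      dout <- loss_grad(cfg$loss, fw$out, yb)
      pg <- nn_backward(model$graph, model$params, fw, dout)
      t <- t + 1L
      up <- adam_step(model$params, pg, state, t, cfg, frozen)
      model$params <- up$params; state <- up$state
      ep_loss <- ep_loss + l * length(idx)
    }
    ep_loss <- ep_loss / N
    vl <- if (is.null(val_patches)) ep_loss
          else eval_loss_on(model, cfg, val_patches$inputs, val_patches$targets,
                            cfg$batch_size)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.6f  val %.6f", epoch, ep_loss, vl))
    if (vl < best_val) {
      best_val <- vl; best_params <- model$params; wait <- 0L
    } else if (cfg$early_stop_patience > 0L) {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
  }
  model$params <- best_params
  model$history <- hist
  model
}

#' Save / load model weights
#'
#' Weights (and the model spec) are serialized with R's native format.
#' @param model a `us_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params,
               patch_size = model$patch_size, history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- readRDS(path)
  m <- build_model(s$spec, s$patch_size)
  m$params <- s$params
  m$history <- s$history
  m
}
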