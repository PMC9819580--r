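## Minimal computational-graph framework for small fully-convolutional
## image-restoration networks.  Activations are numeric arrays with
## dim = c(H, W, C, N).  A network is a directed acyclic graph described as an
## ordered list of nodes; each node names its input node(s), so concatenation
## skips (U-Net) and residual additions (REDNet) are expressed directly.
##
## Node types: input, conv, tconv (stride-2 transposed conv), maxpool, bn,
## relu, dropout, concat, add.  conv nodes may be frozen (trainable = FALSE),
## which is how the fixed Sobel edge-extraction layer is represented.

nn_node <- function(name, type, inputs = NULL, ...) {
  c(list(name = name, type = type, inputs = inputs), list(...))
}

#' @keywords internal
nn_graph <- function(nodes) {
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  structure(list(nodes = nodes), class = "nn_graph")
}

## He/Glorot-uniform initialization, seeded for reproducibility.
glorot_uniform <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

#' Initialize the parameters of a graph
#' @keywords internal
nn_init <- function(graph, seed = 1L, final_zero = FALSE) {
  set.seed(seed)
  params <- list()
  conv_names <- names(graph$nodes)[vapply(graph$nodes, function(nd)
    nd$type %in% c("conv", "tconv"), TRUE)]
  last_conv <- if (length(conv_names)) conv_names[length(conv_names)] else ""
  for (nd in graph$nodes) {
    if (nd$type %in% c("conv", "tconv")) {
      k <- nd$k; cin <- nd$cin; cout <- nd$cout
      if (!is.null(nd$weights)) {           # fixed kernels (e.g. Sobel bank)
        W <- nd$weights; b <- rep(0, cout)
      } else if (final_zero && nd$name == last_conv) {
        W <- array(0, c(k, k, cin, cout)); b <- rep(0, cout)
      } else {
        W <- array(glorot_uniform(k * k * cin, k * k * cout, k * k * cin * cout),
                   c(k, k, cin, cout))
        b <- rep(0, cout)
      }
      params[[nd$name]] <- list(W = W, b = b)
    } else if (nd$type == "bn") {
      C <- nd$channels
      params[[nd$name]] <- list(gamma = rep(1, C), beta = rep(0, C),
                                moving_mean = rep(0, C), moving_var = rep(1, C))
    }
  }
  params
}

#' Count parameters exactly by summation over nodes
#' @keywords internal
nn_count_params <- function(graph) {
  total <- trainable <- 0
  for (nd in graph$nodes) {
    p <- switch(nd$type,
      conv  = ,
      tconv = nd$k^2 * nd$cin * nd$cout + nd$cout,
      bn    = 4L * nd$channels,   # gamma, beta, moving mean, moving var
      0L)
    tr <- switch(nd$type,
      conv  = ,
      tconv = if (isFALSE(nd$trainable)) 0L else p,
      bn    = 2L * nd$channels,   # moving stats are never trained
      0L)
    total <- total + p
    trainable <- trainable + tr
  }
  list(total = total, trainable = trainable, non_trainable = total - trainable)
}

## zero-stuffing used by the stride-2 transposed convolution: x goes to the
## even grid positions of a twice-as-large array, then a same-padded conv runs.
zstuff2 <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  y
}
unstuff2 <- function(dy) {
  d <- dim(dy)
  dy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
}

bn_eps <- 1e-3

#' Forward pass
#'
#' @param graph nn_graph
#' @param params parameter list from [nn_init()]
#' @param x input array (H, W, C, N)
#' @param training logical; batch statistics + dropout when TRUE
#' @param rng_dropout optional function(n) returning uniforms (for dropout)
#' @return list(out = final activation, cache = per-node activations)
#' @keywords internal
nn_forward <- function(graph, params, x, training = FALSE, momentum = 0.99) {
  acts <- list(); cache <- list()
  out_name <- NULL
  for (nd in graph$nodes) {
    ins <- lapply(nd$inputs, function(nm) acts[[nm]])
    a <- switch(nd$type,
      input = x,
      conv = {
        p <- params[[nd$name]]
        .conv2d_fwd(ins[[1]], dim(ins[[1]]), p$W, nd$k, nd$cin, nd$cout,
                    p$b, if (is.null(nd$dilation)) 1L else nd$dilation)
      },
      tconv = {
        p <- params[[nd$name]]
        xs <- zstuff2(ins[[1]])
        cache[[nd$name]] <- list(zdim = dim(xs), z = xs)
        .conv2d_fwd(xs, dim(xs), p$W, nd$k, nd$cin, nd$cout, p$b, 1L)
      },
      maxpool = {
        r <- .maxpool2_fwd(ins[[1]], dim(ins[[1]]))
        cache[[nd$name]] <- list(idx = r$idx, xdim = dim(ins[[1]]))
        r$y
      },
      bn = {
        p <- params[[nd$name]]
        xin <- ins[[1]]; d <- dim(xin)
        xm <- matrix(aperm(xin, c(1, 2, 4, 3)), ncol = d[3])
        if (training) {
          mu <- colMeans(xm)
          v <- colMeans(xm^2) - mu^2
        } else {
          mu <- p$moving_mean; v <- p$moving_var
        }
        xc <- sweep(xm, 2, mu, `-`)
        inv <- 1 / sqrt(v + bn_eps)
        xhat <- sweep(xc, 2, inv, `*`)
        ym <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
        cache[[nd$name]] <- list(xhat = xhat, inv = inv, mu = mu, v = v, d = d)
        aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      },
      relu = {
        xin <- ins[[1]]
        cache[[nd$name]] <- list(mask = xin > 0)
        xin * (xin > 0)
      },
      dropout = {
        xin <- ins[[1]]
        if (training && nd$rate > 0) {
          keep <- (runif(length(xin)) >= nd$rate) / (1 - nd$rate)
          cache[[nd$name]] <- list(keep = keep)
          array(xin * keep, dim(xin))
        } else {
          cache[[nd$name]] <- list(keep = NULL)
          xin
        }
      },
      concat = {
        d1 <- dim(ins[[1]])
        cache[[nd$name]] <- list(splits = vapply(ins, function(z) dim(z)[3], 0))
        ar <- array(0, c(d1[1], d1[2], sum(vapply(ins, function(z) dim(z)[3], 0)), d1[4]))
        at <- 0L
        for (z in ins) {
          cz <- dim(z)[3]
          ar[, , (at + 1):(at + cz), ] <- z
          at <- at + cz
        }
        ar
      },
      add = ins[[1]] + ins[[2]],
      stop("unknown node type: ", nd$type))
    acts[[nd$name]] <- a
    out_name <- nd$name
  }
  list(out = acts[[out_name]], acts = acts, cache = cache, out_name = out_name)
}

## Batch-norm statistics update (training); returns updated params.
nn_update_bn_stats <- function(graph, params, fw, momentum = 0.99) {
  for (nd in graph$nodes) {
    if (nd$type == "bn") {
      cc <- fw$cache[[nd$name]]
      p <- params[[nd$name]]
      p$moving_mean <- momentum * p$moving_mean + (1 - momentum) * cc$mu
      p$moving_var  <- momentum * p$moving_var  + (1 - momentum) * cc$v
      params[[nd$name]] <- p
    }
  }
  params
}

#' Backward pass: returns gradients for trainable conv/tconv/bn parameters.
#' @keywords internal
nn_backward <- function(graph, params, fw, dout) {
  nodes <- graph$nodes
  grads_out <- list()                 # accumulated dL/d(activation) per node
  grads_out[[fw$out_name]] <- dout
  pgrads <- list()
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    dy <- grads_out[[nd$name]]
    if (is.null(dy)) next
    ins <- nd$inputs
    push <- function(nm, g) {
      grads_out[[nm]] <<- if (is.null(grads_out[[nm]])) g else grads_out[[nm]] + g
    }
    switch(nd$type,
      input = NULL,
      conv = {
        p <- params[[nd$name]]
        x <- fw$acts[[ins[[1]]]]
        need_dw <- !isFALSE(nd$trainable)
        r <- .conv2d_bwd(x, dim(x), p$W, nd$k, nd$cin, nd$cout, dy,
                         if (is.null(nd$dilation)) 1L else nd$dilation,
                         TRUE, need_dw)
        if (need_dw)
          pgrads[[nd$name]] <- list(W = array(r$dw, dim(p$W)), b = r$db)
        push(ins[[1]], r$dx)
      },
      tconv = {
        p <- params[[nd$name]]
        z <- fw$cache[[nd$name]]$z
        r <- .conv2d_bwd(z, dim(z), p$W, nd$k, nd$cin, nd$cout, dy, 1L, TRUE, TRUE)
        pgrads[[nd$name]] <- list(W = array(r$dw, dim(p$W)), b = r$db)
        push(ins[[1]], unstuff2(r$dx))
      },
      maxpool = {
        cc <- fw$cache[[nd$name]]
        push(ins[[1]], .maxpool2_bwd(dy, cc$idx, cc$xdim))
      },
      bn = {
        p <- params[[nd$name]]; cc <- fw$cache[[nd$name]]
        d <- cc$d; m <- d[1] * d[2] * d[4]
        dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
        dgamma <- colSums(dym * cc$xhat)
        dbeta <- colSums(dym)
        dxhat <- sweep(dym, 2, p$gamma, `*`)
        ## dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat))
        s1 <- colSums(dxhat); s2 <- colSums(dxhat * cc$xhat)
        dxm <- sweep(dxhat, 2, s1 / m, `-`) -
          sweep(cc$xhat, 2, s2 / m, `*`)
        dxm <- sweep(dxm, 2, cc$inv, `*`)
        pgrads[[nd$name]] <- list(gamma = dgamma, beta = dbeta)
        push(ins[[1]], aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)))
      },
      relu = push(ins[[1]], dy * fw$cache[[nd$name]]$mask),
      dropout = {
        keep <- fw$cache[[nd$name]]$keep
        push(ins[[1]], if (is.null(keep)) dy else array(dy * keep, dim(dy)))
      },
      concat = {
        splits <- fw$cache[[nd$name]]$splits
        at <- 0L
        for (j in seq_along(ins)) {
          push(ins[[j]], dy[, , (at + 1):(at + splits[j]), , drop = FALSE])
          at <- at + splits[j]
        }
      },
      add = { push(ins[[1]], dy); push(ins[[2]], dy) })
    grads_out[[nd$name]] <- NULL      # free
  }
  pgrads
}
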