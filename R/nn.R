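# Minimal 1-D convolutional network engine.
#
# Activations flow as arrays of dim c(len, maps, batch). Layers are
# environments holding parameters, gradients, running state and the cache
# of the last forward pass; models are ordered lists of layers (a
# "resblock" layer nests two sub-lists). Convolution kernels live in
# src/convnet.cpp; everything cheap (BN, ReLU, pooling) is vectorized R.
#
# Only trainable tensors (conv weights/biases, BN scale/shift) count as
# parameters; BN running statistics are state, not parameters.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "nn_layer"
  e
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_conv <- function(k, n_in, n_out) {
  l <- new_layer("conv", k = as.integer(k), n_in = n_in, n_out = n_out,
                 pad_l = as.integer(floor((k - 1) / 2)))
  l$params$W <- glorot_uniform(k * n_in, k * n_out, c(k * n_in, n_out))
  l$params$b <- numeric(n_out)
  l
}

layer_dwconv <- function(k, maps) {
  l <- new_layer("dwconv", k = as.integer(k), maps = maps,
                 pad_l = as.integer(floor((k - 1) / 2)))
  l$params$W <- glorot_uniform(k, k, c(k, maps))
  l$params$b <- numeric(maps)
  l
}

layer_bn <- function(maps, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", maps = maps, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, maps)
  l$params$beta <- numeric(maps)
  l$run_mean <- numeric(maps)
  l$run_var <- rep(1, maps)
  l
}

layer_relu <- function() new_layer("relu")
layer_sigmoid <- function() new_layer("sigmoid")
layer_avgpool2 <- function() new_layer("avgpool2")
layer_gap <- function() new_layer("gap")

# Residual block: out = ReLU(main(x) + skip(x)); skip NULL means identity.
layer_resblock <- function(main, skip = NULL)
  new_layer("resblock", main = main, skip = skip)

layer_forward <- function(l, x, training) {
  switch(l$type,
    conv = {
      l$cache <- x
      cn_conv_fwd(x, l$params$W, l$params$b, l$k, l$pad_l)
    },
    dwconv = {
      l$cache <- x
      cn_dwconv_fwd(x, l$params$W, l$params$b, l$pad_l)
    },
    bn = {
      if (training) {
        mv <- cn_map_meanvar(x)
        mu <- as.numeric(mv$mean); va <- as.numeric(mv$var)
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
      } else {
        mu <- l$run_mean
        va <- l$run_var
      }
      sig <- sqrt(va + l$eps)
      a <- l$params$gamma / sig
      l$cache <- list(x = x, mu = mu, sig = sig, training = training)
      cn_map_affine(x, a, l$params$beta - mu * a)
    },
    relu = {
      l$cache <- cn_relu(x)
      l$cache
    },
    sigmoid = {
      p <- 1 / (1 + exp(-x))
      l$cache <- p
      p
    },
    avgpool2 = {
      n <- dim(x)[1L]
      stopifnot(n %% 2L == 0L)
      y <- (x[seq(1L, n, 2L), , , drop = FALSE] +
            x[seq(2L, n, 2L), , , drop = FALSE]) / 2
      l$cache <- dim(x)
      y
    },
    gap = {
      l$cache <- dim(x)
      colMeans(x, dims = 1L)                  # (maps, batch)
    },
    resblock = {
      main_out <- nn_forward(l$main, x, training)
      skip_out <- if (is.null(l$skip)) x else nn_forward(l$skip, x, training)
      l$cache <- cn_add_relu(main_out, skip_out)
      l$cache
    },
    stop("unknown layer type ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      # a conv fed directly by the raw input never needs dX
      g <- cn_conv_bwd(l$cache, l$params$W, dy, l$k, l$pad_l,
                       !isTRUE(l$no_input_grad))
      l$grads$W <- g$dW
      l$grads$b <- as.numeric(g$db)
      g$dX
    },
    dwconv = {
      g <- cn_dwconv_bwd(l$cache, l$params$W, dy, l$pad_l)
      l$grads$W <- g$dW
      l$grads$b <- as.numeric(g$db)
      g$dX
    },
    bn = {
      cc <- l$cache
      g <- cn_bn_bwd(cc$x, dy, cc$mu, cc$sig, l$params$gamma,
                     cc$training)
      l$grads$gamma <- as.numeric(g$dgamma)
      l$grads$beta <- as.numeric(g$dbeta)
      g$dX
    },
    relu = cn_relu_bwd(l$cache, dy),
    sigmoid = dy * l$cache * (1 - l$cache),
    avgpool2 = {
      d <- l$cache
      dx <- array(0, dim = d)
      dx[seq(1L, d[1L], 2L), , ] <- dy / 2
      dx[seq(2L, d[1L], 2L), , ] <- dy / 2
      dx
    },
    gap = {
      d <- l$cache
      array(rep(dy / d[1L], each = d[1L]), dim = d)
    },
    resblock = {
      ds <- cn_relu_bwd(l$cache, dy)
      dx <- nn_backward(l$main, ds)
      if (is.null(l$skip)) dx + ds
      else dx + nn_backward(l$skip, ds)
    },
    stop("unknown layer type ", l$type))
}

nn_forward <- function(layers, x, training = FALSE) {
  for (l in layers) x <- layer_forward(l, x, training)
  x
}

nn_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- layer_backward(l, dy)
  dy
}

# depth-first traversal over all layers including nested blocks
walk_layers <- function(layers, fn) {
  for (l in layers) {
    if (l$type == "resblock") {
      walk_layers(l$main, fn)
      if (!is.null(l$skip)) walk_layers(l$skip, fn)
    }
    fn(l)
  }
  invisible(NULL)
}

clear_caches <- function(model)
  walk_layers(model$layers, function(l) l$cache <- NULL)

#' Number of trainable parameters of a model
#'
#' Counts conv weights and biases plus batch-norm scale and shift; running
#' batch statistics are untrained state and are excluded.
#'
#' @param model a model built by [build_baseline()] or [build_enhanced()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  walk_layers(model$layers, function(l) {
    for (p in l$params) n <<- n + length(p)
  })
  n
}

#' Analytic receptive field of a model
#'
#' Walks the layer table accumulating `(kernel - 1) * jump` for every
#' convolution and pooling stage (the global average pool is excluded: the
#' receptive field quoted for these models is that of one pre-pooling
#' output unit). For a residual block the longest path is taken.
#'
#' @param model a built model.
#' @return Receptive field in input samples.
#' @export
receptive_field <- function(model) {
  walk <- function(layers, rf, jump) {
    for (l in layers) {
      if (l$type %in% c("conv", "dwconv")) {
        rf <- rf + (l$k - 1L) * jump
      } else if (l$type == "avgpool2") {
        rf <- rf + jump
        jump <- jump * 2L
      } else if (l$type == "resblock") {
        main <- walk(l$main, rf, jump)
        skip <- if (is.null(l$skip)) c(rf, jump)
                else walk(l$skip, rf, jump)
        rf <- max(main[1L], skip[1L])
        jump <- main[2L]
      }
    }
    c(rf, jump)
  }
  walk(model$layers, 1L, 1L)[1L]
}

# Deep-copy weights out of / into a model (for checkpoints and ensembling).
get_weights <- function(model) {
  out <- list()
  i <- 0L
  walk_layers(model$layers, function(l) {
    i <<- i + 1L
    out[[i]] <<- list(params = l$params,
                      run_mean = if (l$type == "bn") l$run_mean,
                      run_var = if (l$type == "bn") l$run_var)
  })
  out
}

set_weights <- function(model, w) {
  i <- 0L
  walk_layers(model$layers, function(l) {
    i <<- i + 1L
    l$params <- w[[i]]$params
    if (l$type == "bn") {
      l$run_mean <- w[[i]]$run_mean
      l$run_var <- w[[i]]$run_var
    }
  })
  invisible(model)
}
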