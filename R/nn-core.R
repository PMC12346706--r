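# Minimal convolutional-network engine: layers are environments holding
# parameters, gradients and per-forward caches.  A "batch" is a plain list of
# H x W x C arrays; every layer_fwd()/layer_bwd() maps batch -> batch.  Each
# layer instance may appear only once in a model graph (caches are per-layer).

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(fan_in, n_out, n_row) {
  matrix(rnorm(n_row * n_out, sd = sqrt(2 / fan_in)), n_row, n_out)
}

#' @noRd
nn_conv <- function(cin, cout, k = 1L, stride = 1L) {
  new_layer("conv",
    cin = cin, cout = cout, k = as.integer(k), stride = as.integer(stride),
    W = he_init(k * k * cin, cout, k * k * cin), b = numeric(cout),
    gW = NULL, gb = NULL, param_names = c("W", "b"))
}

#' @noRd
nn_tconv <- function(cin, cout, k, stride) {
  new_layer("tconv",
    cin = cin, cout = cout, k = as.integer(k), stride = as.integer(stride),
    W = he_init(cin, k * k * cout, cin), b = numeric(cout),
    gW = NULL, gb = NULL, param_names = c("W", "b"))
}

#' @noRd
nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
    c = c, momentum = momentum, eps = eps,
    gamma = rep(1, c), beta = numeric(c),
    run_mean = numeric(c), run_var = rep(1, c),
    ggamma = NULL, gbeta = NULL, param_names = c("gamma", "beta"))
}

#' @noRd
nn_relu <- function() new_layer("relu", param_names = character())

#' @noRd
nn_fc <- function(cin, cout) {
  new_layer("fc",
    cin = cin, cout = cout,
    W = he_init(cin, cout, cin), b = numeric(cout),
    gW = NULL, gb = NULL, param_names = c("W", "b"))
}

chanop <- function(x, v, op) {
  # apply per-channel scalar op over H x W x C array without apply() overhead
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  m <- switch(op,
    mul = sweep(m, 2, v, "*"),
    add = sweep(m, 2, v, "+"))
  array(m, d)
}

acc_grad <- function(layer, nm, g) {
  slot <- paste0("g", nm)
  cur <- get0(slot, envir = layer, ifnotfound = NULL)
  assign(slot, if (is.null(cur)) g else cur + g, envir = layer)
}

layer_fwd <- function(layer, xs, training = FALSE, update_stats = training) {
  switch(layer$type,
    conv = {
      layer$xs <- xs
      lapply(xs, conv2d_fwd, w = layer$W, b = layer$b,
             k = layer$k, s = layer$stride)
    },
    tconv = {
      layer$xs <- xs
      lapply(xs, convt2d_fwd, w = layer$W, b = layer$b,
             k = layer$k, s = layer$stride)
    },
    relu = {
      ys <- lapply(xs, function(x) x * (x > 0))
      layer$masks <- lapply(xs, function(x) x > 0)
      ys
    },
    bn = bn_fwd(layer, xs, training, update_stats),
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, gys, need_input = TRUE, need_pgrads = TRUE) {
  switch(layer$type,
    conv = {
      gxs <- vector("list", length(gys))
      for (i in seq_along(gys)) {
        r <- conv2d_bwd(layer$xs[[i]], layer$W, gys[[i]], layer$k,
                        layer$stride, need_input, need_pgrads)
        if (need_pgrads) {
          acc_grad(layer, "W", r$gw)
          acc_grad(layer, "b", drop(r$gb))
        }
        if (need_input) gxs[[i]] <- r$gx
      }
      if (need_input) gxs else NULL
    },
    tconv = {
      gxs <- vector("list", length(gys))
      for (i in seq_along(gys)) {
        r <- convt2d_bwd(layer$xs[[i]], layer$W, gys[[i]], layer$k,
                         layer$stride, need_input, need_pgrads)
        if (need_pgrads) {
          acc_grad(layer, "W", r$gw)
          acc_grad(layer, "b", drop(r$gb))
        }
        if (need_input) gxs[[i]] <- r$gx
      }
      if (need_input) gxs else NULL
    },
    relu = Map(function(g, m) g * m, gys, layer$masks),
    bn = bn_bwd(layer, gys, need_input, need_pgrads),
    stop("unknown layer type: ", layer$type))
}

bn_fwd <- function(layer, xs, training, update_stats) {
  C <- layer$c
  if (training) {
    n <- 0
    s1 <- numeric(C); s2 <- numeric(C)
    ms <- lapply(xs, function(x) {
      d <- dim(x)
      matrix(x, d[1] * d[2], d[3])
    })
    for (m in ms) {
      n <- n + nrow(m)
      s1 <- s1 + colSums(m)
      s2 <- s2 + colSums(m * m)
    }
    mu <- s1 / n
    v <- pmax(s2 / n - mu^2, 0)
    if (update_stats) {
      mom <- layer$momentum
      layer$run_mean <- (1 - mom) * layer$run_mean + mom * mu
      # unbiased running variance, matching common framework practice
      layer$run_var <- (1 - mom) * layer$run_var +
        mom * v * n / max(n - 1, 1)
    }
    invstd <- 1 / sqrt(v + layer$eps)
    layer$invstd <- invstd
    layer$n_total <- n
    xhat <- lapply(xs, function(x)
      chanop(chanop(x, -mu, "add"), invstd, "mul"))
    layer$xhat <- xhat
    layer$train_mode <- TRUE
    lapply(xhat, function(h)
      chanop(chanop(h, layer$gamma, "mul"), layer$beta, "add"))
  } else {
    invstd <- 1 / sqrt(layer$run_var + layer$eps)
    layer$invstd <- invstd
    layer$train_mode <- FALSE
    scale <- layer$gamma * invstd
    shift <- layer$beta - layer$run_mean * scale
    lapply(xs, function(x) chanop(chanop(x, scale, "mul"), shift, "add"))
  }
}

bn_bwd <- function(layer, gys, need_input, need_pgrads) {
  C <- layer$c
  if (!isTRUE(layer$train_mode)) {
    scale <- layer$gamma * layer$invstd
    if (need_pgrads)
      stop("batchnorm parameter gradients require a training-mode forward")
    return(if (need_input) lapply(gys, chanop, v = scale, op = "mul"))
  }
  n <- layer$n_total
  sg <- numeric(C); sgx <- numeric(C)
  for (i in seq_along(gys)) {
    d <- dim(gys[[i]])
    gm <- matrix(gys[[i]], d[1] * d[2], d[3])
    hm <- matrix(layer$xhat[[i]], d[1] * d[2], d[3])
    sg <- sg + colSums(gm)
    sgx <- sgx + colSums(gm * hm)
  }
  if (need_pgrads) {
    acc_grad(layer, "gamma", sgx)
    acc_grad(layer, "beta", sg)
  }
  if (!need_input) return(NULL)
  gmean <- sg / n
  gxmean <- sgx / n
  coef <- layer$gamma * layer$invstd
  Map(function(g, h) {
    t1 <- chanop(g, -gmean, "add")
    t2 <- chanop(h, gxmean, "mul")
    chanop(t1 - t2, coef, "mul")
  }, gys, layer$xhat)
}

# ---- residual bottleneck block -------------------------------------------

#' @noRd
nn_bottleneck <- function(cin, mid, cout, k3, stride) {
  blk <- new_layer("bottleneck",
    cin = cin, mid = mid, cout = cout, k3 = as.integer(k3),
    stride = as.integer(stride), param_names = character())
  blk$conv1 <- nn_conv(cin, mid, 1L, 1L)
  blk$bn1 <- nn_bn(mid)
  blk$relu1 <- nn_relu()
  blk$conv2 <- nn_conv(mid, mid, k3, stride)
  blk$bn2 <- nn_bn(mid)
  blk$relu2 <- nn_relu()
  blk$conv3 <- nn_conv(mid, cout, 1L, 1L)
  blk$bn3 <- nn_bn(cout)
  blk$relu3 <- nn_relu()
  blk$has_short <- (cin != cout) || (stride != 1L) || (k3 != 1L)
  if (blk$has_short) {
    blk$sconv <- nn_conv(cin, cout, 1L, stride)
    blk$sbn <- nn_bn(cout)
  }
  blk
}

block_sublayers <- function(blk) {
  nms <- c("conv1", "bn1", "relu1", "conv2", "bn2", "relu2",
           "conv3", "bn3", "relu3")
  if (blk$has_short) nms <- c(nms, "sconv", "sbn")
  lapply(nms, function(n) blk[[n]])
}

crop_to <- function(x, h, w) {
  if (dim(x)[1] == h && dim(x)[2] == w) x else x[seq_len(h), seq_len(w), , drop = FALSE]
}

block_fwd <- function(blk, xs, training = FALSE, update_stats = training) {
  h <- layer_fwd(blk$conv1, xs, training, update_stats)
  h <- layer_fwd(blk$bn1, h, training, update_stats)
  h <- layer_fwd(blk$relu1, h, training, update_stats)
  h <- layer_fwd(blk$conv2, h, training, update_stats)
  h <- layer_fwd(blk$bn2, h, training, update_stats)
  h <- layer_fwd(blk$relu2, h, training, update_stats)
  h <- layer_fwd(blk$conv3, h, training, update_stats)
  h <- layer_fwd(blk$bn3, h, training, update_stats)
  if (blk$has_short) {
    s <- layer_fwd(blk$sconv, xs, training, update_stats)
    s <- layer_fwd(blk$sbn, s, training, update_stats)
  } else {
    s <- xs
  }
  # no-padding main path can be smaller than the stride-only shortcut:
  # crop the shortcut top-left so residual addition is defined
  blk$short_dims <- lapply(s, dim)
  z <- Map(function(m, sc) m + crop_to(sc, dim(m)[1], dim(m)[2]), h, s)
  layer_fwd(blk$relu3, z, training, update_stats)
}

block_bwd <- function(blk, gys, need_input = TRUE, need_pgrads = TRUE) {
  g <- layer_bwd(blk$relu3, gys, TRUE, need_pgrads)
  # shortcut branch: embed gradient back into the (possibly larger) pre-crop shape
  gshort <- Map(function(gz, d) {
    if (all(d[1:2] == dim(gz)[1:2])) gz
    else {
      big <- array(0, d)
      big[seq_len(dim(gz)[1]), seq_len(dim(gz)[2]), ] <- gz
      big
    }
  }, g, blk$short_dims)
  if (blk$has_short) {
    gs <- layer_bwd(blk$sbn, gshort, TRUE, need_pgrads)
    gs <- layer_bwd(blk$sconv, gs, need_input, need_pgrads)
  } else {
    gs <- gshort
  }
  gm <- layer_bwd(blk$bn3, g, TRUE, need_pgrads)
  gm <- layer_bwd(blk$conv3, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$relu2, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$bn2, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$conv2, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$relu1, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$bn1, gm, TRUE, need_pgrads)
  gm <- layer_bwd(blk$conv1, gm, need_input, need_pgrads)
  if (!need_input) return(NULL)
  Map(`+`, gm, gs)
}

# ---- parameter plumbing ---------------------------------------------------

collect_layers <- function(obj) {
  if (inherits(obj, "nn_layer")) {
    if (obj$type == "bottleneck") return(block_sublayers(obj))
    return(list(obj))
  }
  if (is.list(obj)) return(unlist(lapply(obj, collect_layers), recursive = FALSE))
  list()
}

#' Collect parameter references of a model component
#'
#' Returns a list of `(layer, name)` handles for every trainable array in the
#' object (a layer, a list of layers, or a model).
#' @param obj a layer, list of layers, or model object
#' @return list of parameter handles
#' @keywords internal
nn_parameters <- function(obj) {
  layers <- collect_layers(obj)
  out <- list()
  for (ly in layers) {
    for (nm in ly$param_names) {
      out[[length(out) + 1L]] <- list(layer = ly, name = nm)
    }
  }
  out
}

param_lengths <- function(params) {
  vapply(params, function(p) length(p$layer[[p$name]]), numeric(1))
}

#' @noRd
param_vector <- function(params) {
  unlist(lapply(params, function(p) as.numeric(p$layer[[p$name]])),
         use.names = FALSE)
}

#' @noRd
set_param_vector <- function(params, v) {
  off <- 0L
  for (p in params) {
    cur <- p$layer[[p$name]]
    n <- length(cur)
    new <- v[(off + 1L):(off + n)]
    if (!is.null(dim(cur))) dim(new) <- dim(cur)
    assign(p$name, new, envir = p$layer)
    off <- off + n
  }
  invisible(NULL)
}

#' @noRd
grad_vector <- function(params) {
  unlist(lapply(params, function(p) {
    g <- get0(paste0("g", p$name), envir = p$layer, ifnotfound = NULL)
    if (is.null(g)) numeric(length(p$layer[[p$name]])) else as.numeric(g)
  }), use.names = FALSE)
}

#' @noRd
zero_grads <- function(params) {
  for (p in params) assign(paste0("g", p$name), NULL, envir = p$layer)
  invisible(NULL)
}
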