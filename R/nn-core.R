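# Internal layer primitives for the CNN trainer.
#
# Convolutions and max pooling run through the compiled im2col kernels in
# src/nn_kernels.cpp (one BLAS multiplication per image); batch norm, dense
# layers, dropout and the loss are vectorised R. Gather/scatter indices are
# precomputed per layer at build time since the input size is fixed.
#
# Batch layout: conv stages use H x W x C x N arrays (column-major), dense
# stages use N x D matrices.

# im2col index matrix for a (Hp x Wp x C) input, k x k kernel, stride 1.
# Row order matches the column-major layout of a (k, k, C) weight block.
im2col_index <- function(Hp, Wp, C, k) {
  oh <- Hp - k + 1L; ow <- Wp - k + 1L
  dh <- rep(0:(k - 1L), times = k * C)
  dw <- rep(rep(0:(k - 1L), each = k), times = C)
  cc <- rep(0:(C - 1L), each = k * k)
  offs <- dh + Hp * dw + Hp * Wp * cc          # kernel offsets (0-based)
  ii <- rep(seq_len(oh), times = ow)
  jj <- rep(seq_len(ow), each = oh)
  base <- ii + Hp * (jj - 1L)                  # 1-based flat anchors
  outer(as.integer(offs), as.integer(base), `+`)
}

# pooling index matrix over one (H x W) plane, k x k window, given stride
pool_index <- function(H, W, k, stride) {
  oh <- (H - k) %/% stride + 1L; ow <- (W - k) %/% stride + 1L
  dh <- rep(0:(k - 1L), times = k)
  dw <- rep(0:(k - 1L), each = k)
  offs <- dh + H * dw
  ii <- rep(seq_len(oh), times = ow)
  jj <- rep(seq_len(ow), each = oh)
  base <- (stride * (ii - 1L) + 1L) + H * (stride * (jj - 1L))
  outer(as.integer(offs), as.integer(base), `+`)
}

xavier_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# ---- layer constructors ----------------------------------------------------

layer_conv <- function(in_shape, filters, k = 3L, pad = 0L, name = "conv") {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  oh <- Hp - k + 1L; ow <- Wp - k + 1L
  if (oh < 1 || ow < 1)
    stop("spatial collapse at stage ", sQuote(name),
         ": output size ", oh, "x", ow, call. = FALSE)
  k2c <- k * k * C
  list(type = "conv", name = name, k = k, pad = as.integer(pad),
       in_shape = as.integer(in_shape), out_shape = c(oh, ow, filters),
       idx = im2col_index(Hp, Wp, C, k),
       W = matrix(xavier_uniform(filters * k2c, k2c, k * k * filters),
                  filters, k2c),
       b = numeric(filters))
}

layer_bn <- function(channels, name = "bn", momentum = 0.9, eps = 1e-3) {
  list(type = "bn", name = name, channels = channels,
       momentum = momentum, eps = eps,
       gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

layer_relu <- function(name = "relu") list(type = "relu", name = name)

layer_pool <- function(in_shape, k = 3L, stride = 2L, name = "pool") {
  H <- in_shape[1]; W <- in_shape[2]
  oh <- (H - k) %/% stride + 1L; ow <- (W - k) %/% stride + 1L
  if (oh < 1 || ow < 1)
    stop("spatial collapse at stage ", sQuote(name),
         ": output size ", oh, "x", ow, call. = FALSE)
  list(type = "pool", name = name, k = k, stride = stride,
       in_shape = as.integer(in_shape), out_shape = c(oh, ow, in_shape[3]),
       idx = pool_index(H, W, k, stride))
}

layer_dropout <- function(rate, name = "dropout")
  list(type = "dropout", name = name, rate = rate)

layer_flatten <- function(in_shape, name = "flatten")
  list(type = "flatten", name = name, in_shape = in_shape,
       width = prod(in_shape))

layer_dense <- function(in_width, out_width, name = "dense") {
  list(type = "dense", name = name,
       W = matrix(xavier_uniform(in_width * out_width, in_width, out_width),
                  in_width, out_width),
       b = numeric(out_width))
}

layer_gap <- function(in_shape, name = "gap")
  list(type = "gap", name = name, in_shape = in_shape,
       width = in_shape[3])

# ---- forward / backward ----------------------------------------------------

# broadcast a per-channel vector over an (H x W x C x N) array
.bcast <- function(v, hw) rep(v, each = hw)

# per-channel sums of a 4-d array (over H, W and N)
.channel_sums <- function(A, hw, C, N) {
  .rowSums(matrix(.colSums(A, hw, C * N), C, N), C, N)
}

nn_forward_layer <- function(layer, X, train, cache_env) {
  cache <- NULL
  if (isTRUE(layer$frozen)) train <- FALSE  # frozen layers run in eval mode
  switch(layer$type,
    conv = {
      d <- dim(X); N <- d[4]
      if (layer$pad > 0) {
        p <- layer$pad
        Xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], N))
        Xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- X
      } else Xp <- X
      os <- layer$out_shape
      Y <- conv_forward_cpp(Xp, dim(Xp), layer$W, layer$b, layer$idx,
                            os[1], os[2])
      cache <- list(Xp = Xp, dimXp = dim(Xp))
      X <- Y
    },
    bn = {
      spatial <- length(dim(X)) == 4
      if (spatial) {
        d <- dim(X)
        hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
        M <- hw * N
        if (train && M > 1) {
          mu <- .channel_sums(X, hw, C, N) / M
          ctr <- X - .bcast(mu, hw)
          va <- .channel_sums(ctr * ctr, hw, C, N) / M
          layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
          layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
          assign(layer$name, layer, envir = cache_env$layers)
        } else {
          mu <- layer$run_mean
          ctr <- X - .bcast(mu, hw)
          va <- layer$run_var
        }
        inv_std <- 1 / sqrt(va + layer$eps)
        xhat <- ctr * .bcast(inv_std, hw)
        Y <- xhat * .bcast(layer$gamma, hw) + .bcast(layer$beta, hw)
        cache <- list(xhat = xhat, inv_std = inv_std, spatial = TRUE,
                      hw = hw, C = C, N = N, train_stats = train && M > 1)
      } else {
        M <- nrow(X)
        if (train && M > 1) {
          mu <- colMeans(X)
          ctr <- sweep(X, 2, mu)
          va <- colMeans(ctr * ctr)
          layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
          layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
          assign(layer$name, layer, envir = cache_env$layers)
        } else {
          mu <- layer$run_mean
          ctr <- sweep(X, 2, mu)
          va <- layer$run_var
        }
        inv_std <- 1 / sqrt(va + layer$eps)
        xhat <- sweep(ctr, 2, inv_std, `*`)
        Y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
        cache <- list(xhat = xhat, inv_std = inv_std, spatial = FALSE,
                      train_stats = train && M > 1)
      }
      X <- Y
    },
    relu = {
      cache <- list(mask = X > 0)
      X <- X * cache$mask
    },
    pool = {
      os <- layer$out_shape
      res <- pool_forward_cpp(X, dim(X), layer$idx, os[1], os[2])
      cache <- list(amax = res$amax, dimX = dim(X))
      X <- res$out
    },
    dropout = {
      if (train && layer$rate > 0) {
        keep <- stats::runif(length(X)) >= layer$rate
        scale <- 1 / (1 - layer$rate)
        cache <- list(keep = keep, scale = scale)
        X <- X * keep * scale
      }
    },
    flatten = {
      d <- dim(X)
      cache <- list(dimX = d)
      dim(X) <- c(prod(d[1:3]), d[4])
      X <- t(X)
    },
    gap = {
      d <- dim(X)
      cache <- list(dimX = d)
      dim(X) <- c(d[1] * d[2], d[3] * d[4])
      X <- matrix(colMeans(X), d[3], d[4])
      X <- t(X)
    },
    dense = {
      cache <- list(X = X)
      X <- X %*% layer$W + rep(layer$b, each = nrow(X))
    },
    stop("unknown layer type ", layer$type)
  )
  list(out = X, cache = cache)
}

nn_backward_layer <- function(layer, dY, cache, grads) {
  switch(layer$type,
    conv = {
      os <- layer$out_shape
      res <- conv_backward_cpp(cache$Xp, cache$dimXp, layer$W, dY,
                               layer$idx, os[1], os[2])
      grads$W <- res$dW
      grads$b <- as.numeric(res$db)
      dXp <- res$dXp
      dim(dXp) <- cache$dimXp
      if (layer$pad > 0) {
        p <- layer$pad
        H <- layer$in_shape[1]; W <- layer$in_shape[2]
        dXp <- dXp[(p + 1):(p + H), (p + 1):(p + W), , , drop = FALSE]
      }
      dXp
    },
    bn = {
      if (cache$spatial) {
        hw <- cache$hw; C <- cache$C; N <- cache$N
        M <- hw * N
        xhat <- cache$xhat
        grads$gamma <- .channel_sums(dY * xhat, hw, C, N)
        grads$beta <- .channel_sums(dY, hw, C, N)
        dxhat <- dY * .bcast(layer$gamma, hw)
        if (cache$train_stats) {
          s1 <- .channel_sums(dxhat, hw, C, N)
          s2 <- .channel_sums(dxhat * xhat, hw, C, N)
          dX <- (dxhat - .bcast(s1 / M, hw) - xhat * .bcast(s2 / M, hw)) *
            .bcast(cache$inv_std, hw)
        } else {
          dX <- dxhat * .bcast(cache$inv_std, hw)
        }
        dX
      } else {
        M <- nrow(dY)
        xhat <- cache$xhat
        grads$gamma <- colSums(dY * xhat)
        grads$beta <- colSums(dY)
        dxhat <- sweep(dY, 2, layer$gamma, `*`)
        if (cache$train_stats) {
          s1 <- colSums(dxhat)
          s2 <- colSums(dxhat * xhat)
          dX <- sweep(dxhat, 2, s1 / M) - sweep(xhat, 2, s2 / M, `*`)
          dX <- sweep(dX, 2, cache$inv_std, `*`)
        } else {
          dX <- sweep(dxhat, 2, cache$inv_std, `*`)
        }
        dX
      }
    },
    relu = dY * cache$mask,
    pool = {
      pool_backward_cpp(dY, cache$amax, layer$idx, cache$dimX)
    },
    dropout = {
      if (is.null(cache)) dY else dY * cache$keep * cache$scale
    },
    flatten = {
      dX <- t(dY)
      dim(dX) <- cache$dimX
      dX
    },
    gap = {
      d <- cache$dimX
      hw <- d[1] * d[2]
      array(rep(t(dY) / hw, each = hw), d)
    },
    dense = {
      grads$W <- crossprod(cache$X, dY)
      grads$b <- colSums(dY)
      dY %*% t(layer$W)
    },
    stop("unknown layer type ", layer$type)
  )
}

# full forward pass; returns logits and per-layer caches
nn_forward <- function(model, X, train = FALSE) {
  cache_env <- list(layers = new.env(parent = emptyenv()))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    res <- nn_forward_layer(model$layers[[i]], X, train, cache_env)
    X <- res$out
    caches[[i]] <- res$cache
  }
  # collect BN running-stat updates written during the pass
  for (nm in ls(cache_env$layers)) {
    for (i in seq_along(model$layers))
      if (identical(model$layers[[i]]$name, nm))
        model$layers[[i]] <- get(nm, envir = cache_env$layers)
  }
  list(out = X, caches = caches, model = model)
}

# backward pass from d(logits); returns per-layer gradient list
nn_backward <- function(model, caches, dY, stop_at = 0L) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    if (i <= stop_at) break
    g <- new.env(parent = emptyenv())
    dY <- nn_backward_layer(model$layers[[i]], dY, caches[[i]], g)
    grads[[i]] <- as.list(g)
  }
  grads
}

trainable_param_names <- function(layer) {
  switch(layer$type,
    conv = c("W", "b"),
    dense = c("W", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

n_trainable_params <- function(model, layers = seq_along(model$layers)) {
  total <- 0L
  for (i in layers) {
    layer <- model$layers[[i]]
    for (p in trainable_param_names(layer)) total <- total + length(layer[[p]])
  }
  total
}

# sum of |W| over weight matrices (conv + dense kernels; not biases or BN)
l1_weight_norm <- function(model, layers = seq_along(model$layers)) {
  s <- 0
  for (i in layers) {
    layer <- model$layers[[i]]
    if (layer$type %in% c("conv", "dense")) s <- s + sum(abs(layer$W))
  }
  s
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy from logits, mean over all entries
bce_from_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}
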