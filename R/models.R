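#' CranioNet architecture specification
#'
#' CranioNet is a compact from-scratch CNN for multilabel tool presence:
#' a sequence of blocks of two 3 x 3 stride-1 convolutions followed by a
#' 3 x 3 stride-2 max pooling, with batch normalisation and reLU after
#' every convolution and 0.25 dropout after each block. Only the first
#' block's convolutions are padded (P = 1); the rest are valid. The
#' convolutional stack feeds a hidden dense layer (reLU, batch norm,
#' 0.5 dropout) and a sigmoid output over the 10 labels.
#'
#' The default (3 blocks of 32/64/128 filters, hidden width 512) is the
#' shallowest standard filter doubling that keeps all valid-padded spatial
#' sizes positive from a 64 x 64 input (trace 64 -> ... -> 4).
#'
#' @param filters Integer vector of per-block filter counts.
#' @param dense_width Width of the hidden dense layer.
#' @param input_size Input side length in pixels (default 64).
#' @param n_out Number of output labels (default 10).
#' @param conv_dropout,dense_dropout Dropout probabilities (0.25 / 0.5).
#' @return A list of class `cranionet_spec`.
#' @export
cranionet_spec <- function(filters = c(32L, 64L, 128L), dense_width = 512L,
                           input_size = 64L, n_out = n_labels(),
                           conv_dropout = 0.25, dense_dropout = 0.5) {
  stopifnot(length(filters) >= 1, all(filters >= 1), dense_width >= 1,
            input_size >= 8, n_out >= 1)
  structure(list(filters = as.integer(filters),
                 dense_width = as.integer(dense_width),
                 input_size = as.integer(input_size),
                 n_out = as.integer(n_out),
                 conv_dropout = conv_dropout, dense_dropout = dense_dropout),
            class = "cranionet_spec")
}

#' Spatial size trace of a CranioNet spec
#'
#' Applies the convolution arithmetic of the spec stage by stage: padded
#' 3 x 3 convolutions keep the size, valid ones shrink it by 2, and the
#' 3 x 3 stride-2 pooling maps `s` to `floor((s - 3) / 2) + 1`. An error
#' naming the stage is raised if any size drops below 1.
#'
#' @param spec A [cranionet_spec()].
#' @return Named integer vector of sizes: `input`, then `conv<b>_1`,
#'   `conv<b>_2`, `pool<b>` per block.
#' @export
#' @examples
#' cranionet_spatial_trace(cranionet_spec())
cranionet_spatial_trace <- function(spec) {
  s <- spec$input_size
  out <- c(input = s)
  for (b in seq_along(spec$filters)) {
    pad <- if (b == 1) 1L else 0L
    for (j in 1:2) {
      s <- s + 2L * pad - 2L
      nm <- sprintf("conv%d_%d", b, j)
      if (s < 1) stop("spatial collapse at stage ", sQuote(nm), call. = FALSE)
      out[nm] <- s
    }
    s <- (s - 3L) %/% 2L + 1L
    nm <- sprintf("pool%d", b)
    if (s < 1) stop("spatial collapse at stage ", sQuote(nm), call. = FALSE)
    out[nm] <- s
  }
  out
}

#' Build a CranioNet model
#'
#' Weights use Xavier (Glorot uniform) initialisation, biases start at
#' zero, batch-norm scales at one. The returned model maps a
#' `size x size x 3 x N` batch to per-label probabilities via
#' [predict_proba()].
#'
#' @param spec A [cranionet_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A model object (list with class `cranio_model`).
#' @export
#' @examples
#' m <- build_cranionet(cranionet_spec(filters = c(8, 16), dense_width = 32),
#'                      seed = 1)
#' model_param_count(m)
build_cranionet <- function(spec = cranionet_spec(), seed = 1L) {
  cranionet_spatial_trace(spec)  # fail early, naming the offending stage
  with_local_seed(seed, {
    layers <- list()
    shape <- c(spec$input_size, spec$input_size, 3L)
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    for (b in seq_along(spec$filters)) {
      pad <- if (b == 1) 1L else 0L
      f <- spec$filters[b]
      for (j in 1:2) {
        cv <- layer_conv(shape, f, pad = pad, name = sprintf("conv%d_%d", b, j))
        shape <- cv$out_shape
        add(cv)
        add(layer_bn(f, name = sprintf("bn%d_%d", b, j)))
        add(layer_relu(name = sprintf("relu%d_%d", b, j)))
      }
      pl <- layer_pool(shape, name = sprintf("pool%d", b))
      shape <- pl$out_shape
      add(pl)
      add(layer_dropout(spec$conv_dropout, name = sprintf("drop%d", b)))
    }
    add(layer_flatten(shape, name = "flatten"))
    add(layer_dense(prod(shape), spec$dense_width, name = "dense_hidden"))
    add(layer_bn(spec$dense_width, name = "bn_dense"))
    add(layer_relu(name = "relu_dense"))
    add(layer_dropout(spec$dense_dropout, name = "drop_dense"))
    add(layer_dense(spec$dense_width, spec$n_out, name = "dense_out"))
    structure(list(layers = layers, spec = spec, kind = "cranionet",
                   input_shape = c(spec$input_size, spec$input_size, 3L),
                   n_out = spec$n_out, frozen_until = 0L),
              class = "cranio_model")
  })
}

#' Frozen random convolutional backbone
#'
#' A fixed, seeded convolutional feature extractor used to exercise the
#' transfer-learning path without downloading pretrained weights: two
#' valid 3 x 3 convolution + reLU + 3 x 3 stride-2 pool stages with
#' Xavier-initialised weights that never update.
#'
#' @param channels Output feature-map depth.
#' @param seed Integer seed fixing the weights.
#' @param input_size Input side length (default 64).
#' @return A `backbone_adapter` (list with frozen `layers` and `out_shape`).
#' @export
random_backbone <- function(channels = 16L, seed = 1L, input_size = 64L) {
  with_local_seed(seed, {
    shape <- c(input_size, input_size, 3L)
    c1 <- layer_conv(shape, 8L, name = "bb_conv1")
    p1 <- layer_pool(c1$out_shape, name = "bb_pool1")
    c2 <- layer_conv(p1$out_shape, channels, name = "bb_conv2")
    p2 <- layer_pool(c2$out_shape, name = "bb_pool2")
    layers <- list(c1, layer_relu("bb_relu1"), p1,
                   c2, layer_relu("bb_relu2"), p2)
    layers <- lapply(layers, function(l) { l$frozen <- TRUE; l })
    structure(list(layers = layers, out_shape = p2$out_shape,
                   input_shape = shape, name = "random_backbone"),
              class = "backbone_adapter")
  })
}

#' Build a transfer-learning model on a frozen backbone
#'
#' The head follows the transfer recipe: global average pooling over the
#' backbone's spatial feature map, 0.5 dropout, and a dense sigmoid
#' classifier over the labels. Only the head's dense layer (C x L weights +
#' L biases) is trainable; backbone parameters never update.
#'
#' @param backbone A `backbone_adapter` (e.g. [random_backbone()]) whose
#'   layers emit an `h x w x C` spatial feature map.
#' @param n_out Number of labels (default 10).
#' @param seed Seed for head initialisation.
#' @param dropout Head dropout probability (default 0.5).
#' @return A model object of class `cranio_model`.
#' @export
build_transfer_model <- function(backbone, n_out = n_labels(), seed = 1L,
                                 dropout = 0.5) {
  if (!inherits(backbone, "backbone_adapter"))
    stop("backbone must be a backbone_adapter", call. = FALSE)
  if (length(backbone$out_shape) != 3)
    stop("backbone must emit a spatial (h x w x C) feature map", call. = FALSE)
  with_local_seed(seed, {
    C <- backbone$out_shape[3]
    layers <- c(backbone$layers,
                list(layer_gap(backbone$out_shape, name = "gap"),
                     layer_dropout(dropout, name = "drop_head"),
                     layer_dense(C, n_out, name = "dense_out")))
    structure(list(layers = layers, spec = NULL, kind = "transfer",
                   input_shape = backbone$input_shape, n_out = n_out,
                   frozen_until = length(backbone$layers)),
              class = "cranio_model")
  })
}

#' Number of trainable parameters of a model
#'
#' Counts convolution and dense kernels and biases plus batch-norm scale
#' and shift parameters, excluding layers frozen by transfer learning.
#'
#' @param model A `cranio_model`.
#' @param trainable_only Exclude frozen (backbone) layers (default TRUE).
#' @return Integer parameter count.
#' @export
model_param_count <- function(model, trainable_only = TRUE) {
  idx <- seq_along(model$layers)
  if (trainable_only && model$frozen_until > 0)
    idx <- idx[idx > model$frozen_until]
  n_trainable_params(model, idx)
}

#' Predict per-label probabilities
#'
#' Runs the model in evaluation mode (batch statistics frozen, dropout off)
#' and applies the sigmoid, treating every label independently.
#'
#' @param model A `cranio_model`.
#' @param X An `H x W x 3` image or an `H x W x 3 x N` batch array.
#' @return N x 10 matrix of probabilities in (0, 1), canonical label columns.
#' @export
predict_proba <- function(model, X) {
  if (length(dim(X)) == 3) dim(X) <- c(dim(X), 1L)
  stopifnot(length(dim(X)) == 4,
            all(dim(X)[1:3] == model$input_shape))
  z <- nn_forward(model, X, train = FALSE)$out
  p <- sigmoid(z)
  colnames(p) <- tool_labels()[seq_len(ncol(p))]
  p
}

#' @export
print.cranio_model <- function(x, ...) {
  cat(sprintf("<cranio_model: %s>\n", x$kind))
  cat(sprintf("  input %dx%dx%d -> %d labels\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3], x$n_out))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    np <- n_trainable_params(x, i)
    cat(sprintf("  %-12s %-10s%s%s\n", l$name, l$type,
                if (np > 0) sprintf(" params %-9d", np) else "",
                if (isTRUE(l$frozen)) " [frozen]" else ""))
  }
  cat(sprintf("  trainable parameters: %d\n", model_param_count(x)))
  invisible(x)
}

#' Architecture descriptor of a model
#'
#' A JSON-serialisable summary: one entry per layer with its type, name,
#' shapes and parameter count, plus totals.
#'
#' @param model A `cranio_model`.
#' @return A list.
#' @export
model_descriptor <- function(model) {
  layers <- lapply(seq_along(model$layers), function(i) {
    l <- model$layers[[i]]
    n <- n_trainable_params(model, i)
    entry <- list(type = l$type, name = l$name, params = n)
    if (!is.null(l$out_shape)) entry$out_shape <- as.integer(l$out_shape)
    if (isTRUE(l$frozen)) entry$frozen <- TRUE
    entry
  })
  list(kind = model$kind, input_shape = as.integer(model$input_shape),
       n_out = model$n_out,
       trainable_params = model_param_count(model),
       layers = layers)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the full model (weights, batch-norm
#' running statistics, architecture); a JSON architecture descriptor is
#' written alongside as `<path>.json`.
#'
#' @param model A `cranio_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model_descriptor(model), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cranio_model"))
    stop("not a cranio_model checkpoint: ", path, call. = FALSE)
  model
}
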