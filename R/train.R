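#' Training configuration
#'
#' The training recipe: binary cross-entropy with weighted L1 regularisation
#' of the kernels, Adam (first-moment decay 0.9, epsilon 1e-8; second
#' moment at the conventional 0.999), batches of 64. From scratch the
#' learning rate is 1e-4 over 20 epochs; for transfer heads use 1e-5 over
#' 10 epochs ([transfer_train_config()]).
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs Number of passes over the training set (default 20).
#' @param batch_size Mini-batch size (default 64).
#' @param lambda_l1 Weight of the L1 penalty on convolution/dense kernels
#'   (default 1e-5; 0 disables).
#' @param beta1,beta2,epsilon Adam moment decays and stabiliser.
#' @param seed Seed controlling shuffling, dropout and augmentation; the
#'   whole run is reproducible given the seed.
#' @param augment An [augment_config()] applied on the fly to training
#'   batches, or `NULL` for none. Validation is never augmented.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 20L, batch_size = 64L,
                         lambda_l1 = 1e-5, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 42L,
                         augment = augment_config()) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, lambda_l1 >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lambda_l1 = lambda_l1,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
transfer_train_config <- function(...) {
  cfg <- train_config(learning_rate = 1e-5, epochs = 10L, ...)
  cfg
}

#' Read a training configuration from YAML
#'
#' Recognised top-level keys mirror the [train_config()] arguments; an
#' `augment:` mapping holds [augment_config()] fields (`augment: null`
#' disables augmentation).
#'
#' @param path YAML file path.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  aug <- if (is.null(y$augment)) NULL else do.call(augment_config, y$augment)
  y$augment <- NULL
  cfg <- do.call(train_config, y)
  cfg$augment <- aug
  cfg
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    ps <- trainable_param_names(l)
    stats::setNames(lapply(ps, function(p)
      list(m = array(0, dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim(l[[p]]) %||% length(l[[p]])))), ps)
  })
}

adam_step <- function(model, grads, state, t, cfg) {
  lr <- cfg$learning_rate
  corr1 <- 1 - cfg$beta1^t
  corr2 <- 1 - cfg$beta2^t
  for (i in seq_along(model$layers)) {
    if (i <= model$frozen_until) next
    layer <- model$layers[[i]]
    g <- grads[[i]]
    if (is.null(g) || !length(g)) next
    for (p in trainable_param_names(layer)) {
      gp <- g[[p]]
      if (cfg$lambda_l1 > 0 && p == "W" && layer$type %in% c("conv", "dense"))
        gp <- gp + cfg$lambda_l1 * sign(layer[[p]])
      st <- state[[i]][[p]]
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * gp
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * gp * gp
      state[[i]][[p]] <- st
      layer[[p]] <- layer[[p]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + cfg$epsilon)
    }
    model$layers[[i]] <- layer
  }
  list(model = model, state = state)
}

# loss (BCE + L1 penalty) and d(loss)/d(logits) for one batch
batch_loss <- function(model, z, y, cfg) {
  data_loss <- bce_from_logits(z, y)
  penalty <- if (cfg$lambda_l1 > 0)
    cfg$lambda_l1 * l1_weight_norm(model,
      seq_along(model$layers)[seq_along(model$layers) > model$frozen_until])
  else 0
  list(loss = data_loss + penalty,
       dz = (sigmoid(z) - y) / length(y))
}

#' Evaluate the loss of a model on a set of items
#'
#' Runs in evaluation mode (no dropout, batch-norm running statistics, no
#' augmentation).
#'
#' @param model A `cranio_model`.
#' @param items List of items with preprocessed `$image` and `$labels`.
#' @param cfg A [train_config()] (for the L1 weight and batch size).
#' @return Mean loss over the items.
#' @export
evaluate_loss <- function(model, items, cfg = train_config()) {
  stopifnot(length(items) >= 1)
  total <- 0
  batches <- split(seq_along(items), (seq_along(items) - 1L) %/% cfg$batch_size)
  for (ix in batches) {
    X <- stack_images(lapply(items[ix], `[[`, "image"))
    y <- labels_matrix(items[ix])
    z <- nn_forward(model, X, train = FALSE)$out
    total <- total + bce_from_logits(z, y) * length(ix)
  }
  pen <- if (cfg$lambda_l1 > 0)
    cfg$lambda_l1 * l1_weight_norm(model,
      seq_along(model$layers)[seq_along(model$layers) > model$frozen_until])
  else 0
  total / length(items) + pen
}

#' Train a model
#'
#' Minimises binary cross-entropy plus the weighted L1 kernel penalty with
#' Adam over shuffled mini-batches, applying the augmentation transforms on
#' the fly to training images only. Batch-norm layers use batch statistics
#' during training and exponentially averaged running statistics for
#' validation. The run is fully reproducible given `cfg$seed`. Training
#' aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A `cranio_model` from [build_cranionet()] or
#'   [build_transfer_model()].
#' @param train_items Non-empty list of items with preprocessed `$image`
#'   (arrays matching the model input) and `$labels` (one-hot vectors).
#' @param val_items Optional validation items (loss recorded per epoch).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (trained) and `history` (data.frame with
#'   columns `epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, train_items, val_items = NULL,
                        cfg = train_config(), verbose = FALSE) {
  if (!length(train_items)) stop("empty training set", call. = FALSE)
  if (!all(vapply(train_items, function(it)
    identical(dim(it$image), as.integer(model$input_shape)), logical(1))))
    stop("training images must match the model input shape; run preprocess_frame()",
         call. = FALSE)
  with_local_seed(cfg$seed, {
    state <- adam_init(model)
    t <- 0L
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    n <- length(train_items)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, (seq_along(perm) - 1L) %/% cfg$batch_size)
      epoch_loss <- 0
      for (ix in batches) {
        imgs <- lapply(train_items[ix], `[[`, "image")
        if (!is.null(cfg$augment))
          imgs <- lapply(imgs, augment_frame, cfg = cfg$augment)
        X <- stack_images(imgs)
        y <- labels_matrix(train_items[ix])
        fwd <- nn_forward(model, X, train = TRUE)
        model <- fwd$model  # batch-norm running stats advanced
        bl <- batch_loss(model, fwd$out, y, cfg)
        if (!is.finite(bl$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (diverged; lower the learning rate)", call. = FALSE)
        epoch_loss <- epoch_loss + bl$loss * length(ix)
        grads <- nn_backward(model, fwd$caches, bl$dz,
                             stop_at = model$frozen_until)
        t <- t + 1L
        st <- adam_step(model, grads, state, t, cfg)
        model <- st$model
        state <- st$state
      }
      train_loss <- epoch_loss / n
      val_loss <- if (length(val_items)) evaluate_loss(model, val_items, cfg)
                  else NA_real_
      history[epoch, ] <- list(epoch, train_loss, val_loss)
      if (verbose)
        message(sprintf("epoch %d/%d  train %.4f  val %s", epoch, cfg$epochs,
                        train_loss,
                        if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
    }
    list(model = model, history = history)
  })
}

#' Write a loss history as CSV
#'
#' Columns: `epoch`, `train_loss`, `val_loss`.
#'
#' @param history Data frame as returned in `train_model()$history`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Exact-match accuracy of a model on items
#'
#' Fraction (percent) of items whose thresholded predicted label set equals
#' the ground-truth set over all 10 labels.
#'
#' @param model A `cranio_model`.
#' @param items List of items with `$image` and `$labels`.
#' @param threshold Detection threshold (default 0.5).
#' @param batch_size Inference batch size.
#' @return Percentage in \[0, 100\].
#' @export
model_exact_match <- function(model, items, threshold = 0.5,
                              batch_size = 64L) {
  stopifnot(length(items) >= 1)
  truth <- labels_matrix(items)
  batches <- split(seq_along(items), (seq_along(items) - 1L) %/% batch_size)
  probs <- do.call(rbind, lapply(batches, function(ix)
    predict_proba(model, stack_images(lapply(items[ix], `[[`, "image")))))
  pred_sets <- lapply(seq_len(nrow(probs)), function(i)
    threshold_detections(unname(probs[i, ]), threshold))
  exact_match_accuracy(pred_sets, truth)
}
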