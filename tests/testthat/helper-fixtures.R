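# Shared fixture builders: everything is generated in code at test time.

# a small rendered item set covering the given label sets
render_items <- function(label_sets, n_per = 3, seed = 101,
                         cfg = scene_config(seed = seed), size = NULL) {
  items <- list()
  k <- 0L
  for (ls in label_sets) {
    for (j in seq_len(n_per)) {
      k <- k + 1L
      fr <- render_frame(ls, cfg, seed = seed + k)
      img <- if (is.null(size)) fr$image else preprocess_frame(fr$image, size)
      items[[k]] <- list(image = img, labels = fr$labels)
    }
  }
  items
}

# tiny CranioNet used wherever a real forward/backward pass is needed
tiny_spec <- function(input_size = 16L, n_out = 4L) {
  cranionet_spec(filters = c(3L, 4L), dense_width = 8L,
                 input_size = input_size, n_out = n_out)
}

# model with constant output probabilities (logit-parameterised head)
constant_model <- function(probs) {
  stopifnot(length(probs) == n_labels())
  m <- build_transfer_model(random_backbone(channels = 4L, seed = 1),
                            n_out = n_labels(), seed = 1)
  i <- length(m$layers)  # dense_out is last
  m$layers[[i]]$W[] <- 0
  m$layers[[i]]$b <- stats::qlogis(probs)
  m
}

# detection log with the given per-frame detected label sets (0.9/0.1 probs)
log_from_sets <- function(sets, frame_rate = 15) {
  probs <- do.call(rbind, lapply(sets, function(s)
    labels_to_vector(s) * 0.8 + 0.1))
  detection_log(probs, frame_rate = frame_rate)
}

random_label_sets <- function(n, p = 0.25) {
  lapply(seq_len(n), function(i)
    tool_labels()[stats::runif(n_labels()) < p])
}
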