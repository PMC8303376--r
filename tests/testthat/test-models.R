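test_that("the default spec's spatial trace follows convolution arithmetic", {
  # hand-computed: padded convs keep 64; valid convs shrink by 2;
  # 3x3 stride-2 pooling maps s -> floor((s - 3) / 2) + 1
  tr <- cranionet_spatial_trace(cranionet_spec())
  expect_identical(unname(tr),
                   c(64L, 64L, 64L, 31L, 29L, 27L, 13L, 11L, 9L, 4L))
  expect_named(tr, c("input", "conv1_1", "conv1_2", "pool1", "conv2_1",
                     "conv2_2", "pool2", "conv3_1", "conv3_2", "pool3"))
})

test_that("a spec whose spatial size collapses is rejected by stage name", {
  bad <- cranionet_spec(filters = c(8, 16, 32, 64))  # block 4 from 4x4: 2 -> 0
  expect_error(cranionet_spatial_trace(bad), "conv4_2")
  expect_error(build_cranionet(bad), "conv4_2")
})

test_that("parameter count matches the layer-by-layer closed form", {
  # independent oracle: conv k^2*Cin*F + F; BN 2 per channel;
  # dense Din*Dout + Dout; pooling/dropout/flatten contribute nothing
  closed_form <- function(filters, dense_width, n_out = 10L) {
    total <- 0L
    cin <- 3L
    for (f in filters) {
      total <- total + (9L * cin * f + f) + 2L * f  # conv1 + bn
      total <- total + (9L * f * f + f) + 2L * f    # conv2 + bn
      cin <- f
    }
    tr <- cranionet_spatial_trace(cranionet_spec(filters, dense_width))
    flat <- unname(tr[length(tr)])^2 * filters[length(filters)]
    as.integer(total + (flat * dense_width + dense_width) + 2L * dense_width +
                 (dense_width * n_out + n_out))
  }
  for (cfgs in list(list(c(32L, 64L, 128L), 512L),
                    list(c(8L, 16L), 64L))) {
    m <- build_cranionet(cranionet_spec(cfgs[[1]], cfgs[[2]]), seed = 1)
    expect_identical(model_param_count(m),
                     closed_form(cfgs[[1]], cfgs[[2]]))
  }
})

test_that("forward pass maps batches to per-label sigmoid outputs", {
  m <- build_cranionet(tiny_spec(), seed = 3)
  X <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
  p <- predict_proba(m, X)
  expect_identical(dim(p), c(5L, 4L))
  expect_true(all(p > 0 & p < 1))
  # single image convenience
  p1 <- predict_proba(m, X[, , , 1])
  expect_equal(unname(p1), unname(p[1, , drop = FALSE]), tolerance = 1e-12)
})

test_that("the transfer head adds exactly C*L + L trainable parameters", {
  bb <- random_backbone(channels = 8, seed = 2)
  m <- build_transfer_model(bb, n_out = 10, seed = 3)
  expect_identical(model_param_count(m), 8L * 10L + 10L)
  expect_identical(dim(predict_proba(m, array(runif(64 * 64 * 3), c(64, 64, 3)))),
                   c(1L, 10L))
  expect_error(build_transfer_model(list(out_shape = c(4, 4, 8))),
               "backbone_adapter")
})

test_that("global average pooling of a constant feature map gives that constant", {
  l <- cranioflow:::layer_gap(c(3L, 3L, 5L))
  X <- array(2.5, c(3, 3, 5, 2))
  res <- cranioflow:::nn_forward_layer(l, X, train = FALSE,
                                       list(layers = new.env()))
  expect_equal(res$out, matrix(2.5, 2, 5))
})

test_that("backbone weights stay bitwise frozen through training", {
  bb <- random_backbone(channels = 4, seed = 5)
  m <- build_transfer_model(bb, n_out = 10, seed = 6)
  before <- lapply(m$layers[seq_len(m$frozen_until)], function(l) l$W)
  items <- render_items(list("Motor", "Scalpel"), n_per = 4, seed = 40)
  fit <- train_model(m, items,
                     cfg = train_config(epochs = 1, batch_size = 4, seed = 1,
                                        augment = NULL))
  after <- lapply(fit$model$layers[seq_len(m$frozen_until)], function(l) l$W)
  expect_identical(before, after)
})

test_that("the L1 penalty never lowers the loss on identical weights", {
  m <- build_cranionet(tiny_spec(n_out = 10L), seed = 7)
  items <- render_items(list("Motor"), n_per = 3, seed = 50, size = 16)
  l0 <- evaluate_loss(m, items, train_config(lambda_l1 = 0))
  l1 <- evaluate_loss(m, items, train_config(lambda_l1 = 1e-3))
  expect_gt(l1, l0)
})

test_that("training loss decreases on a degenerate constant-label set", {
  spec <- cranionet_spec(filters = c(3L, 4L), dense_width = 8L,
                         input_size = 16L, n_out = 10L,
                         conv_dropout = 0, dense_dropout = 0)
  m <- build_cranionet(spec, seed = 8)
  fr <- render_frame("Motor", scene_config(seed = 60), seed = 61)
  items <- list(list(image = preprocess_frame(fr$image, 16),
                     labels = fr$labels))
  cfg <- train_config(learning_rate = 1e-3, epochs = 5, batch_size = 1,
                      lambda_l1 = 0, seed = 2, augment = NULL)
  fit <- train_model(m, items, cfg = cfg)
  expect_identical(nrow(fit$history), 5L)
  expect_true(all(diff(fit$history$train_loss) < 0))
})

test_that("training is reproducible: same seed gives identical histories", {
  items <- render_items(list("Motor", c("Forceps", "Scalpel")), n_per = 3,
                        seed = 70, size = 16)
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 9)
  m <- build_cranionet(tiny_spec(input_size = 16, n_out = 10), seed = 10)
  f1 <- train_model(m, items, cfg = cfg)
  f2 <- train_model(m, items, cfg = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("checkpoints round-trip through save/load with a JSON descriptor", {
  m <- build_cranionet(tiny_spec(), seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  desc <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(desc$trainable_params, model_param_count(m))
  back <- load_model(path)
  X <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  expect_identical(predict_proba(back, X), predict_proba(m, X))
})

test_that("training configs load from YAML with augmentation overrides", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("learning_rate: 1.0e-3", "epochs: 3", "batch_size: 16",
               "augment:", "  rotation: 5", "  horizontal_flip: false"), path)
  cfg <- read_train_config(path)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_identical(cfg$epochs, 3L)
  expect_equal(cfg$augment$rotation, 5)
  expect_false(cfg$augment$horizontal_flip)
  writeLines(c("epochs: 2", "augment: null"), path)
  expect_null(read_train_config(path)$augment)
})
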