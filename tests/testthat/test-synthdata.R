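test_that("rendered frames carry the requested labels and are deterministic", {
  cfg <- scene_config(seed = 5)
  fr <- render_frame(character(0), cfg, seed = 9)
  expect_identical(dim(fr$image), c(64L, 64L, 3L))
  expect_true(all(fr$image >= 0 & fr$image <= 1))
  expect_identical(vector_to_labels(fr$labels), "Environment")

  fr2 <- render_frame(character(0), cfg, seed = 9)
  expect_identical(fr, fr2)  # bit-identical under the same seed

  fr3 <- render_frame(c("Motor", "Scalpel"), cfg, seed = 9)
  expect_setequal(vector_to_labels(fr3$labels),
                  c("Motor", "Scalpel", "Environment"))

  # without the phantom/backdrop the Environment bit is clear
  off <- scene_config(seed = 5, environment_visible = FALSE)
  expect_identical(sum(render_frame(character(0), off, seed = 1)$labels), 0L)
})

test_that("each tool glyph is separable from background by mean colour", {
  # brute-force pixel-statistic classifier as a learnability oracle
  cfg <- scene_config(seed = 31, occluder_prob = 0)
  n <- 60
  bg <- lapply(seq_len(n), function(i)
    render_frame(character(0), cfg, seed = 5000 + i)$image)
  cols <- cranioflow:::.glyph_colors()
  for (tool in setdiff(tool_labels(), "Environment")) {
    pos <- lapply(seq_len(n), function(i)
      render_frame(tool, cfg, seed = 7000 + i)$image)
    col <- cols[[tool]]
    score <- function(img) {
      img <- img * 0.35 / mean(img)  # cancel the global brightness draw
      d2 <- (img[, , 1] - col[1])^2 + (img[, , 2] - col[2])^2 +
            (img[, , 3] - col[3])^2
      mean(d2 < 0.08)
    }
    s_pos <- vapply(pos, score, numeric(1))
    s_bg <- vapply(bg, score, numeric(1))
    thr <- (mean(s_pos) + mean(s_bg)) / 2
    acc <- (sum(s_pos > thr) + sum(s_bg <= thr)) / (2 * n)
    expect_gte(acc, 0.95)
  }
})

test_that("training-set generation writes the expected folder tree", {
  d <- withr::local_tempdir()
  man <- generate_training_set(d, frames_per_combination = 2,
                               cfg = scene_config(seed = 3))
  folders <- list.dirs(d, recursive = FALSE, full.names = FALSE)
  expect_length(folders, 13L)
  pngs <- list.files(d, pattern = "\\.png$", recursive = TRUE)
  expect_length(pngs, 26L)
  expect_true(file.exists(file.path(d, "manifest.json")))
  # the default preset: 11 phase combinations + phantom + hands variant
  expect_true(all(c("Environment", "Environment.hands") %in% folders))
  expect_true(folder_name_from_labels(c(phase_tools("P4"), "Environment"))
              %in% folders)
  counts <- vapply(man$folders, function(f) f$n_frames, integer(1))
  expect_identical(sum(counts), 26L)
})

test_that("identical seeds reproduce identical folder trees byte-for-byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_training_set(d1, frames_per_combination = 1,
                        cfg = scene_config(seed = 17))
  generate_training_set(d2, frames_per_combination = 1,
                        cfg = scene_config(seed = 17))
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("frame totals split as evenly as integer division allows", {
  per <- distribute_frames(10000, 13)
  expect_identical(sum(per), 10000L)
  expect_lte(diff(range(per)), 1L)
  expect_identical(distribute_frames(26, 13), rep(2L, 13))
})

test_that("surgery video frames carry the covering phase's tool set", {
  tl <- timeline(phase_ids(), rep(1L, 11))  # one frame per phase
  vid <- generate_surgery_video(tl, scene_config(seed = 23))
  expect_length(vid$frames, 11L)
  expect_identical(vid$timeline, tl)
  for (t in 1:11) {
    want <- labels_to_vector(c(phase_tools(tl$phase[t]), "Environment"))
    expect_identical(vid$labels[t, ], want)
  }
  # 11 distinct label vectors (phase tool sets are pairwise distinct)
  expect_identical(anyDuplicated(apply(vid$labels, 1, paste, collapse = "")), 0L)
})

test_that("surgery video writes frames and ground-truth timeline to disk", {
  d <- withr::local_tempdir()
  tl <- surgery_timeline(n_frames = 22)
  vid <- generate_surgery_video(tl, scene_config(seed = 2), out_dir = d)
  expect_length(list.files(d, pattern = "\\.png$"), 22L)
  back <- read_timeline(file.path(d, "timeline.json"))
  expect_equal(as.data.frame(back), as.data.frame(tl))
})

test_that("zero-noise simulated logs reproduce the ground truth exactly", {
  tl <- surgery_timeline(n_frames = 150)
  log <- simulate_detection_log(tl, noise_model(), seed = 4)
  expect_identical(nrow(log), 150L)
  sets <- detected_sets(log)
  for (t in seq_len(150)) {
    want <- c(phase_tools(timeline_phase_at(tl, t - 1L)), "Environment")
    expect_setequal(sets[[t]], want)
  }
})

test_that("simulated logs are byte-identical under the same seed", {
  tl <- surgery_timeline(n_frames = 120)
  nm <- noise_model(flip_rate = 0.1, jitter = 4, dropout_rate = 0.05)
  a <- simulate_detection_log(tl, nm, seed = 99)
  b <- simulate_detection_log(tl, nm, seed = 99)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_log(a, p1); write_log(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("detection flips occur at the configured empirical rate", {
  tl <- timeline("P1", 10000L)
  rate <- 0.07
  log <- simulate_detection_log(tl, noise_model(flip_rate = rate), seed = 8)
  truth <- labels_to_vector(c("Scalpel", "Environment"))
  det <- do.call(rbind, lapply(detected_sets(log), labels_to_vector))
  flip_freq <- colMeans(det != matrix(truth, 10000, 10, byrow = TRUE))
  expect_true(all(abs(flip_freq - rate) < 0.02))
})

test_that("full dropout empties every frame and full flip inverts detections", {
  tl <- timeline("P6", 50L)
  log <- simulate_detection_log(tl, noise_model(dropout_rate = 1), seed = 1)
  expect_true(all(log$detected == "None"))
  log2 <- simulate_detection_log(tl, noise_model(flip_rate = 1), seed = 1)
  want <- setdiff(tool_labels(), c("Motor", "Environment"))
  for (s in detected_sets(log2)) expect_setequal(s, want)
})
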