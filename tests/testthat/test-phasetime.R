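test_that("phase signals match exact tool sets with Environment ignored", {
  sets <- list(c("Scalpel", "Environment"),   # right-phase for P1
               c("Scalpel", "Motor"),         # wrong-phase tool present
               character(0),                  # "None"
               "Scalpel")                     # right-phase, no Environment
  log <- log_from_sets(sets)
  expect_identical(build_phase_signal(log, "P1"), c(1L, 0L, 0L, 1L))
  # relaxed mode tolerates extra detections but still needs the right tools
  expect_identical(build_phase_signal(log, "P1", relaxed = TRUE),
                   c(1L, 1L, 0L, 1L))
  expect_identical(build_phase_signal(log, "P2"), c(0L, 0L, 0L, 0L))
})

test_that("moving-average smoothing shrinks at edges and removes blips", {
  cfg3 <- phase_estimation_config(window = 3)
  # averages [1/2, 2/3, 1, 2/3, 1/2] -> thresholded at 0.5
  expect_identical(smooth_and_binarize(c(0, 1, 1, 1, 0), cfg3),
                   c(0L, 1L, 1L, 1L, 0L))
  # a constant signal is unchanged by averaging
  expect_identical(smooth_and_binarize(rep(1, 8), cfg3), rep(1L, 8))
  expect_identical(smooth_and_binarize(rep(0, 8), cfg3), rep(0L, 8))
  # an isolated 1 in zeros averages to 1/3 < 0.5 and is removed
  expect_identical(smooth_and_binarize(c(0, 0, 1, 0, 0), cfg3), rep(0L, 5))
  expect_error(smooth_and_binarize(c(0, 1), phase_estimation_config(15)),
               "exceeds")
  expect_error(phase_estimation_config(window = 4), "window")
})

test_that("batch finding matches a brute-force scan on random vectors", {
  expect_identical(find_batches(c(0, 1, 1, 0, 1)),
                   data.frame(start = c(1L, 4L), end = c(2L, 4L)))
  expect_identical(nrow(find_batches(rep(0, 6))), 0L)
  expect_identical(find_batches(c(1, 1, 0, 0, 1, 1)),
                   data.frame(start = c(0L, 4L), end = c(1L, 5L)))
  expect_error(find_batches(c(0, 2)), "binary")

  brute <- function(x) {
    starts <- integer(0); ends <- integer(0)
    inside <- FALSE
    for (i in seq_along(x)) {
      if (x[i] == 1 && !inside) { starts <- c(starts, i - 1L); inside <- TRUE }
      if (x[i] == 0 && inside) { ends <- c(ends, i - 2L); inside <- FALSE }
    }
    if (inside) ends <- c(ends, length(x) - 1L)
    data.frame(start = starts, end = ends)
  }
  withr::with_seed(42, {
    for (i in 1:1000) {
      x <- rbinom(sample(1:25, 1), 1, runif(1))
      expect_identical(find_batches(x), brute(x))
    }
  })
})

test_that("interphase limits average the adjacent batch boundaries", {
  expect_identical(interphase_limit(100, 110), 105L)
  expect_identical(interphase_limit(10, 11), 11L)  # half rounds up
  expect_identical(interphase_limit(7, 7), 7L)
})

test_that("hits before the running cursor are discarded", {
  # P8 {Pointer} shows up at 0..5, long before its turn, and again at
  # 40..50; P6 {Motor} runs 6..25. After P6 the cursor sits at 25, so
  # P8's early batch (start 0 < 25) must be skipped in favour of (40, 50)
  sets <- lapply(0:55, function(t) {
    if (t <= 5 || t %in% 40:50) "Pointer"
    else if (t <= 25) "Motor"
    else "Scissors"
  })
  log <- log_from_sets(sets)
  est <- estimate_phases(log, c("P6", "P8"),
                         phase_estimation_config(window = 1))
  expect_true(all(est$detected))
  p8 <- est[est$phase == "P8", ]
  expect_identical(c(p8$raw_start, p8$raw_end), c(40L, 50L))
  p6 <- est[est$phase == "P6", ]
  expect_identical(c(p6$raw_start, p6$raw_end), c(6L, 25L))
  # shared boundary: mean of 25 and 40 -> 33 (round half up); the next
  # phase starts at the limit, the previous ends just before it
  expect_identical(p8$start, 33L)
  expect_identical(p6$end, 32L)
  expect_identical(p6$raw_start, p6$start)  # first phase keeps its start
  expect_identical(p8$end, p8$raw_end)      # last phase keeps its end
})

test_that("an absent phase is flagged and leaves the cursor unchanged", {
  sets <- c(rep(list("Motor"), 30), rep(list("Pointer"), 30))
  log <- log_from_sets(sets)
  est <- estimate_phases(log, c("P6", "P7", "P8"),
                         phase_estimation_config(window = 5))
  expect_identical(est$detected, c(TRUE, FALSE, TRUE))
  expect_true(is.na(est$start[2]))
  p8 <- est[est$phase == "P8", ]
  expect_identical(p8$raw_start, 30L)
})

test_that("zero-noise logs recover every boundary within half a window", {
  cfg <- phase_estimation_config(window = 15)
  tol <- ceiling(cfg$window / 2)
  for (seed in 1:3) {
    tl <- surgery_timeline(n_frames = 400 + 37 * seed)
    log <- simulate_detection_log(tl, noise_model(), seed = seed)
    est <- estimate_phases(log, cfg = cfg)
    expect_true(all(est$detected))
    expect_true(all(abs(est$start - tl$start) <= tol))
    expect_true(all(abs(est$end - tl$end) <= tol))
  }
})

test_that("final intervals stay ordered and non-overlapping on noisy logs", {
  for (seed in 1:5) {
    tl <- surgery_timeline(n_frames = 500)
    log <- simulate_detection_log(
      tl, noise_model(flip_rate = 0.08, jitter = 10, dropout_rate = 0.02),
      seed = seed)
    est <- estimate_phases(log)
    det <- est[est$detected, ]
    if (nrow(det) > 1) {
      expect_true(all(det$start <= det$end))
      expect_true(all(diff(det$start) > 0))
      expect_true(all(det$start[-1] > det$end[-nrow(det)]))
    }
  }
})

test_that("coverage follows the interval-overlap convention", {
  expect_equal(phase_coverage(c(10, 20), c(8, 22)), 100)   # engulfing: 100%
  expect_equal(phase_coverage(c(10, 19), c(15, 19)), 50)   # 5 of 10 frames
  expect_equal(phase_coverage(c(10, 20), c(30, 40)), 0)    # disjoint
  expect_equal(phase_coverage(c(10, 20), NULL), 0)         # undetected
  expect_equal(phase_coverage(c(0, 9), c(0, 9)), 100)
  expect_error(phase_coverage(c(20, 10), c(0, 5)), "inverted")
  expect_error(phase_coverage(c(0, 10), c(5, 2)), "inverted")
})

test_that("coverage is monotone under predicted-interval enlargement", {
  withr::with_seed(7, {
    for (i in 1:100) {
      gt <- sort(sample(0:100, 2))
      pr <- sort(sample(0:100, 2))
      grown <- c(max(pr[1] - sample(0:10, 1), 0), pr[2] + sample(0:10, 1))
      expect_gte(phase_coverage(gt, grown), phase_coverage(gt, pr))
    }
  })
})

test_that("coverage tables aggregate per-phase results against ground truth", {
  tl <- surgery_timeline(n_frames = 300)
  log <- simulate_detection_log(tl, noise_model(), seed = 2)
  est <- estimate_phases(log)
  cov <- coverage_table(est, tl)
  expect_identical(nrow(cov), 11L)
  expect_identical(cov$phase, phase_ids())
  expect_true(all(cov$coverage >= 0 & cov$coverage <= 100))
  expect_equal(attr(cov, "mean_coverage"), mean(cov$coverage))
  path <- withr::local_tempfile(fileext = ".json")
  write_phase_report(est, path)
  rep <- jsonlite::read_json(path)
  expect_length(rep, 11L)
  expect_identical(rep[[1]]$phase, "P1")
})
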