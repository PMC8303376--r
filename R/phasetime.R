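#' Phase-estimation configuration
#'
#' @param window Moving-average length in frames; odd, >= 1. The default 15
#'   is one second at the 15 frames/s recording rate and is the most
#'   consequential free parameter of the estimator.
#' @param threshold Binarisation threshold on the smoothed signal, in (0, 1).
#' @param relaxed Logical; when TRUE a frame matches a phase if all
#'   right-phase tools are detected, extra detections allowed. The default
#'   (exact) additionally requires that no wrong-phase tool is present.
#' @return A list of class `phase_estimation_config`.
#' @export
phase_estimation_config <- function(window = 15L, threshold = 0.5,
                                    relaxed = FALSE) {
  stopifnot(window >= 1, window %% 2 == 1, threshold > 0, threshold < 1)
  structure(list(window = as.integer(window), threshold = threshold,
                 relaxed = isTRUE(relaxed)),
            class = "phase_estimation_config")
}

#' Build the binary right-phase-tool signal for one phase
#'
#' Element `t` is 1 when the detected set at frame `t` (with `Environment`
#' ignored) equals the phase's right-phase tool set, and 0 when other
#' (wrong-phase) tools are in the field or right-phase tools are missing.
#'
#' @param log A [detection_log()].
#' @param id Phase id (`"P1"`..`"P11"`), or a character vector of tool
#'   names to match against directly.
#' @param relaxed See [phase_estimation_config()].
#' @return Integer vector of 0/1, one element per log record.
#' @export
#' @examples
#' tl <- surgery_timeline(n_frames = 110)
#' log <- simulate_detection_log(tl, seed = 1)
#' sum(build_phase_signal(log, "P1"))
build_phase_signal <- function(log, id, relaxed = FALSE) {
  stopifnot(inherits(log, "detection_log"))
  tools <- if (length(id) == 1L && id %in% phase_ids()) phase_tools(id)
           else sort(canonical_label(id))
  thr <- attr(log, "threshold") %||% 0.5
  det <- as.matrix(log[paste0("p_", tool_labels())]) > thr
  colnames(det) <- tool_labels()
  wrong <- setdiff(tool_labels(), c(tools, "Environment"))
  right_ok <- if (length(tools)) rowSums(det[, tools, drop = FALSE]) == length(tools)
              else rep(TRUE, nrow(det))
  hit <- if (relaxed) right_ok
         else right_ok & rowSums(det[, wrong, drop = FALSE]) == 0
  as.integer(hit)
}

#' Smooth a binary signal and re-binarise it
#'
#' Centred moving average whose window shrinks symmetrically at the signal
#' edges, followed by thresholding (strictly above). Transient
#' misdetections shorter than about half the window are suppressed.
#'
#' @param signal Numeric 0/1 vector.
#' @param cfg A [phase_estimation_config()] (window must not exceed the
#'   signal length).
#' @return Integer 0/1 vector of the same length.
#' @export
#' @examples
#' smooth_and_binarize(c(0, 1, 1, 1, 0), phase_estimation_config(window = 3))
smooth_and_binarize <- function(signal, cfg = phase_estimation_config()) {
  n <- length(signal)
  if (cfg$window > n)
    stop("smoothing window (", cfg$window, ") exceeds signal length (", n, ")",
         call. = FALSE)
  h <- (cfg$window - 1L) %/% 2L
  cs <- cumsum(c(0, signal))
  t <- seq_len(n)
  lo <- pmax(t - h, 1L)
  hi <- pmin(t + h, n)
  avg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  as.integer(avg > cfg$threshold)
}

#' Find maximal runs of 1s in a binary vector
#'
#' @param x Vector of 0s and 1s.
#' @return Data frame with columns `start`, `end`: 0-based inclusive
#'   positions of each maximal run, in order (zero rows if none).
#' @export
#' @examples
#' find_batches(c(0, 1, 1, 0, 1))
find_batches <- function(x) {
  if (length(x) && !all(x %in% c(0, 1)))
    stop("input must be binary (0/1)", call. = FALSE)
  if (!length(x)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(as.integer(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Interphase limit between two consecutive phases
#'
#' The shared boundary is the mean of the previous phase's detected end and
#' the next phase's detected start, rounded half-up to an integer frame.
#'
#' @param prev_end End frame of the previous phase's accepted batch.
#' @param next_start Start frame of the next phase's accepted batch.
#' @return Integer frame index of the boundary.
#' @export
#' @examples
#' interphase_limit(100, 110)
interphase_limit <- function(prev_end, next_start) {
  as.integer(round_half_up((prev_end + next_start) / 2))
}

#' Estimate phase intervals from a detection log
#'
#' For each phase in order, the per-phase binary signal is smoothed,
#' re-binarised, and segmented into batches of 1s; a cursor enforces the
#' sequential workflow: the first batch starting at or after the cursor is
#' accepted and the cursor moves to its end, so earlier hits are discarded.
#' Boundaries between consecutively detected phases are then replaced by
#' the interphase limit (see [interphase_limit()]): the next phase's final
#' interval starts at the limit and the previous phase's ends one frame
#' before it. The first detected phase keeps its batch start and the last
#' keeps its batch end. A phase with no acceptable batch is flagged
#' undetected and leaves the cursor unchanged.
#'
#' @param log A [detection_log()].
#' @param phases Ordered phase ids (default all of `P1`..`P11`), or a named
#'   list of phase specs as from [phase_specs()].
#' @param cfg A [phase_estimation_config()].
#' @return Data frame of class `phase_estimates`, one row per phase:
#'   `phase`, `detected`, `raw_start`, `raw_end`, `start`, `end`
#'   (`NA` where undetected).
#' @export
estimate_phases <- function(log, phases = phase_ids(),
                            cfg = phase_estimation_config()) {
  stopifnot(inherits(log, "detection_log"))
  if (is.list(phases)) {
    tool_sets <- lapply(phases, `[[`, "tools")
    ids <- names(phases)
  } else {
    ids <- phases
    tool_sets <- lapply(phases, phase_tools)
  }
  frames <- log$frame
  n <- length(ids)
  raw_start <- raw_end <- rep(NA_integer_, n)
  detected <- logical(n)
  cursor <- 0L
  for (i in seq_len(n)) {
    sig <- build_phase_signal(log, tool_sets[[i]], relaxed = cfg$relaxed)
    sig <- smooth_and_binarize(sig, cfg)
    b <- find_batches(sig)
    if (nrow(b)) {
      # positions -> frame indices of the log
      bs <- frames[b$start + 1L]
      be <- frames[b$end + 1L]
      ok <- which(bs >= cursor)
      if (length(ok)) {
        j <- ok[1]
        raw_start[i] <- bs[j]
        raw_end[i] <- be[j]
        detected[i] <- TRUE
        cursor <- be[j]
      }
    }
  }
  start <- raw_start
  end <- raw_end
  det_idx <- which(detected)
  if (length(det_idx) > 1) {
    for (k in seq_len(length(det_idx) - 1L)) {
      a <- det_idx[k]; b2 <- det_idx[k + 1L]
      lim <- interphase_limit(raw_end[a], raw_start[b2])
      end[a] <- lim - 1L
      start[b2] <- lim
    }
  }
  out <- data.frame(phase = ids, detected = detected,
                    raw_start = raw_start, raw_end = raw_end,
                    start = start, end = end, stringsAsFactors = FALSE)
  class(out) <- c("phase_estimates", "data.frame")
  out
}

#' Percentage of a ground-truth phase covered by its prediction
#'
#' `100 * overlap / length` with inclusive frame counts, capped at 100: a
#' prediction that starts before and ends after the ground truth scores
#' 100%; an undetected phase scores 0.
#'
#' @param gt Two-element vector `c(start, end)` of the ground-truth interval.
#' @param pred Two-element vector for the prediction, or `NULL`/`NA` for an
#'   undetected phase.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' phase_coverage(c(10, 20), c(8, 22))
#' phase_coverage(c(10, 19), c(15, 19))
phase_coverage <- function(gt, pred) {
  stopifnot(length(gt) == 2)
  if (gt[1] > gt[2]) stop("inverted ground-truth interval", call. = FALSE)
  if (is.null(pred) || any(is.na(pred))) return(0)
  stopifnot(length(pred) == 2)
  if (pred[1] > pred[2]) stop("inverted predicted interval", call. = FALSE)
  ov <- min(gt[2], pred[2]) - max(gt[1], pred[1]) + 1
  min(100 * max(ov, 0) / (gt[2] - gt[1] + 1), 100)
}

#' Per-phase coverage table against a ground-truth timeline
#'
#' @param est A `phase_estimates` data frame from [estimate_phases()].
#' @param tl The ground-truth [timeline()].
#' @return Data frame with one row per ground-truth phase: `phase`,
#'   `gt_start`, `gt_end`, `start`, `end`, `coverage` (percent); attribute
#'   `mean_coverage` holds the average over phases.
#' @export
coverage_table <- function(est, tl) {
  validate_timeline(tl)
  rows <- lapply(seq_len(nrow(tl)), function(i) {
    id <- tl$phase[i]
    j <- match(id, est$phase)
    pred <- if (!is.na(j) && est$detected[j]) c(est$start[j], est$end[j]) else NULL
    data.frame(phase = id, gt_start = tl$start[i], gt_end = tl$end[i],
               start = if (is.null(pred)) NA_integer_ else pred[1],
               end = if (is.null(pred)) NA_integer_ else pred[2],
               coverage = phase_coverage(c(tl$start[i], tl$end[i]), pred),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_coverage") <- mean(out$coverage)
  out
}

#' Write a phase-estimation report as JSON
#'
#' One object per phase with `phase`, `detected`, `raw_batch` and
#' `final_interval` (nulls where undetected).
#'
#' @param est A `phase_estimates` data frame.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_phase_report <- function(est, path) {
  obj <- lapply(seq_len(nrow(est)), function(i) {
    list(phase = est$phase[i], detected = est$detected[i],
         raw_batch = if (est$detected[i]) c(est$raw_start[i], est$raw_end[i]),
         final_interval = if (est$detected[i]) c(est$start[i], est$end[i]))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
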