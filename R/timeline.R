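#' Ground-truth phase timeline
#'
#' A timeline is an ordered list of contiguous, non-overlapping phase
#' segments over integer frame indices (0-based, inclusive endpoints),
#' together with the recording frame rate.
#'
#' @param phases Character vector of phase ids, strictly in `P1`..`P11` order.
#' @param durations Integer vector of segment lengths in frames (same length
#'   as `phases`, all >= 1). Segments are laid out contiguously from frame 0.
#' @param frame_rate Frames per second (default 15, the recording rate).
#' @return An object of class `cranio_timeline`: a data.frame with columns
#'   `phase`, `start`, `end` and attribute `frame_rate`.
#' @export
#' @examples
#' tl <- timeline(c("P1", "P2"), c(30, 45))
#' timeline_n_frames(tl)
timeline <- function(phases, durations, frame_rate = 15) {
  stopifnot(length(phases) == length(durations), length(phases) >= 1,
            all(durations >= 1), frame_rate > 0)
  ord <- match(phases, phase_ids())
  if (anyNA(ord)) stop("unknown phase id(s) in timeline", call. = FALSE)
  if (is.unsorted(ord, strictly = TRUE))
    stop("timeline phases must be strictly in P1..P11 order", call. = FALSE)
  ends <- cumsum(as.integer(durations)) - 1L
  starts <- c(0L, utils::head(ends, -1L) + 1L)
  out <- data.frame(phase = phases, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("cranio_timeline", "data.frame")
  out
}

validate_timeline <- function(tl) {
  stopifnot(is.data.frame(tl), all(c("phase", "start", "end") %in% names(tl)))
  if (!nrow(tl)) stop("timeline has no segments", call. = FALSE)
  if (any(tl$start > tl$end)) stop("timeline segment with start > end", call. = FALSE)
  if (tl$start[1] != 0) stop("timeline must start at frame 0", call. = FALSE)
  if (nrow(tl) > 1) {
    gaps <- tl$start[-1] - tl$end[-nrow(tl)]
    if (any(gaps != 1)) stop("timeline segments must be contiguous", call. = FALSE)
  }
  ord <- match(tl$phase, phase_ids())
  if (anyNA(ord) || is.unsorted(ord, strictly = TRUE))
    stop("timeline phases must be strictly in P1..P11 order", call. = FALSE)
  invisible(tl)
}

#' @rdname timeline
#' @export
timeline_n_frames <- function(tl) {
  validate_timeline(tl)
  tl$end[nrow(tl)] + 1L
}

#' @rdname timeline
#' @param tl A `cranio_timeline`.
#' @param frame 0-based frame index (vectorised).
#' @export
timeline_phase_at <- function(tl, frame) {
  validate_timeline(tl)
  idx <- findInterval(frame, tl$start)
  bad <- frame < 0 | frame > tl$end[nrow(tl)]
  out <- tl$phase[idx]
  out[bad] <- NA_character_
  out
}

#' Read / write a timeline as JSON
#'
#' Schema: `{"frame_rate": 15, "segments": [{"phase": "P1", "start": 0,
#' "end": 89}, ...]}` with 0-based inclusive frame indices.
#'
#' @param tl A `cranio_timeline`.
#' @param path File path.
#' @return `read_timeline()` returns a `cranio_timeline`; `write_timeline()`
#'   returns `path` invisibly.
#' @export
write_timeline <- function(tl, path) {
  validate_timeline(tl)
  obj <- list(
    frame_rate = attr(tl, "frame_rate"),
    segments = lapply(seq_len(nrow(tl)), function(i)
      list(phase = tl$phase[i], start = tl$start[i], end = tl$end[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- obj$segments
  if (is.null(segs) || !length(segs)) stop("timeline JSON has no segments", call. = FALSE)
  phases <- vapply(segs, function(s) s$phase, character(1))
  starts <- vapply(segs, function(s) as.integer(s$start), integer(1))
  ends <- vapply(segs, function(s) as.integer(s$end), integer(1))
  durations <- ends - starts + 1L
  if (starts[1] != 0L) stop("timeline must start at frame 0", call. = FALSE)
  tl <- timeline(phases, durations,
                 frame_rate = as.numeric(obj$frame_rate %||% 15))
  if (!all(tl$end == ends)) stop("timeline segments must be contiguous", call. = FALSE)
  tl
}

#' Reference surgery timeline
#'
#' The default full-scale timeline: all eleven phases over 4920 frames at
#' 15 frames/s (about 5.5 minutes), with fixed per-phase durations roughly
#' proportional to the work done in each phase (osteotomies and screwing run
#' longer than incision or suturing). `n_frames` rescales the same
#' proportions to a shorter recording.
#'
#' @param n_frames Total number of frames (default 4920).
#' @param frame_rate Frames per second (default 15).
#' @return A `cranio_timeline` covering `P1`..`P11`.
#' @export
#' @examples
#' surgery_timeline(n_frames = 660)
surgery_timeline <- function(n_frames = 4920L, frame_rate = 15) {
  stopifnot(n_frames >= 11)
  # relative durations of P1..P11 (sum 100); fixed so runs are reproducible
  w <- c(7, 11, 7, 9, 9, 11, 11, 8, 12, 7, 8)
  d <- floor(n_frames * cumsum(w) / sum(w))
  durations <- as.integer(diff(c(0, d)))
  if (any(durations < 1)) stop("n_frames too small for 11 phases", call. = FALSE)
  timeline(phase_ids(), durations, frame_rate = frame_rate)
}
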