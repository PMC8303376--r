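#' Default training-set label combinations
#'
#' The thirteen scene variants the training generator emulates: the eleven
#' phase tool sets (each with the `Environment` bit, since the phantom stays
#' in the field), the phantom alone, and an empty-gloved-hands variant over
#' the bare sheet. The hands variant carries the same `Environment`-only
#' label set as the phantom video, so its folder name takes a `.hands`
#' variant suffix (everything after a dot in a folder name is ignored by the
#' labeller, see [load_labeled_frames()]).
#'
#' @return List of 13 entries `list(labels =, folder =, scene =)` where
#'   `scene` holds [scene_config()] overrides for that variant.
#' @export
training_combinations <- function() {
  combos <- lapply(phase_ids(), function(id) {
    labs <- c(phase_tools(id), "Environment")
    list(labels = labs, folder = folder_name_from_labels(labs), scene = list())
  })
  combos <- c(combos, list(
    list(labels = "Environment", folder = "Environment", scene = list()),
    list(labels = "Environment", folder = "Environment.hands",
         scene = list(occluder_prob = 1))
  ))
  combos
}

#' Generate a synthetic training folder tree
#'
#' Writes one folder of PNG frames per label combination, named by the
#' underscore-joined label names (the layout [load_labeled_frames()] reads),
#' plus a `manifest.json` recording the seed and per-folder frame counts.
#' The sheet wrinkle pattern is reseeded per folder, emulating recordings
#' where the sheet was rearranged between videos.
#'
#' @param out_dir Output directory (created if missing).
#' @param combinations List as returned by [training_combinations()], or a
#'   plain list of character label sets.
#' @param frames_per_combination Frames per folder: either a scalar or a
#'   vector with one count per combination (see [distribute_frames()] for
#'   splitting a total as evenly as integer division allows).
#' @param cfg A [scene_config()]; `cfg$seed` drives all randomness.
#' @return Invisibly, the manifest as a list.
#' @export
#' @examples
#' \donttest{
#' d <- tempfile()
#' generate_training_set(d, frames_per_combination = 2,
#'                       cfg = scene_config(seed = 1))
#' list.dirs(d, recursive = FALSE)
#' }
generate_training_set <- function(out_dir,
                                  combinations = training_combinations(),
                                  frames_per_combination = 50L,
                                  cfg = scene_config()) {
  stopifnot(length(combinations) >= 1, all(frames_per_combination >= 1))
  if (length(frames_per_combination) == 1L)
    frames_per_combination <- rep(frames_per_combination, length(combinations))
  stopifnot(length(frames_per_combination) == length(combinations))
  combinations <- lapply(combinations, function(cmb) {
    if (is.character(cmb))
      cmb <- list(labels = cmb, folder = folder_name_from_labels(cmb),
                  scene = list())
    stopifnot(!is.null(cmb$labels))
    cmb$folder <- cmb$folder %||% folder_name_from_labels(cmb$labels)
    cmb$scene <- cmb$scene %||% list()
    cmb
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)

  manifest <- list(seed = cfg$seed, size = cfg$size, folders = list())
  for (i in seq_along(combinations)) {
    cmb <- combinations[[i]]
    fcfg <- cfg
    fcfg[names(cmb$scene)] <- cmb$scene
    dir.create(file.path(out_dir, cmb$folder), showWarnings = FALSE)
    for (j in seq_len(frames_per_combination[i])) {
      # per-frame seed: folder index and frame index keep streams disjoint
      fseed <- (cfg$seed + 104729L * i + j) %% .Machine$integer.max
      fr <- render_frame(cmb$labels, fcfg, seed = fseed)
      png::writePNG(fr$image,
                    file.path(out_dir, cmb$folder,
                              sprintf("frame_%05d.png", j)))
    }
    manifest$folders[[i]] <- list(
      name = cmb$folder,
      labels = as.list(sort(canonical_label(cmb$labels))),
      n_frames = as.integer(frames_per_combination[i]))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Split a total frame budget over folders as evenly as possible
#'
#' Integer division with the remainder spread over the leading folders, so
#' counts differ by at most one and always sum to `total`.
#'
#' @param total Total number of frames.
#' @param n Number of folders.
#' @return Integer vector of length `n` summing to `total`.
#' @export
#' @examples
#' distribute_frames(10000, 13)
distribute_frames <- function(total, n) {
  stopifnot(total >= n, n >= 1)
  base <- total %/% n
  extra <- total %% n
  as.integer(base + (seq_len(n) <= extra))
}

#' Generate a synthetic surgery video as a frame directory
#'
#' Renders one frame per timeline position, each showing the right-phase
#' tools of the covering phase (plus the always-visible phantom), and writes
#' the ground-truth timeline next to the frames as `timeline.json`.
#' Illumination varies frame to frame per the scene config, emulating the
#' changing lighting of the test recording.
#'
#' @param out_dir Output directory for `frame_%06d.png` files; `NULL` keeps
#'   frames in memory (only sensible for short timelines).
#' @param tl A [timeline()] covering `P1`..`P11` (or an ordered subset).
#' @param cfg A [scene_config()].
#' @return List with `timeline` (the ground truth, verbatim), `labels`
#'   (n_frames x 10 matrix of ground-truth label vectors), and either
#'   `files` (paths) or `frames` (list of arrays) depending on `out_dir`.
#' @export
generate_surgery_video <- function(tl, cfg = scene_config(), out_dir = NULL) {
  validate_timeline(tl)
  n <- timeline_n_frames(tl)
  phases <- timeline_phase_at(tl, seq_len(n) - 1L)
  in_memory <- is.null(out_dir)
  if (!in_memory) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)
  }
  labels <- matrix(0L, n, n_labels(), dimnames = list(NULL, tool_labels()))
  frames <- if (in_memory) vector("list", n) else character(n)
  for (t in seq_len(n)) {
    tools <- phase_tools(phases[t])
    fseed <- (cfg$seed + 15485863L + t) %% .Machine$integer.max
    fr <- render_frame(tools, cfg, seed = fseed)
    labels[t, ] <- fr$labels
    if (in_memory) {
      frames[[t]] <- fr$image
    } else {
      frames[t] <- file.path(out_dir, sprintf("frame_%06d.png", t - 1L))
      png::writePNG(fr$image, frames[t])
    }
  }
  if (!in_memory) write_timeline(tl, file.path(out_dir, "timeline.json"))
  out <- list(timeline = tl, labels = labels)
  if (in_memory) out$frames <- frames else out$files <- frames
  out
}

#' Detection-noise model
#'
#' Emulates the error modes of a per-frame CNN detector on top of a
#' ground-truth timeline: per-label detection flips (misclassifications),
#' random shifts of the phase boundaries (transition ambiguity while tools
#' are exchanged), and whole-frame dropouts (nothing detected).
#'
#' @param flip_rate Per-frame, per-label probability of toggling a detection.
#' @param jitter Maximum shift, in frames, applied to each phase boundary.
#' @param dropout_rate Per-frame probability that all detections are emptied.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(flip_rate = 0, jitter = 0L, dropout_rate = 0) {
  stopifnot(flip_rate >= 0, flip_rate <= 1, dropout_rate >= 0,
            dropout_rate <= 1, jitter >= 0)
  structure(list(flip_rate = flip_rate, jitter = as.integer(jitter),
                 dropout_rate = dropout_rate), class = "noise_model")
}

#' Simulate a detection log from a ground-truth timeline
#'
#' Bypasses the CNN entirely: the detected set at each frame starts as the
#' right-phase tools of the covering segment (plus `Environment`), then the
#' noise model is applied — boundary jitter first, then label flips, then
#' frame dropouts. Probabilities are written as 0.9 for detected and 0.1 for
#' undetected labels, so any threshold in (0.1, 0.9) reproduces the sets.
#'
#' @param tl A [timeline()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return A [detection_log()] with one record per timeline frame.
#' @export
#' @examples
#' tl <- surgery_timeline(n_frames = 220)
#' log <- simulate_detection_log(tl, noise_model(flip_rate = 0.02), seed = 1)
#' nrow(log)
simulate_detection_log <- function(tl, noise = noise_model(), seed = 1L) {
  validate_timeline(tl)
  with_local_seed(seed, {
    n <- timeline_n_frames(tl)
    jt <- tl
    if (noise$jitter > 0 && nrow(tl) > 1) {
      ends <- tl$end
      for (k in seq_len(nrow(tl) - 1L)) {
        lo <- (if (k == 1L) tl$start[1] else ends[k - 1L] + 1L)
        hi <- tl$end[nrow(tl)] - (nrow(tl) - k)  # room for later segments
        ends[k] <- min(max(ends[k] + sample(-noise$jitter:noise$jitter, 1L),
                           lo), hi)
      }
      # re-impose strictly increasing ends
      for (k in seq_len(nrow(tl) - 1L))
        if (k > 1L && ends[k] <= ends[k - 1L]) ends[k] <- ends[k - 1L] + 1L
      jt <- timeline(tl$phase, diff(c(-1L, ends)),
                     frame_rate = attr(tl, "frame_rate"))
    }
    phases <- timeline_phase_at(jt, seq_len(n) - 1L)
    det <- matrix(0L, n, n_labels(), dimnames = list(NULL, tool_labels()))
    for (p in unique(phases))
      det[phases == p, ] <- matrix(labels_to_vector(c(phase_tools(p), "Environment")),
                                   sum(phases == p), n_labels(), byrow = TRUE)
    if (noise$flip_rate > 0) {
      flips <- matrix(stats::runif(n * n_labels()) < noise$flip_rate,
                      n, n_labels())
      det <- (det + flips) %% 2L
    }
    if (noise$dropout_rate > 0)
      det[stats::runif(n) < noise$dropout_rate, ] <- 0L
    probs <- det * 0.8 + 0.1
    detection_log(probs, frame_rate = attr(tl, "frame_rate"), threshold = 0.5)
  })
}
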