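#' Threshold per-label probabilities into a detected tool set
#'
#' A label counts as detected when its probability is strictly above the
#' threshold (default 0.5); a probability exactly at the threshold is not a
#' detection. An empty result is rendered as `"None"` in logs.
#'
#' @param probabilities Numeric vector of length 10 in \[0, 1\], aligned to
#'   [tool_labels()] (names, if present, are checked).
#' @param threshold Detection threshold in (0, 1); default 0.5.
#' @return Character vector of detected label names (possibly empty).
#' @export
#' @examples
#' p <- stats::setNames(rep(0.2, 10), tool_labels())
#' p["Scalpel"] <- 0.7
#' threshold_detections(p)
threshold_detections <- function(probabilities, threshold = 0.5) {
  stopifnot(length(probabilities) == n_labels(),
            threshold > 0, threshold < 1)
  if (any(!is.finite(probabilities)) ||
      any(probabilities < 0) || any(probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!is.null(names(probabilities)) &&
      !identical(names(probabilities), tool_labels()))
    stop("probability names must follow the canonical label order", call. = FALSE)
  tool_labels()[probabilities > threshold]
}

#' Construct a detection log
#'
#' A detection log holds the time-ordered per-frame label probabilities
#' produced by a detector, together with the thresholded tool sets. It is a
#' data.frame with columns `frame` (0-based index), `time_s`
#' (`frame / frame_rate`), one `p_<label>` column per canonical label, and
#' `detected` (semicolon-joined label names, `"None"` when empty), plus
#' attributes `frame_rate` and `threshold`.
#'
#' @param probs Numeric matrix, one row per frame, 10 columns in canonical
#'   label order, values in \[0, 1\].
#' @param frame_rate Frames per second.
#' @param threshold Detection threshold in (0, 1).
#' @param frames Optional integer vector of 0-based frame indices (strictly
#'   increasing); defaults to `0:(nrow(probs) - 1)`.
#' @return An object of class `detection_log`.
#' @export
detection_log <- function(probs, frame_rate = 15, threshold = 0.5,
                          frames = NULL) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0) probs <- matrix(numeric(0), 0, n_labels())
  stopifnot(ncol(probs) == n_labels(), threshold > 0, threshold < 1,
            frame_rate > 0)
  if (is.null(frames)) frames <- seq_len(nrow(probs)) - 1L
  frames <- as.integer(frames)
  stopifnot(length(frames) == nrow(probs))
  if (length(frames) && (any(frames < 0) || is.unsorted(frames, strictly = TRUE)))
    stop("frame indices must be non-negative and strictly increasing", call. = FALSE)
  detected <- vapply(seq_len(nrow(probs)), function(i) {
    d <- threshold_detections(unname(probs[i, ]), threshold)
    if (length(d)) paste(d, collapse = ";") else "None"
  }, character(1))
  df <- data.frame(frame = frames, time_s = frames / frame_rate,
                   stringsAsFactors = FALSE)
  for (j in seq_len(n_labels())) df[[paste0("p_", tool_labels()[j])]] <- probs[, j]
  df$detected <- detected
  attr(df, "frame_rate") <- frame_rate
  attr(df, "threshold") <- threshold
  class(df) <- c("detection_log", "data.frame")
  df
}

#' Detected tool sets of a log
#'
#' @param log A [detection_log()].
#' @return List of character vectors, one per record (empty for `"None"`).
#' @export
detected_sets <- function(log) {
  stopifnot(inherits(log, "detection_log"))
  lapply(log$detected, function(s)
    if (identical(s, "None")) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]])
}

log_columns <- function() {
  c("frame", "time_s", paste0("p_", tool_labels()), "detected")
}

#' Run per-frame multilabel inference over a frame sequence
#'
#' Frames are preprocessed to the network input (64 x 64 x 3, \[0, 1\]),
#' passed through the model in evaluation mode, and thresholded into
#' detected tool sets. Unreadable frames are skipped with a warning; the
#' number skipped is available as `attr(log, "skipped")`.
#'
#' @param model A model built by [build_cranionet()] or
#'   [build_transfer_model()] (trained or not).
#' @param frames A directory of PNG/JPEG frames, a character vector of file
#'   paths, or a list of image arrays.
#' @param frame_rate Frames per second used for the `time_s` column.
#' @param threshold Detection threshold.
#' @param batch_size Inference batch size.
#' @return A [detection_log()] with one record per readable frame.
#' @export
run_inference <- function(model, frames, frame_rate = 15, threshold = 0.5,
                          batch_size = 64L) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames))
    frames <- sort(list.files(frames, pattern = "\\.(png|jpe?g)$",
                              ignore.case = TRUE, full.names = TRUE))
  n <- length(frames)
  imgs <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    img <- tryCatch({
      raw <- if (is.character(frames)) read_image(frames[[i]]) else frames[[i]]
      preprocess_frame(raw)
    }, error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable frame ", i, call. = FALSE)
    } else {
      imgs[[i]] <- img
      ok[i] <- TRUE
    }
  }
  imgs <- imgs[ok]
  kept <- which(ok)
  probs <- matrix(numeric(0), 0, n_labels())
  if (length(imgs)) {
    batches <- split(seq_along(imgs), (seq_along(imgs) - 1L) %/% batch_size)
    probs <- do.call(rbind, lapply(batches, function(ix)
      predict_proba(model, stack_images(imgs[ix]))))
  }
  log <- detection_log(probs, frame_rate = frame_rate, threshold = threshold,
                       frames = kept - 1L)
  attr(log, "skipped") <- sum(!ok)
  log
}

#' Write / read a detection log as CSV
#'
#' The schema is fixed: header
#' `frame,time_s,p_Forceps,...,p_Environment,detected` (probability columns
#' in canonical label order), probabilities printed with 6 decimals, and the
#' `detected` column holding semicolon-joined label names or `"None"`.
#' `read_log(write_log(x))` reproduces `x` up to that float precision.
#'
#' @param log A [detection_log()].
#' @param path CSV file path.
#' @return `read_log()` returns a [detection_log()]; `write_log()` returns
#'   `path` invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "detection_log"))
  pcols <- paste0("p_", tool_labels())
  lines <- c(paste(log_columns(), collapse = ","))
  if (nrow(log)) {
    pm <- as.matrix(log[pcols])
    body <- vapply(seq_len(nrow(log)), function(i) {
      paste(c(format(log$frame[i], scientific = FALSE),
              sprintf("%.6f", log$time_s[i]),
              sprintf("%.6f", pm[i, ]),
              log$detected[i]), collapse = ",")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_log
#' @param frame_rate,threshold Metadata for the reconstructed log;
#'   `frame_rate = NULL` recovers it from the `time_s` column.
#' @export
read_log <- function(path, frame_rate = NULL, threshold = 0.5) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty detection log file", call. = FALSE)
  if (!identical(lines[1], paste(log_columns(), collapse = ",")))
    stop("malformed detection log header at line 1", call. = FALSE)
  n <- length(lines) - 1L
  probs <- matrix(NA_real_, n, n_labels())
  frames <- integer(n)
  detected <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(parts) != length(log_columns()))
      stop("malformed detection log row at line ", i + 1L, call. = FALSE)
    frames[i] <- suppressWarnings(as.integer(parts[1]))
    pr <- suppressWarnings(as.numeric(parts[3:12]))
    if (is.na(frames[i]) || anyNA(pr))
      stop("malformed detection log row at line ", i + 1L, call. = FALSE)
    probs[i, ] <- pr
    detected[i] <- parts[13]
  }
  if (is.null(frame_rate)) {
    frame_rate <- if (n >= 1 && frames[n] > 0) {
      t_last <- as.numeric(strsplit(lines[n + 1L], ",", fixed = TRUE)[[1]][2])
      if (t_last > 0) frames[n] / t_last else 15
    } else 15
  }
  detection_log(probs, frame_rate = frame_rate, threshold = threshold,
                frames = frames)
}

#' Read an image file into an array
#'
#' Reads PNG (via the png package); grayscale images are expanded to three
#' channels and any alpha channel is dropped.
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (ext != "png")
    stop("unsupported image format ", sQuote(ext), " (PNG frames expected)",
         call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
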