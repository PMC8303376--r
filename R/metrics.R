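#' Per-label confusion counts over frames
#'
#' Standard per-label tally: a frame contributes a TP when the label is
#' truly present and predicted, a FN when present but missed, a FP when
#' absent but predicted, and a TN otherwise.
#'
#' @param pred_sets List of predicted label sets (character vectors), one
#'   per frame.
#' @param truth N x 10 binary matrix of ground-truth label vectors in
#'   canonical order (see [labels_matrix()]), or a list of label sets.
#' @param label Label name.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(pred_sets, truth, label) {
  label <- canonical_label(label)
  if (is.list(truth))
    truth <- do.call(rbind, lapply(truth, function(s) labels_to_vector(s)))
  if (length(pred_sets) != nrow(truth))
    stop("predictions and truth have different lengths", call. = FALSE)
  pred <- vapply(pred_sets, function(s) label %in% s, logical(1))
  act <- truth[, label] == 1
  c(TP = sum(pred & act), TN = sum(!pred & !act),
    FP = sum(pred & !act), FN = sum(!pred & act))
}

.safe_ratio <- function(num, den) {
  if (den == 0) return(NA_real_)  # undefined: reported as not-applicable
  100 * num / den
}

#' Precision, recall and F1 from confusion counts
#'
#' All values are percentages. A metric whose denominator is zero is
#' undefined and returned as `NA` (not-applicable) rather than 0 or 100,
#' so it can be excluded from averages explicitly.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN` (see
#'   [confusion_counts()]).
#' @return Percentage, or `NA` when undefined.
#' @export
#' @examples
#' metric_precision(c(TP = 3, TN = 0, FP = 1, FN = 0))
metric_precision <- function(counts) .safe_ratio(counts[["TP"]], counts[["TP"]] + counts[["FP"]])

#' @rdname metric_precision
#' @export
metric_recall <- function(counts) .safe_ratio(counts[["TP"]], counts[["TP"]] + counts[["FN"]])

#' @rdname metric_precision
#' @export
metric_accuracy <- function(counts) {
  tot <- sum(counts[c("TP", "TN", "FP", "FN")])
  .safe_ratio(counts[["TP"]] + counts[["TN"]], tot)
}

#' F1 score from precision and recall percentages
#'
#' Harmonic mean `2PR / (P + R)`, rounded half-up to one decimal for
#' reporting (`digits = NULL` keeps full precision). Undefined (`NA`) when
#' `P + R` is zero or either input is not-applicable.
#'
#' @param p,r Precision and recall in percent.
#' @param digits Decimals for reporting (default 1; `NULL` = no rounding).
#' @return F1 in percent, or `NA`.
#' @export
#' @examples
#' f1_from_pr(72.5, 100)
f1_from_pr <- function(p, r, digits = 1) {
  if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
  f1 <- 2 * p * r / (p + r)
  if (is.null(digits)) f1 else round_half_up(f1, digits)
}

#' Frame exact-match accuracy
#'
#' Percentage of frames whose predicted label set equals the ground-truth
#' set exactly over all 10 labels: a frame with three true tools counts as
#' wrong if the model reports four, even though most per-label decisions
#' are correct.
#'
#' @inheritParams confusion_counts
#' @return Percentage in \[0, 100\].
#' @export
exact_match_accuracy <- function(pred_sets, truth) {
  if (is.list(truth))
    truth <- do.call(rbind, lapply(truth, function(s) labels_to_vector(s)))
  n <- length(pred_sets)
  if (n == 0) stop("no frames to evaluate", call. = FALSE)
  if (n != nrow(truth))
    stop("predictions and truth have different lengths", call. = FALSE)
  hits <- vapply(seq_len(n), function(i)
    identical(unname(labels_to_vector(pred_sets[[i]])),
              as.integer(truth[i, ])), logical(1))
  100 * sum(hits) / n
}

#' Confusion percentages in the per-tool table convention
#'
#' TP and FN are expressed as percentages of the truly-present frames and
#' TN and FP as percentages of the truly-absent frames, so each pair sums
#' to 100: `TP% = 100 TP / (TP + FN)`, `FN% = 100 FN / (TP + FN)`,
#' `TN% = 100 TN / (TN + FP)`, `FP% = 100 FP / (TN + FP)`.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named vector `c(TP, TN, FP, FN)` of percentages (`NA` pair when
#'   a partition is empty).
#' @export
#' @examples
#' table4_percentages(c(TP = 50, TN = 99, FP = 1, FN = 0))
table4_percentages <- function(counts) {
  pos <- counts[["TP"]] + counts[["FN"]]
  neg <- counts[["TN"]] + counts[["FP"]]
  c(TP = .safe_ratio(counts[["TP"]], pos),
    TN = .safe_ratio(counts[["TN"]], neg),
    FP = .safe_ratio(counts[["FP"]], neg),
    FN = .safe_ratio(counts[["FN"]], pos))
}

#' Column average for report tables
#'
#' Arithmetic mean of per-tool metric values, rounded half-up to one
#' decimal for reporting. `NA` (not-applicable) entries are an error by
#' default: silently dropping them would corrupt the average.
#'
#' @param values Numeric vector (percent).
#' @param digits Decimals for reporting (default 1; `NULL` = none).
#' @param na_rm Drop `NA` values instead of erroring.
#' @return Mean in percent.
#' @export
#' @examples
#' column_average(c(100, 100, 95.8, 72.5, 100, 94.5, 100, 100, 100))
column_average <- function(values, digits = 1, na_rm = FALSE) {
  if (!length(values)) stop("empty column", call. = FALSE)
  if (anyNA(values)) {
    if (!na_rm) stop("column contains not-applicable values", call. = FALSE)
    values <- values[!is.na(values)]
    if (!length(values)) return(NA_real_)
  }
  m <- mean(values)
  if (is.null(digits)) m else round_half_up(m, digits)
}

#' Full multilabel metric report
#'
#' Per-tool precision, recall, F1 and per-label accuracy for the nine
#' surgical tools (the `Environment` label is excluded from the per-tool
#' table but participates in the exact-match comparison), an `Average` row,
#' and the frame exact-match accuracy as attribute `exact_match`.
#'
#' @inheritParams confusion_counts
#' @param digits Decimals for reporting (default 1).
#' @return Data frame of class `metric_report` with columns `tool`,
#'   `precision`, `recall`, `f1`, `accuracy`.
#' @export
metric_report <- function(pred_sets, truth, digits = 1) {
  if (is.list(truth))
    truth <- do.call(rbind, lapply(truth, function(s) labels_to_vector(s)))
  tools <- setdiff(tool_labels(), "Environment")
  rows <- lapply(tools, function(tl) {
    cc <- confusion_counts(pred_sets, truth, tl)
    p <- metric_precision(cc); r <- metric_recall(cc)
    data.frame(tool = tl,
               precision = round_half_up(p, digits),
               recall = round_half_up(r, digits),
               f1 = f1_from_pr(p, r, digits),
               accuracy = round_half_up(metric_accuracy(cc), digits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # the Average row drops not-applicable cells explicitly (a tool the
  # detector never predicts has no precision); NA never enters the mean
  avg <- data.frame(tool = "Average",
                    precision = column_average(out$precision, digits, na_rm = TRUE),
                    recall = column_average(out$recall, digits, na_rm = TRUE),
                    f1 = column_average(out$f1, digits, na_rm = TRUE),
                    accuracy = column_average(out$accuracy, digits, na_rm = TRUE),
                    stringsAsFactors = FALSE)
  out <- rbind(out, avg)
  attr(out, "exact_match") <- exact_match_accuracy(pred_sets, truth)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write a metric report as CSV and/or JSON
#'
#' The CSV mirrors the per-tool table layout (tool rows with
#' precision/recall/F1/accuracy columns and an Average row); the JSON adds
#' the frame exact-match accuracy.
#'
#' @param report A [metric_report()].
#' @param csv,json Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_metric_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(exact_match = attr(report, "exact_match"),
           per_tool = as.data.frame(report)),
      json, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", digits = NA)
  invisible(report)
}
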