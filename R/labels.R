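#' Tool and environment label vocabulary
#'
#' The vocabulary contains the nine surgical tools used during open cranial
#' vault remodeling plus an `Environment` label that marks every no-tool
#' element of the scene (patient phantom, drapes, empty gloved hands).
#' The canonical order is alphabetical with `Environment` placed last; all
#' label vectors, CSV columns and probability outputs follow this order.
#'
#' @return Character vector of the 10 label names in canonical order.
#' @export
#' @examples
#' tool_labels()
tool_labels <- function() {
  c("Forceps", "FTGuide", "Handpiece", "Motor", "Osteotome",
    "Pointer", "Scalpel", "Scissors", "SOGuide", "Environment")
}

#' @rdname tool_labels
#' @export
n_labels <- function() 10L

# alias table: lower-cased token -> canonical name. Folder tokens cannot
# contain underscores, but prose forms ("SO guide") are accepted for JSON
# phase files and user input.
.label_aliases <- function() {
  canon <- tool_labels()
  al <- stats::setNames(canon, tolower(canon))
  extra <- c(
    "so guide"  = "SOGuide",  "soguide" = "SOGuide",  "so-guide" = "SOGuide",
    "ft guide"  = "FTGuide",  "ftguide" = "FTGuide",  "ft-guide" = "FTGuide",
    "scalpel knife" = "Scalpel",
    "background" = "Environment"
  )
  c(al, extra[!names(extra) %in% names(al)])
}

#' Resolve a label token to its canonical name
#'
#' Matching is case-insensitive and accepts the prose aliases
#' (`"SO guide"`, `"FT guide"`, `"scalpel knife"`, `"background"`).
#'
#' @param token Character scalar or vector of tokens.
#' @return Canonical label name(s).
#' @export
canonical_label <- function(token) {
  al <- .label_aliases()
  key <- tolower(trimws(token))
  hit <- al[key]
  if (anyNA(hit)) {
    bad <- token[is.na(hit)]
    stop("unknown label token(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(hit)
}

#' Convert between label sets and one-hot label vectors
#'
#' A label vector is a named binary vector of length 10 aligned to
#' [tool_labels()]; `labels_to_vector()` and `vector_to_labels()` are exact
#' inverses over all 2^10 label subsets.
#'
#' @param labels Character vector of label names (canonicalised first).
#' @param vec Numeric/integer binary vector of length 10.
#' @return `labels_to_vector()`: named integer vector of 0/1;
#'   `vector_to_labels()`: character vector of label names in canonical order.
#' @export
labels_to_vector <- function(labels) {
  v <- stats::setNames(integer(n_labels()), tool_labels())
  if (length(labels)) v[canonical_label(labels)] <- 1L
  v
}

#' @rdname labels_to_vector
#' @export
vector_to_labels <- function(vec) {
  stopifnot(length(vec) == n_labels())
  if (!all(vec %in% c(0, 1))) stop("label vector entries must be 0 or 1", call. = FALSE)
  tool_labels()[vec == 1]
}

#' Encode a training-folder name as a one-hot label vector
#'
#' Training frames are organised in folders named by the underscore-joined
#' labels visible in them, e.g. `"Environment_Forceps_Osteotome"`. Tokens
#' are matched case-insensitively.
#'
#' @param name Folder name (underscore-joined label tokens).
#' @return Named integer label vector (see [labels_to_vector()]).
#' @export
#' @examples
#' encode_folder_name("Environment_Forceps_Osteotome")
encode_folder_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  labels_to_vector(strsplit(name, "_", fixed = TRUE)[[1]])
}

#' Canonical folder name for a label set
#'
#' Inverse of [encode_folder_name()] up to token order: labels are joined by
#' underscores in canonical label order.
#'
#' @param labels Character vector of label names.
#' @return Folder name string ("Empty" for the empty set).
#' @export
folder_name_from_labels <- function(labels) {
  v <- labels_to_vector(labels)
  nm <- vector_to_labels(v)
  if (!length(nm)) return("Empty")
  paste(nm, collapse = "_")
}

# the eleven surgical phases and their right-phase tool sets
.phase_table <- function() {
  list(
    P1  = list(name = "Skin incision",                          tools = "Scalpel"),
    P2  = list(name = "Cranial surface exposure",               tools = c("Osteotome", "Forceps")),
    P3  = list(name = "Surgical cutting guides placement",      tools = c("SOGuide", "FTGuide")),
    P4  = list(name = "Fixation of registration pins",          tools = c("SOGuide", "FTGuide", "Handpiece")),
    P5  = list(name = "Registration",                           tools = c("Pointer", "SOGuide", "FTGuide")),
    P6  = list(name = "Frontal bone osteotomy",                 tools = "Motor"),
    P7  = list(name = "SO bar bone osteotomy",                  tools = c("Motor", "Osteotome")),
    P8  = list(name = "Intraoperative navigation of remodeled bones", tools = "Pointer"),
    P9  = list(name = "Screwing",                               tools = c("Handpiece", "Forceps")),
    P10 = list(name = "Skin placement",                         tools = "Forceps"),
    P11 = list(name = "Suturing",                               tools = c("Scissors", "Forceps"))
  )
}

#' Surgical phase specifications
#'
#' The eleven ordered phases (P1..P11) of the open cranial vault remodeling
#' workflow, each with the set of right-phase tools expected in the surgical
#' field. `Environment` is never a member of a phase tool set.
#'
#' @return Named list of 11 entries `list(name =, tools =)` keyed `P1`..`P11`.
#' @export
#' @examples
#' phase_specs()[["P4"]]
phase_specs <- function() .phase_table()

#' @rdname phase_specs
#' @export
phase_ids <- function() names(.phase_table())

#' Right-phase tool set of a phase
#'
#' @param id Phase id, one of `"P1"`..`"P11"`.
#' @return Character vector of tool names in canonical order.
#' @export
#' @examples
#' phase_tools("P4")
phase_tools <- function(id) {
  tab <- .phase_table()
  if (!is.character(id) || length(id) != 1L || is.na(match(id, names(tab))))
    stop("unknown phase id: ", sQuote(id), call. = FALSE)
  # canonical ordering for stable set comparisons
  vector_to_labels(labels_to_vector(tab[[id]]$tools))
}

#' Export / import phase specifications as JSON
#'
#' Phase definitions are serialised as a list of `{id, name, tools}` objects
#' so a different phase vocabulary can be substituted for the built-in one.
#'
#' @param path File path.
#' @param specs Named list in the shape of [phase_specs()].
#' @return `read_phase_specs()` returns the named list; `write_phase_specs()`
#'   returns `path` invisibly.
#' @export
write_phase_specs <- function(path, specs = phase_specs()) {
  obj <- lapply(names(specs), function(id) {
    list(id = id, name = specs[[id]]$name, tools = as.list(specs[[id]]$tools))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phase_specs
#' @export
read_phase_specs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (entry in obj) {
    if (is.null(entry$id) || is.null(entry$tools))
      stop("phase spec entries need 'id' and 'tools' fields", call. = FALSE)
    tools <- canonical_label(unlist(entry$tools))
    if ("Environment" %in% tools)
      stop("Environment cannot be a member of a phase tool set", call. = FALSE)
    out[[entry$id]] <- list(name = entry$name %||% entry$id, tools = tools)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
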