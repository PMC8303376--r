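#' Load labelled frames from a folder tree
#'
#' Each immediate sub-folder of `root` is named by the underscore-joined
#' labels of the frames it holds (see [encode_folder_name()]); an optional
#' suffix after a dot (e.g. `Environment.hands`) distinguishes recording
#' variants that share a label set and is ignored by the labeller. Frames
#' are read in sorted path order so the result is deterministic.
#'
#' @param root Directory containing label-combination folders.
#' @param preprocess Logical; apply [preprocess_frame()] to each image
#'   (default TRUE).
#' @return List of items `list(image =, labels =, path =, folder =)`.
#' @export
load_labeled_frames <- function(root, preprocess = TRUE) {
  stopifnot(dir.exists(root))
  folders <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(folders)) stop("no label-combination folders under ", root, call. = FALSE)
  items <- list()
  for (folder in folders) {
    base <- sub("\\.[^_]*$", "", folder)
    labels <- if (identical(base, "Empty")) labels_to_vector(character(0))
              else encode_folder_name(base)
    files <- sort(list.files(file.path(root, folder),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      img <- read_image(f)
      if (preprocess) img <- preprocess_frame(img)
      items[[length(items) + 1L]] <- list(image = img, labels = labels,
                                          path = f, folder = folder)
    }
  }
  items
}

#' Preprocess a frame for the network
#'
#' Resizes to the 64 x 64 network input (bilinear) and normalises pixel
#' values to \[0, 1\] (values above 1 are assumed 8-bit and divided by 255).
#'
#' @param img H x W x 3 numeric array with at least one pixel.
#' @param size Output side length (default 64).
#' @return `size` x `size` x 3 array with values in \[0, 1\].
#' @export
preprocess_frame <- function(img, size = 64L) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3 ||
      any(dim(img)[1:2] < 1) || !is.numeric(img))
    stop("expected an H x W x 3 numeric image array", call. = FALSE)
  if (max(img) > 1) img <- img / 255
  img <- pmin(pmax(img, 0), 1)
  resize_image(img, size, size)
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Split items into training and validation sets
#'
#' Items are first put in canonical order (by `$path` when present), then
#' shuffled with the given seed and partitioned with
#' `round(train_fraction * n)` training items, so the split is stable under
#' input reordering. The default 80:20 split of the full 9,934-frame
#' training corpus yields 7,947 training and 1,987 validation images.
#'
#' @param items List of items (as from [load_labeled_frames()]).
#' @param train_fraction Fraction of items used for training, in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return List with elements `train` and `validation` (disjoint, union =
#'   input).
#' @export
#' @examples
#' split_sizes(9934)
split_dataset <- function(items, train_fraction = 0.8, seed = 1L) {
  n <- length(items)
  if (n < 2) stop("need at least 2 items to split", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  paths <- vapply(items, function(it) it$path %||% NA_character_, character(1))
  if (!anyNA(paths)) items <- items[order(paths)]
  perm <- with_local_seed(seed, sample.int(n))
  n_train <- as.integer(round_half_up(train_fraction * n))
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = items[perm[seq_len(n_train)]],
       validation = items[perm[(n_train + 1L):n]])
}

#' @rdname split_dataset
#' @param n Total number of items.
#' @return `split_sizes()`: integer vector `c(train, validation)`.
#' @export
split_sizes <- function(n, train_fraction = 0.8) {
  n_train <- as.integer(round_half_up(train_fraction * n))
  c(train = n_train, validation = as.integer(n) - n_train)
}

#' Stack images and labels into batch arrays
#'
#' @param imgs List of H x W x C arrays of identical shape.
#' @return `stack_images()`: H x W x C x N array.
#' @export
stack_images <- function(imgs) {
  stopifnot(length(imgs) >= 1)
  d <- dim(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(d, length(imgs)))
}

#' @rdname stack_images
#' @param items List of items with `$labels`.
#' @return `labels_matrix()`: N x 10 binary matrix in canonical label order.
#' @export
labels_matrix <- function(items) {
  m <- do.call(rbind, lapply(items, function(it) as.numeric(it$labels)))
  colnames(m) <- tool_labels()
  m
}
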