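# Geometric image primitives shared by preprocessing and augmentation.
# Images are H x W x C numeric arrays in [0, 1]. Out-of-bounds samples are
# filled by nearest-edge replication so transformed frames never acquire
# black borders that could correlate with labels.

# bilinear sample at (row, col) coordinates given in 1-based pixel units
bilinear_sample <- function(img, rows, cols) {
  d <- dim(img)
  H <- d[1]; W <- d[2]; C <- d[3]
  rows <- pmin(pmax(rows, 1), H)
  cols <- pmin(pmax(cols, 1), W)
  r0 <- pmin(floor(rows), H - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(cols), W - 1L); c1 <- c0 + 1
  if (H == 1) { r0 <- r1 <- rep(1, length(rows)) }
  if (W == 1) { c0 <- c1 <- rep(1, length(cols)) }
  fr <- rows - r0; fc <- cols - c0
  n <- length(rows)
  res <- matrix(0, n, C)
  for (ch in seq_len(C)) {
    plane <- img[, , ch]
    i00 <- plane[cbind(r0, c0)]; i01 <- plane[cbind(r0, c1)]
    i10 <- plane[cbind(r1, c0)]; i11 <- plane[cbind(r1, c1)]
    res[, ch] <- (1 - fr) * ((1 - fc) * i00 + fc * i01) +
                 fr * ((1 - fc) * i10 + fc * i11)
  }
  res
}

#' Resize an image with bilinear interpolation
#'
#' @param img H x W x C numeric array.
#' @param out_h,out_w Output height and width in pixels.
#' @return `out_h` x `out_w` x C array.
#' @export
resize_image <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  # map output pixel centres onto input pixel centres
  rows <- (seq_len(out_h) - 0.5) * d[1] / out_h + 0.5
  cols <- (seq_len(out_w) - 0.5) * d[2] / out_w + 0.5
  rr <- rep(rows, times = out_w)
  cc <- rep(cols, each = out_h)
  res <- bilinear_sample(img, rr, cc)
  array(res, c(out_h, out_w, d[3]))
}

#' Augmentation configuration
#'
#' The random geometric transforms applied on the fly during training:
#' rotation, width/height shift, shear, zoom and horizontal flip, each
#' parameter drawn uniformly within its range per presented image.
#'
#' @param rotation Max absolute rotation in degrees (default 15).
#' @param width_shift,height_shift Max absolute shift as a fraction of the
#'   image width/height (default 0.10).
#' @param shear Max absolute shear intensity (default 0.50).
#' @param zoom Max absolute zoom deviation; the scale factor is drawn from
#'   `[1 - zoom, 1 + zoom]` (default 0.10).
#' @param horizontal_flip Logical; flip with probability 0.5 (default TRUE).
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(rotation = 15, width_shift = 0.10,
                           height_shift = 0.10, shear = 0.50, zoom = 0.10,
                           horizontal_flip = TRUE) {
  stopifnot(rotation >= 0, width_shift >= 0, height_shift >= 0,
            shear >= 0, zoom >= 0, zoom < 1, is.logical(horizontal_flip))
  structure(list(rotation = rotation, width_shift = width_shift,
                 height_shift = height_shift, shear = shear, zoom = zoom,
                 horizontal_flip = isTRUE(horizontal_flip)),
            class = "augment_config")
}

#' Sample one set of augmentation parameters
#'
#' Exposed separately so tests can check the sampling distributions and so
#' transforms can be forced (e.g. a guaranteed flip).
#'
#' @param cfg An [augment_config()].
#' @return List with `angle` (degrees), `tx`, `ty` (fractions), `shear`,
#'   `zoom`, `flip` (logical).
#' @export
sample_augment_params <- function(cfg) {
  list(angle = stats::runif(1, -cfg$rotation, cfg$rotation),
       tx = stats::runif(1, -cfg$width_shift, cfg$width_shift),
       ty = stats::runif(1, -cfg$height_shift, cfg$height_shift),
       shear = stats::runif(1, -cfg$shear, cfg$shear),
       zoom = stats::runif(1, 1 - cfg$zoom, 1 + cfg$zoom),
       flip = cfg$horizontal_flip && stats::runif(1) < 0.5)
}

.identity_params <- function(p) {
  p$angle == 0 && p$tx == 0 && p$ty == 0 && p$shear == 0 && p$zoom == 1
}

#' Apply a random geometric augmentation to an image
#'
#' Applies rotation, shift, shear and zoom about the image centre as one
#' composed affine transform (bilinear sampling, nearest-edge fill),
#' followed by an exact horizontal flip when drawn. Labels are unaffected
#' by construction. With all ranges zero and flipping disabled the
#' transform is the identity.
#'
#' @param img H x W x C array.
#' @param cfg An [augment_config()].
#' @param params Optional parameter list as from [sample_augment_params()];
#'   sampled from `cfg` when `NULL`.
#' @return Transformed array of the same shape.
#' @export
augment_frame <- function(img, cfg = augment_config(), params = NULL) {
  d <- dim(img)
  stopifnot(length(d) == 3)
  if (is.null(params)) params <- sample_augment_params(cfg)
  out <- img
  if (!.identity_params(params)) {
    th <- params$angle * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Sh <- matrix(c(1, 0, params$shear, 1), 2, 2)
    Z <- diag(c(params$zoom, params$zoom))
    M <- R %*% Sh %*% Z
    Minv <- solve(M)
    cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
    ty <- params$ty * d[1]; tx <- params$tx * d[2]
    gy <- rep(seq_len(d[1]), times = d[2]) - cy - ty
    gx <- rep(seq_len(d[2]), each = d[1]) - cx - tx
    src_y <- Minv[1, 1] * gy + Minv[1, 2] * gx + cy
    src_x <- Minv[2, 1] * gy + Minv[2, 2] * gx + cx
    out <- array(bilinear_sample(img, src_y, src_x), d)
  }
  if (isTRUE(params$flip)) out <- out[, rev(seq_len(d[2])), , drop = FALSE]
  out
}
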