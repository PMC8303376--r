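#' Synthetic scene configuration
#'
#' Parameters of the procedural scene renderer that emulates the recording
#' conditions of the phantom surgery: a wrinkled green surgical sheet, the
#' skin-coloured patient phantom, blue-gloved hands that partially occlude
#' the field, and illumination that varies between natural light, artificial
#' light and moving shadows.
#'
#' @param size Image side length in pixels (square frames, >= 32; default 64,
#'   the network input size).
#' @param bg_green Base RGB of the surgical sheet.
#' @param wrinkle_amplitude Amplitude of the low-frequency shading that
#'   emulates sheet wrinkles (0 disables).
#' @param brightness_range Two-element range the global brightness scale is
#'   drawn from per frame.
#' @param light_gradient Logical; add a random linear illumination gradient
#'   (moving-shadow emulation).
#' @param occluder_prob Probability that a blue-glove ellipse partially
#'   occludes the scene.
#' @param occluder_size Two-element range of the occluder radius as a
#'   fraction of the image side.
#' @param environment_visible Logical; render the phantom/backdrop (sets the
#'   `Environment` bit). On by default, matching the recordings where the
#'   phantom is always in the field; disable for ablation scenes.
#' @param seed Base RNG seed used by the generators that consume the config.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(size = 64L,
                         bg_green = c(0.10, 0.48, 0.16),
                         wrinkle_amplitude = 0.08,
                         brightness_range = c(0.75, 1.25),
                         light_gradient = TRUE,
                         occluder_prob = 0.3,
                         occluder_size = c(0.15, 0.35),
                         environment_visible = TRUE,
                         seed = 1L) {
  stopifnot(size >= 32, all(brightness_range > 0),
            occluder_prob >= 0, occluder_prob <= 1,
            wrinkle_amplitude >= 0, length(occluder_size) == 2)
  structure(list(size = as.integer(size), bg_green = bg_green,
                 wrinkle_amplitude = wrinkle_amplitude,
                 brightness_range = sort(brightness_range),
                 light_gradient = isTRUE(light_gradient),
                 occluder_prob = occluder_prob,
                 occluder_size = sort(occluder_size),
                 environment_visible = isTRUE(environment_visible),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# distinct colour per glyph; chosen to be separable from the green sheet
.glyph_colors <- function() {
  list(Forceps   = c(0.95, 0.10, 0.85),
       FTGuide   = c(0.98, 0.92, 0.10),
       Handpiece = c(0.55, 0.10, 0.80),
       Motor     = c(0.05, 0.10, 0.50),
       Osteotome = c(0.95, 0.55, 0.10),
       Pointer   = c(0.90, 0.08, 0.08),
       Scalpel   = c(0.70, 0.78, 0.96),  # steel tint, distinct from bright skin
       Scissors  = c(0.04, 0.04, 0.04),
       SOGuide   = c(0.05, 0.85, 0.90))
}

# mask of a tool glyph in rotated local coordinates (u, v), half-size a.
# Each tool has a distinct shape so presence is learnable from either colour
# or geometry.
.glyph_mask <- function(tool, u, v, a) {
  switch(tool,
    Scalpel   = abs(u) <= a & abs(v) <= 0.18 * a,
    Osteotome = abs(u) <= 0.8 * a & abs(v) <= 0.45 * a,
    Forceps   = abs(u) <= a & abs(v - 0.6 * abs(u)) <= 0.22 * a,
    SOGuide   = { r <- sqrt(u^2 + v^2); r >= 0.55 * a & r <= a },
    FTGuide   = { m <- pmax(abs(u), abs(v)); m >= 0.55 * a & m <= a },
    Handpiece = (abs(u) <= 0.7 * a & abs(v) <= 0.3 * a) |
                 sqrt((u - 0.7 * a)^2 + v^2) <= 0.35 * a,
    Pointer   = u >= -a & u <= a & abs(v) <= 0.5 * a * (1 - (u + a) / (2 * a)),
    Motor     = sqrt(u^2 + v^2) <= 0.75 * a,
    Scissors  = abs(u) <= a & (abs(v - 0.7 * u) <= 0.2 * a |
                               abs(v + 0.7 * u) <= 0.2 * a),
    stop("no glyph for tool ", sQuote(tool), call. = FALSE)
  )
}

# evaluate code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render one synthetic surgical-field frame
#'
#' Draws the requested tools as deterministic glyphs (a distinct shape and
#' colour per tool) at randomised position, rotation and scale over the
#' procedural sheet/phantom background, then applies the illumination model
#' and (optionally) a blue-glove occluder. The same `seed` and tool set give
#' a bit-identical image.
#'
#' @param tools Character vector of labels visible in the frame (subset of
#'   [tool_labels()]). `Environment` in `tools` is accepted but redundant:
#'   the bit follows `cfg$environment_visible`.
#' @param cfg A [scene_config()].
#' @param seed Integer seed for this frame; `NULL` uses (and advances) the
#'   current RNG state.
#' @return List with `image` (size x size x 3 array in \[0, 1\]) and `labels`
#'   (one-hot vector, see [labels_to_vector()]).
#' @export
#' @examples
#' fr <- render_frame(c("Scalpel"), scene_config(), seed = 7)
#' dim(fr$image)
#' vector_to_labels(fr$labels)
render_frame <- function(tools, cfg = scene_config(), seed = NULL) {
  tools <- if (length(tools)) canonical_label(tools) else character(0)
  stopifnot(all(tools %in% tool_labels()))
  with_local_seed(seed, .render_frame_impl(tools, cfg))
}

.render_frame_impl <- function(tools, cfg) {
  S <- cfg$size
  xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
  ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index

  # surgical sheet with wrinkle shading (sum of random plane waves)
  shade <- matrix(0, S, S)
  for (k in 1:3) {
    th <- stats::runif(1, 0, pi)
    freq <- stats::runif(1, 1.5, 4.5) * 2 * pi / S
    ph <- stats::runif(1, 0, 2 * pi)
    shade <- shade + sin((cos(th) * xs + sin(th) * ys) * freq + ph)
  }
  shade <- 1 + cfg$wrinkle_amplitude * shade / 3
  img <- array(0, c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- cfg$bg_green[ch] * shade

  paint <- function(mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <<- plane
    }
  }

  # patient phantom: skin-coloured ellipse anchored in one image corner
  if (cfg$environment_visible) {
    cx <- stats::runif(1, 0.15, 0.35) * S
    cy <- stats::runif(1, 0.60, 0.85) * S
    rx <- stats::runif(1, 0.20, 0.30) * S
    ry <- stats::runif(1, 0.15, 0.25) * S
    paint(((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1, c(0.93, 0.78, 0.62))
  }

  cols <- .glyph_colors()
  for (tool in setdiff(tools, "Environment")) {
    cx <- stats::runif(1, 0.22, 0.78) * S
    cy <- stats::runif(1, 0.22, 0.78) * S
    a <- stats::runif(1, 0.16, 0.28) * S
    th <- stats::runif(1, 0, 2 * pi)
    u <- cos(th) * (xs - cx) + sin(th) * (ys - cy)
    v <- -sin(th) * (xs - cx) + cos(th) * (ys - cy)
    paint(.glyph_mask(tool, u, v, a), cols[[tool]])
  }

  # blue-glove occluder, drawn over everything; anchored on the image border
  # (hands reach into the field from its edge), so tools are covered only
  # partially, as in the recordings
  if (stats::runif(1) < cfg$occluder_prob) {
    side <- sample.int(4L, 1L)
    along <- stats::runif(1, 0, 1) * S
    cx <- switch(side, along, along, 0, S)
    cy <- switch(side, 0, S, along, along)
    r <- stats::runif(1, cfg$occluder_size[1], cfg$occluder_size[2]) * S
    ecc <- stats::runif(1, 0.6, 1.4)
    paint(((xs - cx) / r)^2 + ((ys - cy) / (r * ecc))^2 <= 1, c(0.12, 0.30, 0.88))
  }

  # illumination: global brightness draw plus optional linear gradient
  b <- stats::runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
  light <- matrix(b, S, S)
  if (cfg$light_gradient) {
    g <- stats::runif(1, -0.25, 0.25)
    th <- stats::runif(1, 0, 2 * pi)
    ramp <- (cos(th) * (xs - S / 2) + sin(th) * (ys - S / 2)) / S
    light <- light * (1 + g * ramp)
  }
  for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] * light, 0), 1)

  labels <- labels_to_vector(setdiff(tools, "Environment"))
  if (cfg$environment_visible) labels["Environment"] <- 1L
  list(image = img, labels = labels)
}
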