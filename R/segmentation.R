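#' Default colour-rule thresholds for plant segmentation
#'
#' The segmenter works in hue-saturation-value space: a pixel is plant
#' tissue when its hue falls in a green window with enough saturation and
#' brightness, and it is not captured by the blue cage rule. Hues are on
#' the \[0, 1\] scale of [grDevices::rgb2hsv()] (green around 1/3, blue
#' around 2/3). The defaults are tuned to the synthetic palette of
#' [scene_spec()]; for real imagery they are the knobs to adjust in the
#' pipeline config.
#'
#' @return a named list with `plant_hue` (length-2 window), `plant_sat`,
#'   `plant_val` (minima), `cage_hue` (length-2 window) and `cage_sat`.
#' @export
default_thresholds <- function() {
  list(plant_hue = c(0.18, 0.45), plant_sat = 0.20, plant_val = 0.10,
       cage_hue = c(0.52, 0.80), cage_sat = 0.20)
}

as_rgb255 <- function(rgb) {
  d <- dim(rgb)
  if (is.null(d) || length(d) != 3L || d[3] < 3L)
    stop_bad_arg("rgb", "must be a height x width x 3 array")
  rgb <- rgb[, , 1:3, drop = FALSE]
  if (max(rgb) <= 1) rgb <- rgb * 255
  rgb
}

#' Segment plant pixels from an RGB image by a colour rule
#'
#' Marks as plant every pixel inside the green hue/saturation/value window
#' that is not inside the blue (cage) window. An image with no plant-like
#' pixel yields an all-`FALSE` mask (flagged on the log stream, not an
#' error), so batch runs continue past failed acquisitions.
#'
#' @param rgb a height x width x 3 array, either on the 0-255 or the 0-1
#'   scale.
#' @param thresholds colour rule, see [default_thresholds()].
#' @return a logical matrix of the image size; `TRUE` marks plant pixels.
#' @export
segment_plant <- function(rgb, thresholds = default_thresholds()) {
  rgb <- as_rgb255(rgb)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                            as.vector(rgb[, , 3]), maxColorValue = 255)
  th <- thresholds
  is_plant <- hsv[1, ] >= th$plant_hue[1] & hsv[1, ] <= th$plant_hue[2] &
    hsv[2, ] >= th$plant_sat & hsv[3, ] >= th$plant_val
  is_cage <- hsv[1, ] >= th$cage_hue[1] & hsv[1, ] <= th$cage_hue[2] &
    hsv[2, ] >= th$cage_sat
  mask <- matrix(is_plant & !is_cage, h, w)
  if (!any(mask)) pv_log("segment_plant: empty plant mask")
  mask
}

#' Label 8-connected components of a binary mask
#'
#' Components are connected sets of `TRUE` pixels under 8-neighbour
#' adjacency (edges and corners). Implemented as connected components of
#' the pixel adjacency graph.
#'
#' @param mask a logical matrix.
#' @return an integer matrix of the same size; 0 for background, else the
#'   component id (ids are in first-pixel column-major order).
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  k <- length(idx)
  if (k == 0L) return(lab)
  id <- integer(length(mask))
  id[idx] <- seq_len(k)
  h <- nrow(mask)
  rows <- ((idx - 1L) %% h) + 1L
  edges <- integer(0)
  # link each true pixel to its S, E, SE and NE true neighbours (covers
  # all 8 directions once)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- off[1]; dc <- off[2]
    nb <- idx + dr + dc * h
    ok <- rows + dr >= 1L & rows + dr <= h & nb >= 1L & nb <= length(mask)
    ok[ok] <- mask[nb[ok]]
    if (any(ok)) edges <- c(edges, rbind(id[idx[ok]], id[nb[ok]]))
  }
  g <- igraph::make_graph(edges, n = k, directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Remove small connected components from a plant mask
#'
#' Drops 8-connected components with fewer than `min_size` pixels, the
#' standard speckle-noise clean-up after colour segmentation. All other
#' pixels are unchanged.
#'
#' @param mask a logical matrix.
#' @param min_size minimum surviving component size in pixels (>= 1).
#' @return the denoised logical mask.
#' @export
denoise_mask <- function(mask, min_size = 50L) {
  if (!is_count(min_size)) stop_bad_arg("min_size", "must be >= 1")
  if (min_size == 1L || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}
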