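#' Specify a synthetic multi-view plant scene
#'
#' Describes one plant-day's worth of imagery as captured on a
#' conveyor-type imaging chamber: one top view and three side views (plant
#' rotated by 0/120/240 degrees), with green plant tissue, a blue support
#' cage and a near-white pot/background. The three colours must be
#' separable under the additive image noise, which is what makes a simple
#' colour rule a correct segmenter; the validator enforces a pairwise
#' separation of more than `2 * noise_sd` in at least one channel.
#'
#' Plant and cage geometry can be given explicitly as pixel coordinate
#' matrices (used identically in all four views), or generated
#' parametrically: side views get a vertical stem with leaf blobs, the top
#' view a rosette of blobs, both grown/trimmed to an exact target pixel
#' count so segmentation tests have an exact oracle.
#'
#' @param width,height image size in pixels.
#' @param plant_shape either `NULL` (parametric generation) or a two-column
#'   integer matrix of (row, col) plant pixels, rows indexed from the image
#'   top.
#' @param cage_shape either `NULL` (parametric wires/ring), `NA` (no cage)
#'   or a two-column (row, col) matrix. Where cage and plant overlap the
#'   cage wins (it sits in front of the plant).
#' @param target_px plant pixels per view for parametric shapes: a single
#'   count used for every view, or a length-4 vector in view order (top,
#'   side0, side120, side240).
#' @param leaf_count,leaf_radius parametric shape knobs: number and radius
#'   (pixels) of leaf blobs.
#' @param plant_colour,cage_colour,background_colour RGB triples on the
#'   0-255 scale.
#' @param noise_sd standard deviation of the independent per-channel
#'   additive Gaussian noise (0-255 scale); clipped to the valid range.
#' @param seed integer seed; one seed drives the whole scene (shapes for
#'   all four views, then noise) so [make_scene()] is deterministic.
#' @return an object of class `scene_spec`.
#' @seealso [make_scene()]
#' @export
scene_spec <- function(width = 200L, height = 200L,
                       plant_shape = NULL, cage_shape = NULL,
                       target_px = 2000L, leaf_count = 8L, leaf_radius = 6L,
                       plant_colour = c(50, 180, 60),
                       cage_colour = c(40, 60, 200),
                       background_colour = c(245, 245, 245),
                       noise_sd = 0, seed = 1L) {
  if (!is_count(width) || !is_count(height))
    stop_bad_arg("width/height", "must be positive integers")
  for (nm in c("plant_colour", "cage_colour", "background_colour")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(v < 0) || any(v > 255))
      stop_bad_arg(nm, "must be an RGB triple in [0, 255]")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop_bad_arg("noise_sd", "must be a single non-negative number")
  sep <- function(a, b) max(abs(a - b))
  if (sep(plant_colour, cage_colour) <= 2 * noise_sd ||
      sep(plant_colour, background_colour) <= 2 * noise_sd ||
      sep(cage_colour, background_colour) <= 2 * noise_sd)
    stop_bad_arg("noise_sd",
      "plant, cage and background colours must differ by more than 2*noise_sd in some channel")
  check_shape <- function(m, nm) {
    if (is.null(m) || (length(m) == 1L && is.na(m))) return(m)
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop_bad_arg(nm, "must be a two-column (row, col) matrix")
    if (nrow(m) == 0L) stop_bad_arg(nm, "must be non-empty")
    if (any(m < 1) || any(m[, 1] > height) || any(m[, 2] > width))
      stop_bad_arg(nm, "pixels fall outside the image bounds")
    storage.mode(m) <- "integer"
    m
  }
  plant_shape <- check_shape(plant_shape, "plant_shape")
  if (is.null(plant_shape)) {
    if (!length(target_px) %in% c(1L, 4L) || !all(vapply(target_px, is_count, logical(1))))
      stop_bad_arg("target_px", "must be one positive integer or four (per view)")
    if (length(target_px) == 1L) target_px <- rep(target_px, 4L)
    names(target_px) <- view_names()
  }
  cage_shape <- check_shape(cage_shape, "cage_shape")
  structure(list(width = as.integer(width), height = as.integer(height),
                 plant_shape = plant_shape, cage_shape = cage_shape,
                 target_px = if (is.null(plant_shape))
                   stats::setNames(as.integer(target_px), view_names())
                 else NULL,
                 leaf_count = as.integer(leaf_count),
                 leaf_radius = as.integer(leaf_radius),
                 plant_colour = as.numeric(plant_colour),
                 cage_colour = as.numeric(cage_colour),
                 background_colour = as.numeric(background_colour),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "scene_spec")
}

view_names <- function() c("top", "side0", "side120", "side240")

# Paint a disc of radius `rad` centred at (r0, c0) into logical matrix occ.
paint_disc <- function(occ, r0, c0, rad) {
  h <- nrow(occ); w <- ncol(occ)
  rr <- max(1L, floor(r0 - rad)):min(h, ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(w, ceiling(c0 + rad))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  occ[rr, cc] <- occ[rr, cc] | (d2 <= rad^2)
  occ
}

# Grow or trim an occupancy mask to exactly `target` pixels. Trimming keeps
# the pixels nearest the shape centroid; growing adds 8-connected boundary
# pixels nearest the centroid (never into `avoid` cells, e.g. the cage),
# so the silhouette stays compact.
adjust_to_target <- function(occ, target, avoid = NULL) {
  n <- sum(occ)
  if (n == 0L) stop("cannot adjust an empty shape")
  pix <- which(occ, arr.ind = TRUE)
  rc <- colMeans(pix)
  if (n > target) {
    d <- (pix[, 1] - rc[1])^2 + (pix[, 2] - rc[2])^2
    keep <- pix[order(d, pix[, 1], pix[, 2])[seq_len(target)], , drop = FALSE]
    occ[] <- FALSE
    occ[keep] <- TRUE
    return(occ)
  }
  while (n < target) {
    nb <- dilate8(occ) & !occ
    if (!is.null(avoid)) nb <- nb & !avoid
    cand <- which(nb, arr.ind = TRUE)
    if (nrow(cand) == 0L) stop("shape cannot grow to the target pixel count")
    d <- (cand[, 1] - rc[1])^2 + (cand[, 2] - rc[2])^2
    take <- cand[order(d, cand[, 1], cand[, 2])[seq_len(min(nrow(cand), target - n))],
                 , drop = FALSE]
    occ[take] <- TRUE
    n <- sum(occ)
  }
  occ
}

# 8-connected binary dilation by one pixel, via shifted copies.
dilate8 <- function(occ) {
  h <- nrow(occ); w <- ncol(occ)
  out <- occ
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rs <- max(1L, 1L + dr):min(h, h + dr)
    rt <- max(1L, 1L - dr):min(h, h - dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    ct <- max(1L, 1L - dc):min(w, w - dc)
    out[rt, ct] <- out[rt, ct] | occ[rs, cs]
  }
  out
}

# Parametric plant silhouettes. Side views: a stem rising from near the
# pot rim with leaf blobs scattered along it; top view: a rosette of
# blobs around the image centre. Both are adjusted to exactly `target` px.
plant_silhouette <- function(spec, view, target) {
  h <- spec$height; w <- spec$width
  occ <- matrix(FALSE, h, w)
  n_blob <- max(1L, spec$leaf_count)
  rad <- max(2, spec$leaf_radius)
  # enough blob area to reach the target before adjustment
  rad <- max(rad, ceiling(sqrt(target / (pi * n_blob)) * 1.2))
  if (view == "top") {
    r0 <- h / 2; c0 <- w / 2
    occ <- paint_disc(occ, r0, c0, rad)
    ang <- stats::runif(n_blob, 0, 2 * pi)
    rr <- stats::runif(n_blob, 0.5, 1.6) * rad
    for (i in seq_len(n_blob))
      occ <- paint_disc(occ, r0 + rr[i] * sin(ang[i]), c0 + rr[i] * cos(ang[i]), rad)
  } else {
    base <- h - max(3L, round(h * 0.03))
    top <- max(2L, round(h * 0.12))
    cmid <- w / 2
    stem_rows <- top:base
    sw <- 1L
    cc <- pmin(w, pmax(1L, round(cmid) + (-sw):sw))
    occ[stem_rows, cc] <- TRUE
    at <- stats::runif(n_blob, 0.05, 0.95)
    off <- stats::runif(n_blob, -0.9, 0.9) * rad   # blobs overlap the stem
    for (i in seq_len(n_blob)) {
      r0 <- top + at[i] * (base - top)
      occ <- paint_disc(occ, r0, cmid + off[i], rad)
    }
  }
  adjust_to_target(occ, target)
}

# Default cage geometry: two vertical wires in side views, a thin ring in
# the top view (the blue support cage of the imaging setup).
cage_silhouette <- function(spec, view) {
  h <- spec$height; w <- spec$width
  occ <- matrix(FALSE, h, w)
  if (view == "top") {
    r0 <- h / 2; c0 <- w / 2
    rad <- min(h, w) * 0.35
    rr <- seq_len(h); cc <- seq_len(w)
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    occ <- abs(d - rad) <= 1
  } else {
    for (cx in round(c(0.3, 0.7) * w)) {
      cc <- pmin(w, pmax(1L, cx + 0:1))
      occ[round(h * 0.15):(h - 2L), cc] <- TRUE
    }
  }
  occ
}

shape_to_mask <- function(shape, h, w) {
  occ <- matrix(FALSE, h, w)
  occ[shape] <- TRUE
  occ
}

#' Render a synthetic multi-view scene with ground truth
#'
#' Paints one top view and three side views: background colour everywhere,
#' plant colour on the plant silhouette and cage colour on the cage
#' geometry, the cage occluding the plant where the two overlap. Gaussian
#' per-channel noise (`spec$noise_sd`) is then added independently per
#' pixel and clipped to \[0, 255\]. The ground truth (per-view plant pixel
#' counts, top-view hull area, per-side-view bounding heights) is computed
#' from the noiseless label masks, so it is invariant to the noise level.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `multi_view_scene` with elements
#'   * `images`: named list (`top`, `side0`, `side120`, `side240`) of
#'     height x width x 3 arrays on the 0-255 scale;
#'   * `masks`: the noiseless plant label masks (logical matrices);
#'   * `truth`: list with `plant_px` (named per-view counts), `hull_px`
#'     (top-view filled convex-hull pixel area) and `height_px` (named
#'     per-side-view plant heights).
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    images <- list(); masks <- list(); cages <- list()
    # all geometry is drawn before any noise so the silhouettes (and hence
    # the ground truth) do not depend on noise_sd
    for (v in view_names()) {
      cm <- if (is.null(spec$cage_shape)) cage_silhouette(spec, v)
            else if (length(spec$cage_shape) == 1L && is.na(spec$cage_shape))
              matrix(FALSE, h, w)
            else shape_to_mask(spec$cage_shape, h, w)
      if (is.null(spec$plant_shape)) {
        pm <- plant_silhouette(spec, v, spec$target_px[[v]])
        pm_vis <- pm & !cm            # cage occludes plant ...
        if (sum(pm_vis) != spec$target_px[[v]])  # ... but the visible plant
          pm_vis <- adjust_to_target(pm_vis, spec$target_px[[v]], avoid = cm)
      } else {                        # still hits the requested pixel count
        pm_vis <- shape_to_mask(spec$plant_shape, h, w) & !cm
      }
      masks[[v]] <- pm_vis
      cages[[v]] <- cm
    }
    for (v in view_names()) {
      img <- array(0, dim = c(h, w, 3))
      for (k in 1:3) {
        ch <- matrix(spec$background_colour[k], h, w)
        ch[masks[[v]]] <- spec$plant_colour[k]
        ch[cages[[v]]] <- spec$cage_colour[k]
        img[, , k] <- ch
      }
      if (spec$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
        img[img < 0] <- 0; img[img > 255] <- 255
      }
      images[[v]] <- round(img)
    }
    truth <- list(
      plant_px = vapply(masks, sum, numeric(1)),
      hull_px = if (sum(masks$top) > 0) hull_fill_count(masks$top) else 0,
      height_px = vapply(masks[c("side0", "side120", "side240")],
                         function(m) if (sum(m) > 0) plant_height(m) else 0,
                         numeric(1)))
    structure(list(images = images, masks = masks, truth = truth,
                   spec = spec), class = "multi_view_scene")
  })
}
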