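# Digital trait extraction: convex-hull canopy area, plant height and the
# per-plant-day trait record combining all four views.

# Filled convex hull of a mask, counted in pixels. The hull is taken over
# the *squares* of the true pixels (all four cell corners), and a grid
# cell counts as covered when its centre lies in the closed hull. This
# makes the hull a superset of the mask, so compactness (area / hull
# area) can never exceed 1.
hull_fill_count <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0L) stop("no plant object: empty mask", call. = FALSE)
  if (n == 1L) return(1L)
  # corner points of each true cell, (x, y) = (col, row) centre +- 1/2
  x <- c(pix[, 2] - 0.5, pix[, 2] + 0.5, pix[, 2] - 0.5, pix[, 2] + 0.5)
  y <- c(pix[, 1] - 0.5, pix[, 1] - 0.5, pix[, 1] + 0.5, pix[, 1] + 0.5)
  hidx <- grDevices::chull(x, y)
  hx <- x[hidx]; hy <- y[hidx]
  # chull returns clockwise order in (x, y); orient counter-clockwise
  m <- length(hx)
  area2 <- sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  # candidate cells: bounding box of the mask (hull cannot exceed it)
  rr <- min(pix[, 1]):max(pix[, 1])
  cc <- min(pix[, 2]):max(pix[, 2])
  px <- rep(cc, each = length(rr))
  py <- rep(rr, times = length(cc))
  inside <- rep(TRUE, length(px))
  eps <- 1e-9 * max(1, max(abs(x)), max(abs(y)))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & cross >= -eps
    if (!any(inside)) break
  }
  sum(inside)
}

#' Top-view convex-hull area in kilopixels
#'
#' Area of the filled convex hull of the plant object, the canopy-spread
#' trait measured on top-view images. The hull envelope is rasterized back
#' onto the pixel grid and counted, then scaled to kilopixels, so the
#' value is directly comparable with the plant pixel area and their ratio
#' (canopy compactness) is bounded by 1.
#'
#' @param mask logical plant mask with at least one `TRUE` pixel.
#' @return hull area in kilopixels (pixel count / 1000).
#' @export
convex_hull_area <- function(mask) {
  hull_fill_count(mask) / 1000
}

#' Plant height from a side-view mask
#'
#' Row extent of the plant object: `max(row) - min(row) + 1` over true
#' pixels, rows counted from the image top (the height of the bounding
#' rectangle drawn around the segmented plant).
#'
#' @param mask logical plant mask with at least one `TRUE` pixel.
#' @return height in pixels.
#' @export
plant_height <- function(mask) {
  rows <- which(mask, arr.ind = TRUE)[, 1]
  if (length(rows) == 0L) stop("no plant object: empty mask", call. = FALSE)
  max(rows) - min(rows) + 1L
}

#' Bundle one plant-day's four views
#'
#' @param top RGB array for the top view.
#' @param sides named or ordered list of the three side-view RGB arrays
#'   (rotations 0, 120 and 240 degrees).
#' @param plant_id,genotype identifiers.
#' @param das integer days after sowing.
#' @return an object of class `multi_view_set`.
#' @export
multi_view_set <- function(top, sides, plant_id = "plant", genotype = "genotype",
                           das = NA_integer_) {
  if (length(sides) != 3L)
    stop_bad_arg("sides", "exactly three side views are required")
  names(sides) <- c("side0", "side120", "side240")
  structure(list(plant_id = plant_id, genotype = genotype,
                 das = as.integer(das), top = top, sides = sides),
            class = "multi_view_set")
}

#' Extract the digital vigour traits from a multi-view image set
#'
#' Runs colour segmentation ([segment_plant()]) and component denoising
#' ([denoise_mask()]) on all four views, then computes the trait record:
#' * `eb_kpix` — estimated shoot biomass: sum of the plant pixel counts of
#'   the three side views and the top view, in kilopixels;
#' * `tva_kpix` — top-view area: top-view plant pixel count / 1000;
#' * `tvch_kpix` — top-view convex hull area ([convex_hull_area()]);
#' * `tvcom` — top-view compactness, `tva / tvch` (in \[0, 1\]);
#' * `eh_px` — estimated plant height: maximum [plant_height()] over the
#'   three side views.
#'
#' A view whose denoised mask is empty does not abort the record: the
#' traits that depend on it are reported `NA` and the view is listed in
#' the `flags` column.
#'
#' @param imageset a [multi_view_set()].
#' @param thresholds colour rule, see [default_thresholds()].
#' @param min_size component denoising threshold in pixels.
#' @return a one-row `data.frame` with columns `plant_id`, `genotype`,
#'   `das`, `eb_kpix`, `tva_kpix`, `tvch_kpix`, `tvcom`, `eh_px`, `flags`.
#' @export
extract_traits <- function(imageset, thresholds = default_thresholds(),
                           min_size = 50L) {
  stopifnot(inherits(imageset, "multi_view_set"))
  views <- c(list(top = imageset$top), imageset$sides)
  masks <- lapply(views, function(img)
    denoise_mask(segment_plant(img, thresholds), min_size))
  counts <- vapply(masks, sum, numeric(1))
  empty <- names(counts)[counts == 0]
  if (length(empty))
    pv_log("extract_traits: empty mask in view(s) ", paste(empty, collapse = ","))
  side_nm <- c("side0", "side120", "side240")
  eb <- if (any(counts == 0)) NA_real_ else sum(counts) / 1000
  tva <- if (counts["top"] == 0) NA_real_ else counts[["top"]] / 1000
  tvch <- if (counts["top"] == 0) NA_real_ else convex_hull_area(masks$top)
  tvcom <- if (is.na(tva)) NA_real_ else tva / tvch
  heights <- counts[side_nm]
  eh <- if (all(counts[side_nm] == 0)) NA_real_ else
    max(vapply(masks[side_nm][counts[side_nm] > 0], plant_height, numeric(1)))
  data.frame(plant_id = imageset$plant_id, genotype = imageset$genotype,
             das = imageset$das, eb_kpix = eb, tva_kpix = tva,
             tvch_kpix = tvch, tvcom = tvcom, eh_px = eh,
             flags = if (length(empty)) paste("empty", paste(empty, collapse = "+"))
                     else "", stringsAsFactors = FALSE)
}
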