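# Independent oracles and small fixture builders used across the suite.

mask_from_pixels <- function(px, h, w) {
  m <- matrix(FALSE, h, w)
  m[as.matrix(px)] <- TRUE
  m
}

# Brute-force filled convex hull by separating-line search: a candidate
# cell centre lies outside the hull of the true-pixel squares iff some
# line through two corner points has every corner weakly on one side and
# the candidate strictly on the other. Independent of chull().
brute_hull_fill <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(pix) >= 1)
  x <- c(pix[, 2] - 0.5, pix[, 2] + 0.5, pix[, 2] - 0.5, pix[, 2] + 0.5)
  y <- c(pix[, 1] - 0.5, pix[, 1] - 0.5, pix[, 1] + 0.5, pix[, 1] + 0.5)
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  rr <- min(pix[, 1]):max(pix[, 1])
  cc <- min(pix[, 2]):max(pix[, 2])
  cand <- cbind(rep(cc, each = length(rr)), rep(rr, times = length(cc)))
  outside <- rep(FALSE, nrow(cand))
  eps <- 1e-9
  for (i in seq_len(n)) {
    dx <- pts[, 1] - pts[i, 1]
    dy <- pts[, 2] - pts[i, 2]
    ax <- pts[, 1] - pts[i, 1]
    ay <- pts[, 2] - pts[i, 2]
    # cross[j, s] of direction j with point s, both relative to pts[i, ]
    cr <- outer(dx, ay) - outer(dy, ax)
    jmin <- cr[cbind(seq_len(n), max.col(-cr, ties.method = "first"))]
    jmax <- cr[cbind(seq_len(n), max.col(cr, ties.method = "first"))]
    cx <- cand[, 1] - pts[i, 1]
    cy <- cand[, 2] - pts[i, 2]
    for (j in which(jmin >= -eps | jmax <= eps)) {
      if (dx[j] == 0 && dy[j] == 0) next
      crc <- dx[j] * cy - dy[j] * cx
      if (jmin[j] >= -eps) outside <- outside | crc < -eps
      if (jmax[j] <= eps) outside <- outside | crc > eps
    }
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  inside <- cand[!outside, , drop = FALSE]
  out[cbind(inside[, 2], inside[, 1])] <- TRUE
  out
}

# Brute-force split-line SSE: scan candidate breakpoints and fit the
# continuous basis with lm.fit, independently of the package's profiling
# loop and refinement.
brute_force_min_sse <- function(days, values, n_candidates = 10000) {
  t <- days[order(days)]
  y <- values[order(days)]
  n <- length(t)
  xs <- seq(t[2], t[n - 1], length.out = n_candidates)
  best <- Inf
  for (X in xs) {
    f <- stats::lm.fit(cbind(1, t - X, pmax(t - X, 0)), y)
    s <- sum(f$residuals^2)
    if (s < best) best <- s
  }
  best
}

# A small noiseless scene with explicit plant/cage geometry.
explicit_scene <- function(plant_px, cage_px = NA, w = 100L, h = 100L,
                           noise_sd = 0, seed = 1L) {
  scene_spec(width = w, height = h, plant_shape = plant_px,
             cage_shape = cage_px, noise_sd = noise_sd, seed = seed)
}

# n distinct pixels in an h x w grid, uniformly without replacement.
random_pixels <- function(n, h, w) {
  idx <- sample(h * w, n)
  cbind(((idx - 1) %% h) + 1, ((idx - 1) %/% h) + 1)
}

reduced_cohort_config <- function(out_dir, seed = 7L) {
  cfg <- default_config()
  cfg$cohort$genotypes <- c("Alma", "Dunn", "Whero", "Cressy Blue",
                            "Derrimut", "Dunwa", "Parafield", "Bohatyr")
  cfg$cohort$n_reps <- 4L
  cfg$cohort$day_start <- 17L
  cfg$cohort$day_end <- 26L
  cfg$scene$width <- 200L
  cfg$scene$height <- 200L
  cfg$scene$pixels_per_kpix <- 30
  cfg$ndvi$reference_day <- 25L
  cfg$paths$out_dir <- out_dir
  cfg$seed <- seed
  cfg
}
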