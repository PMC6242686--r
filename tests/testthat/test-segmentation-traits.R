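# Colour segmentation, component denoising, hull/height traits and the
# combined trait record, checked against scene ground truth and
# brute-force geometric oracles.

test_that("colour segmentation recovers the painted plant exactly", {
  set.seed(201)
  plant <- random_pixels(500, 100, 100)
  sc <- make_scene(explicit_scene(plant))
  expect_equal(sum(segment_plant(sc$images$top)), 500)

  # blue cage occluding 10 plant pixels removes them from the plant mask
  free <- which(!mask_from_pixels(plant, 100, 100), arr.ind = TRUE)
  cage <- rbind(plant[1:10, ], free[1:30, ])
  sc2 <- make_scene(explicit_scene(plant, cage))
  expect_equal(sum(segment_plant(sc2$images$top)), 490)
  expect_identical(segment_plant(sc2$images$top), sc2$masks$top)
})

test_that("segmentation stays within 2% of ground truth under image noise", {
  for (seed in 1:20) {
    sc <- make_scene(scene_spec(width = 100, height = 100, target_px = 800,
                                noise_sd = 5, seed = seed))
    got <- sum(segment_plant(sc$images$top))
    expect_lte(abs(got - sc$truth$plant_px[["top"]]),
               0.02 * sc$truth$plant_px[["top"]])
  }
})

test_that("segmentation is invariant to separable background changes", {
  set.seed(202)
  plant <- random_pixels(400, 80, 80)
  counts <- vapply(list(c(245, 245, 245), c(10, 10, 10), c(200, 40, 40)),
                   function(bg) {
                     sc <- make_scene(scene_spec(width = 80, height = 80,
                                                 plant_shape = plant,
                                                 cage_shape = NA,
                                                 background_colour = bg))
                     sum(segment_plant(sc$images$top))
                   }, numeric(1))
  expect_true(all(counts == 400))
})

test_that("denoising removes only components below the size threshold", {
  m <- matrix(FALSE, 60, 120)
  m[10:34, 10:29] <- TRUE                       # one 500-px block
  expect_identical(denoise_mask(m, 50), m)

  speck <- m
  set.seed(203)
  for (i in 1:12) {
    r <- 36 + 2 * i
    speck[r, sample(3, 1) + 9 * i] <- TRUE      # isolated specks, size 1
  }
  expect_equal(sum(denoise_mask(speck, 50)), 500)

  # component sizes 49 / 50 / 51: only the 50 and 51 survive
  sizes <- matrix(FALSE, 20, 200)
  sizes[2, 1:49] <- TRUE
  sizes[8, 1:50] <- TRUE
  sizes[14, 1:51] <- TRUE
  expect_equal(sum(denoise_mask(sizes, 50)), 101)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE      # diagonal chain
  lab <- label_components(m)
  expect_equal(max(lab), 1)
  m[5, 5] <- TRUE
  expect_equal(max(label_components(m)), 2)
})

test_that("hull area follows the pixel-square convention", {
  blk <- mask_from_pixels(cbind(rep(6:15, each = 10), rep(6:15, 10)), 20, 20)
  expect_equal(convex_hull_area(blk), 0.100)
  corners <- mask_from_pixels(cbind(c(6, 6, 15, 15), c(6, 15, 6, 15)), 20, 20)
  expect_equal(convex_hull_area(corners), 0.100)
  single <- mask_from_pixels(cbind(3, 3), 5, 5)
  expect_equal(convex_hull_area(single), 0.001)
  empty <- matrix(FALSE, 5, 5)
  expect_error(convex_hull_area(empty), "no plant object")
})

test_that("hull rasterization agrees with the brute-force oracle", {
  set.seed(204)
  for (i in 1:8) {
    n <- sample(3:60, 1)
    m <- mask_from_pixels(random_pixels(n, 24, 24), 24, 24)
    expect_equal(1000 * convex_hull_area(m), sum(brute_hull_fill(m)),
                 info = paste("case", i))
  }
  # collinear masks: hull degenerates to the covered segment
  diag3 <- mask_from_pixels(cbind(c(2, 4, 6), c(2, 4, 6)), 8, 8)
  expect_equal(1000 * convex_hull_area(diag3), sum(brute_hull_fill(diag3)))
})

test_that("plant height is the inclusive row extent", {
  m <- matrix(FALSE, 100, 10)
  m[10:50, 4] <- TRUE
  expect_equal(plant_height(m), 41)
  expect_equal(plant_height(mask_from_pixels(cbind(7, 3), 10, 10)), 1)
  blobs <- matrix(FALSE, 100, 10)
  blobs[5:9, 2] <- TRUE
  blobs[90:99, 8] <- TRUE
  expect_equal(plant_height(blobs), 95)
  expect_error(plant_height(matrix(FALSE, 3, 3)), "no plant object")
})

test_that("trait records combine the four views per the trait definitions", {
  set.seed(205)
  mk_view <- function(n) {
    sc <- make_scene(explicit_scene(random_pixels(n, 100, 100)))
    sc$images$top
  }
  set <- multi_view_set(mk_view(500),
                        list(mk_view(400), mk_view(420), mk_view(380)),
                        plant_id = "p1", genotype = "g1", das = 27)
  rec <- extract_traits(set, min_size = 1)
  expect_equal(rec$eb_kpix, 1.700)
  expect_equal(rec$tva_kpix, 0.500)
  expect_equal(rec$flags, "")
  expect_lte(rec$tvcom, 1)
  expect_gte(rec$tvch_kpix, rec$tva_kpix)

  # a solid convex blob has compactness exactly 1
  blk <- cbind(rep(30:49, each = 20), rep(30:49, 20))
  sc <- make_scene(explicit_scene(blk))
  set2 <- multi_view_set(sc$images$top, list(sc$images$top, sc$images$top,
                                             sc$images$top), das = 27)
  expect_equal(extract_traits(set2)$tvcom, 1.0)

  # plus-sign of 5 pixels: rasterized hull covers the 3x3 cross box
  plus <- cbind(c(40, 41, 41, 41, 42), c(41, 40, 41, 42, 41))
  scp <- make_scene(explicit_scene(plus))
  setp <- multi_view_set(scp$images$top, list(sc$images$top, sc$images$top,
                                              sc$images$top), das = 27)
  recp <- extract_traits(setp, min_size = 1)
  expect_equal(recp$tvcom, 5 / 9)
  expect_equal(1000 * recp$tvch_kpix, sum(brute_hull_fill(scp$masks$top)))
})

test_that("noiseless traits equal the scene ground truth exactly", {
  sc <- make_scene(scene_spec(width = 150, height = 150,
                              target_px = c(900, 700, 650, 720), seed = 31))
  set <- multi_view_set(sc$images$top, sc$images[c("side0", "side120",
                                                   "side240")], das = 20)
  rec <- extract_traits(set)
  expect_equal(rec$eb_kpix, sum(sc$truth$plant_px) / 1000)
  expect_equal(rec$tva_kpix, sc$truth$plant_px[["top"]] / 1000)
  expect_equal(rec$tvch_kpix, sc$truth$hull_px / 1000)
  expect_equal(rec$eh_px, max(sc$truth$height_px))
})

test_that("an empty view yields a flagged record, not an exception", {
  sc <- make_scene(scene_spec(width = 100, height = 100, target_px = 600,
                              seed = 32))
  blank <- array(245, dim = c(100, 100, 3))
  set <- multi_view_set(sc$images$top,
                        list(blank, sc$images$side120, sc$images$side240),
                        das = 27)
  rec <- extract_traits(set)
  expect_match(rec$flags, "side0")
  expect_true(is.na(rec$eb_kpix))
  expect_false(is.na(rec$tva_kpix))    # top view still measurable
})
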