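# Synthetic scene, growth and reflectance generators: painting rules,
# determinism, the two-phase model, and the biomass-NDVI link.

test_that("scene painting matches the requested geometry exactly", {
  set.seed(101)
  plant <- random_pixels(500, 100, 100)
  sc <- make_scene(explicit_scene(plant))
  expect_equal(unname(sc$truth$plant_px["top"]), 500)
  expect_true(all(sc$truth$plant_px == 500))
  # painted colours are exact without noise
  top <- sc$images$top
  expect_equal(sum(top[, , 2] == 180), 500)

  # cage disjoint from the plant leaves the plant count unchanged
  free <- which(!mask_from_pixels(plant, 100, 100), arr.ind = TRUE)
  cage <- free[seq_len(30), ]
  sc2 <- make_scene(explicit_scene(plant, cage))
  expect_equal(unname(sc2$truth$plant_px["top"]), 500)

  # cage occludes the plant where they overlap
  cage3 <- rbind(plant[1:10, ], free[31:60, ])
  sc3 <- make_scene(explicit_scene(plant, cage3))
  expect_equal(unname(sc3$truth$plant_px["top"]), 490)
  expect_identical(sum(sc3$masks$top), 490L)
})

test_that("scenes are deterministic given the seed and truth ignores noise", {
  spec <- scene_spec(width = 80, height = 80, target_px = 600,
                     noise_sd = 8, seed = 11)
  a <- make_scene(spec)
  b <- make_scene(spec)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
  quiet <- make_scene(scene_spec(width = 80, height = 80, target_px = 600,
                                 noise_sd = 0, seed = 11))
  expect_identical(a$truth, quiet$truth)
  expect_true(a$truth$hull_px >= a$truth$plant_px[["top"]])
})

test_that("colour-separation and geometry invariants are enforced", {
  expect_error(scene_spec(noise_sd = 120), "2\\*noise_sd")
  expect_error(scene_spec(plant_shape = cbind(500, 5), width = 100,
                          height = 100), "bounds")
  expect_error(scene_spec(plant_shape = matrix(numeric(0), 0, 2)),
               "non-empty")
})

test_that("noise-free growth reproduces the two-phase model exactly", {
  # lag slope 9.18 from breakpoint (20.40, 104.50): m(20) = 100.828
  p <- growth_params(X = 20.40, Y = 104.50, s1 = 9.18, s2 = 42.16,
                     cv = 0, n_reps = 1)
  s <- simulate_growth(p)
  expect_equal(s$eb_kpix[s$das == 20], 104.50 + 9.18 * (20 - 20.40))
  expect_equal(s$eb_kpix[s$das == 20], 100.828)
  m <- broken_stick_value(s$das, 20.40, 104.50, 9.18, 42.16)
  expect_equal(s$eb_kpix, m, tolerance = 1e-12)

  # breakpoint on the grid returns Y exactly
  p2 <- growth_params(X = 25, Y = 80, s1 = 5, s2 = 20, cv = 0, n_reps = 1)
  s2 <- simulate_growth(p2)
  expect_identical(s2$eb_kpix[s2$das == 25], 80)

  # s2 > s1 makes the cv = 0 series convex across the breakpoint
  v <- s$eb_kpix
  i <- which(s$das == 20)
  expect_gte(v[i + 1] - 2 * v[i] + v[i - 1], 0)
})

test_that("replicate noise is unbiased multiplicative with the stated cv", {
  p <- growth_params(X = 20.40, Y = 104.50, s1 = 9.18, s2 = 42.16,
                     cv = 0.05, n_reps = 10000, seed = 99)
  s <- simulate_growth(p)
  for (d in c(12, 20, 30, 39)) {
    v <- s$eb_kpix[s$das == d]
    m <- broken_stick_value(d, 20.40, 104.50, 9.18, 42.16)
    se <- m * 0.05 / sqrt(length(v))
    expect_lt(abs(mean(v) - m), 5 * se)
  }
  # small n with a fixed seed stays reproducible
  s8a <- simulate_growth(growth_params(20.4, 104.5, 9.18, 42.16, cv = 0.05,
                                       n_reps = 8, seed = 5))
  s8b <- simulate_growth(growth_params(20.4, 104.5, 9.18, 42.16, cv = 0.05,
                                       n_reps = 8, seed = 5))
  expect_identical(s8a, s8b)
})

test_that("invalid growth parameter sets are rejected", {
  expect_error(growth_params(X = 5, Y = 100, s1 = 5, s2 = 20,
                             day_start = 11, day_end = 39), "breakpoint")
  expect_error(growth_params(X = 20, Y = 100, s1 = -1, s2 = 20), "positive")
  # a growth phase collapsing below zero is rejected ...
  expect_error(growth_params(X = 25, Y = 50, s1 = 4, s2 = -10), "breakpoint on")
  # ... but a lag line extrapolating below zero at the window start is
  # tolerated and truncated at the simulation floor
  p <- growth_params(X = 25, Y = 50, s1 = 10, s2 = 20, cv = 0, n_reps = 1)
  s <- simulate_growth(p)
  expect_true(all(s$eb_kpix > 0))
  expect_equal(s$eb_kpix[s$das == 11], 1e-6)
})

test_that("reflectance records reproduce the linked NDVI", {
  # fixed band sum: target NDVI 0.5 at sum 0.8 gives (R760, R670) = (0.6, 0.2)
  r <- simulate_field_ndvi(c(A = 0.0, B = 1.0),
                           link = list(intercept = 0.5, slope = 0),
                           noise_sd = 0, total_reflectance = 0.8)
  expect_equal(r$R760, c(0.6, 0.6))
  expect_equal(r$R670, c(0.2, 0.2))
  expect_equal(ndvi(r$R670, r$R760), c(0.5, 0.5))

  eb <- seq(100, 400, length.out = 20)
  names(eb) <- paste0("g", 1:20)
  r0 <- simulate_field_ndvi(eb, noise_sd = 0)
  expect_equal(cor(eb, ndvi(r0$R670, r0$R760), method = "spearman"), 1)

  set.seed(102)
  eb44 <- seq(90, 380, length.out = 44) + stats::runif(44, 0, 5)
  names(eb44) <- paste0("g", 1:44)
  rn <- simulate_field_ndvi(eb44, noise_sd = 0.02, seed = 21)
  expect_gt(cor(eb44, ndvi(rn$R670, rn$R760)), 0.9)

  expect_error(simulate_field_ndvi(c(A = 1, B = 2),
                                   link = list(intercept = 0, slope = 1)),
               "NDVI")
})
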