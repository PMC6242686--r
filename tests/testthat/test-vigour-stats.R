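# Physiological indices, correlation and ANOVA machinery, and genotype
# ranking, checked against long-hand formula oracles.

test_that("water-use efficiency is the biomass/water ratio", {
  expect_equal(ewue(100, 2), 50)
  expect_equal(ewue(0, 2), 0)
  # inverting the published Alma-scale ratio recovers the eWUE value
  expect_equal(ewue(370.40, 370.40 / 189.34), 189.34)
  expect_error(ewue(100, 0), "positive")
})

test_that("NDVI follows the two-band normalized difference", {
  expect_equal(ndvi(0.4, 0.4), 0)
  expect_equal(ndvi(0, 0.3), 1)
  expect_equal(ndvi(0.2, 0.6), 0.5)
  set.seed(401)
  a <- runif(50); b <- runif(50, 0.01, 1)
  v <- ndvi(a, b)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(ndvi(b, a), -v)          # antisymmetric under band swap
  expect_error(ndvi(0, 0), "positive")
  expect_error(ndvi(1.2, 0.5), "fraction")
})

test_that("correlation matrix matches the long-hand product-moment formula", {
  x <- c(2.1, 3.4, 1.8, 5.2, 4.4, 6.1, 2.9, 3.3, 5.8, 4.0)
  y <- c(1.0, 2.2, 1.1, 4.8, 3.9, 5.5, 2.0, 2.4, 5.1, 3.2)
  z <- c(9.9, 8.1, 9.5, 4.4, 5.0, 3.2, 8.0, 7.7, 3.9, 6.0)
  pm <- pearson_matrix(data.frame(x, y, z))
  long_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pm$r["x", "y"], long_hand)
  tt <- long_hand * sqrt(8 / (1 - long_hand^2))
  expect_equal(pm$p["x", "y"], 2 * pt(-abs(tt), 8))
  expect_equal(pm$stars["x", "y"], "***")

  expect_equal(pearson_matrix(data.frame(a = x, b = 2 * x + 1))$r["a", "b"], 1)
  expect_equal(pearson_matrix(data.frame(a = x, b = -x))$r["a", "b"], -1)

  # symmetry, unit diagonal, invariance under positive affine transforms
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  pm2 <- pearson_matrix(data.frame(x = 10 * x + 3, y, z))
  expect_equal(pm2$r, pm$r, tolerance = 1e-12)

  expect_warning(pearson_matrix(data.frame(x, const = rep(1, 10))),
                 "zero-variance")
})

test_that("one-way ANOVA matches hand arithmetic and the t-test identity", {
  a <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(a$F, 13.5)
  expect_equal(a$df_between, 1)
  expect_equal(a$df_error, 4)
  expect_equal(a$sed, sqrt(2 * 1 / 3))
  expect_equal(a$lsd, qt(0.975, 4) * sqrt(2 / 3))

  # F on two groups equals the squared pooled two-sample t statistic
  set.seed(402)
  g1 <- rnorm(8, 10); g2 <- rnorm(8, 11)
  a2 <- one_way_anova(c(g1, g2), rep(c("A", "B"), each = 8))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2)
  expect_equal(a2$p, tt$p.value)

  # null case: equal means with noise gives a large p
  set.seed(403)
  vals <- rnorm(40, 5)
  a3 <- one_way_anova(vals, rep(letters[1:4], each = 10))
  expect_gt(a3$p, 0.05)

  # degenerate within-group variance
  expect_warning(a4 <- one_way_anova(c(1, 1, 1, 2, 2, 2),
                                     rep(c("A", "B"), each = 3)),
                 "zero within-group")
  expect_identical(a4$F, Inf)
  expect_identical(a4$p, 0)
  expect_warning(one_way_anova(c(2, 3, 5, 6, 7), c("A", "A", "B", "B", "B")),
                 "harmonic")
})

test_that("group means separated by more than the LSD are t-significant", {
  set.seed(404)
  vals <- rnorm(32, rep(c(10, 10.5, 11.5, 13), each = 8), 1)
  grp <- rep(c("a", "b", "c", "d"), each = 8)
  a <- one_way_anova(vals, grp)
  means <- tapply(vals, grp, mean)
  for (i in 1:3) for (j in (i + 1):4) {
    diff <- abs(means[i] - means[j])
    tstat <- diff / a$sed
    signif <- 2 * pt(-tstat, a$df_error) < 0.05
    expect_identical(unname(diff > a$lsd), unname(signif))
  }
})

test_that("genotype ranking is order-preserving and deterministic", {
  set.seed(405)
  mk <- function(g, eb) data.frame(plant_id = paste0(g, 1:6), genotype = g,
                                   eb_kpix = eb, tva_kpix = eb / 4)
  traits <- rbind(mk("A", rnorm(6, 300, 5)), mk("B", rnorm(6, 150, 5)),
                  mk("C", rnorm(6, 220, 5)))
  vt <- rank_genotypes(traits)
  expect_equal(vt$table$genotype, c("A", "C", "B"))
  expect_equal(vt$table$rank, 1:3)
  expect_identical(vt$table, rank_genotypes(traits)$table)

  # measured biomass takes precedence over estimated biomass as the key
  traits$mb <- rep(c(10, 30, 20), each = 6)
  expect_equal(rank_genotypes(traits)$table$genotype, c("B", "C", "A"))

  # water log adds eWUE; reflectance adds NDVI correlations
  water <- data.frame(plant_id = traits$plant_id,
                      total_water_kg = rep(2, 18))
  eb_mean <- tapply(traits$eb_kpix, traits$genotype, mean)
  refl <- simulate_field_ndvi(eb_mean, noise_sd = 0, seed = 1)
  vt2 <- rank_genotypes(traits, water = water, reflectance = refl)
  expect_true("ewue" %in% names(vt2$table))
  expect_equal(vt2$table$ewue, vt2$table$eb_kpix / 2, tolerance = 0.05)
  expect_equal(vt2$ndvi_cor$r[vt2$ndvi_cor$trait == "eb_kpix"], 1,
               tolerance = 1e-3)
})

test_that("outlier screening happens before genotype means", {
  traits <- data.frame(plant_id = paste0("p", 1:12),
                       genotype = rep(c("A", "B"), each = 6),
                       eb_kpix = c(100, 101, 99, 100, 101, 500,
                                   200, 201, 199, 200, 201, 200))
  vt <- rank_genotypes(traits)
  a_mean <- vt$table$eb_kpix[vt$table$genotype == "A"]
  expect_lt(a_mean, 110)     # the 500 outlier is screened out
})
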