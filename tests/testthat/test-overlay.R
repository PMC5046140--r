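test_that("published contributions normalize to the published weights", {
  ct <- masson_contributions()
  w <- normalize_weights(ct)
  expect_equal(w$weight, c(0.034, 0.139, 0.258, 0.439, 0.130), tolerance = 1e-12)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  one <- normalize_weights(tibble::tibble(variable = "a", contribution = 42))
  expect_equal(one$weight, 1)
  eq <- normalize_weights(tibble::tibble(variable = letters[1:5],
                                         contribution = rep(3, 5)))
  expect_equal(eq$weight, rep(0.2, 5))
})

test_that("weighted overlay is the cellwise convex combination", {
  w <- normalize_weights(tibble::tibble(variable = c("a", "b"),
                                        contribution = c(30, 70)))
  ones <- list(a = eco_raster(matrix(1, 4, 4)), b = eco_raster(matrix(1, 4, 4)))
  expect_true(all(weighted_overlay(ones, w)$values == 1))
  halves <- list(a = eco_raster(matrix(0.5, 4, 4)), b = eco_raster(matrix(0.5, 4, 4)))
  expect_true(all(weighted_overlay(halves, w)$values == 0.5))

  set.seed(60)
  rnd <- list(a = eco_raster(matrix(stats::runif(16), 4, 4)),
              b = eco_raster(matrix(stats::runif(16), 4, 4)))
  out <- weighted_overlay(rnd, w)
  expect_equal(out$values[2, 3],
               0.3 * rnd$a$values[2, 3] + 0.7 * rnd$b$values[2, 3],
               tolerance = 1e-12)
  # bounded by the inputs, nodata propagates
  expect_true(all(out$values <= pmax(rnd$a$values, rnd$b$values) + 1e-12))
  rnd$a$values[1, 1] <- NA
  expect_true(is.na(weighted_overlay(rnd, w)$values[1, 1]))
  expect_error(weighted_overlay(rnd, normalize_weights(
    tibble::tibble(variable = c("a", "zz"), contribution = c(1, 1)))),
    "do not match")
})

test_that("land-cover masking keeps exactly the allowed classes", {
  comp <- eco_raster(matrix(stats::runif(64), 8, 8))
  lc <- eco_raster(matrix(rep(c(1, 2), 32), 8, 8))  # checkerboard by column pairs
  expect_identical(mask_landcover(comp, lc, c(1, 2)), comp)
  none <- mask_landcover(comp, lc, integer(0))
  expect_true(all(is.na(none$values)))
  half <- mask_landcover(comp, lc, 1)
  expect_equal(sum(!is.na(half$values)), 32)
})

test_that("growth and quality maps combine by min, product or mean", {
  g <- eco_raster(matrix(c(0.2, 0.8), 2, 2))
  q <- eco_raster(matrix(c(0.5, 0.5), 2, 2))
  expect_equal(combine_suitability(g, q)$values[, 1], c(0.2, 0.5))
  expect_equal(combine_suitability(g, q, "product")$values[, 1], c(0.1, 0.4))
  expect_equal(combine_suitability(g, q, "mean")$values[, 1], c(0.35, 0.65))
})

test_that("classification counts, areas and percentages are consistent", {
  comp <- eco_raster(matrix(c(0.9, 0.5, 0.1), 1, 3), cellsize = 2)
  cl <- classify_suitability(comp, t_high = 0.7, t_low = 0.3)
  expect_equal(cl$stats$n_cells, c(1L, 1L, 1L))
  expect_equal(cl$stats$area, c(4, 4, 4))
  expect_equal(cl$stats$percent, rep(100 / 3, 3), tolerance = 1e-9)

  all_high <- classify_suitability(eco_raster(matrix(1, 3, 3)), 0.7, 0.4)
  expect_equal(all_high$stats$percent, c(100, 0, 0))

  expect_error(classify_suitability(comp, t_high = 0.3, t_low = 0.7),
               "config error")
})

test_that("class percentages always partition 100, with or without nodata", {
  set.seed(61)
  for (i in 1:20) {
    v <- matrix(stats::runif(100), 10, 10)
    v[sample(100, sample(0:50, 1))] <- NA
    if (all(is.na(v))) next
    cl <- classify_suitability(eco_raster(v), t_high = stats::runif(1, 0.5, 0.9),
                               t_low = stats::runif(1, 0.1, 0.4))
    expect_equal(sum(cl$stats$percent), 100, tolerance = 0.01)
    expect_equal(sum(cl$stats$n_cells), sum(!is.na(v)))
  }
})

test_that("masking never increases any class's cell count", {
  set.seed(62)
  for (i in 1:10) {
    comp <- eco_raster(matrix(stats::runif(144), 12, 12))
    lc <- eco_raster(matrix(sample(1:4, 144, TRUE), 12, 12))
    before <- classify_suitability(comp, 0.7, 0.4)$stats$n_cells
    masked <- mask_landcover(comp, lc, c(1, 3))
    if (all(is.na(masked$values))) next
    after <- classify_suitability(masked, 0.7, 0.4)$stats$n_cells
    expect_true(all(after <= before))
  }
})

test_that("the area report reproduces the published habitat shares", {
  rep <- area_stats_report(masson_area_table())
  suit <- rep[rep$label == "suitable total", ]
  expect_equal(suit$percent, 7.41, tolerance = 1e-9)       # 1.69 + 5.72
  expect_equal(rep$percent[rep$label == "unsuitable"], 92.59)
  expect_equal(suit$area, 14769.86 + 49966.0986, tolerance = 1e-9)

  # percent recomputed from raw areas agrees with the printed rounding
  areas_only <- masson_area_table()[, c("class", "label", "area")]
  rep2 <- area_stats_report(areas_only)
  expect_equal(rep2$percent[rep2$label == "suitable total"], 7.41,
               tolerance = 0.005)

  one_class <- tibble::tibble(class = 1:3,
                              label = c("highly suitable", "marginally suitable",
                                        "unsuitable"),
                              area = c(50, 0, 0))
  rep3 <- area_stats_report(one_class)
  expect_equal(rep3$percent[1:3], c(100, 0, 0))
})
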