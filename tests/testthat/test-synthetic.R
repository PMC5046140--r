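test_that("factor generation is deterministic and honours mean/sd", {
  cfg <- landscape_config(n_rows = 30, n_cols = 30, seed = 11)
  f1 <- generate_factor_rasters(cfg)
  f2 <- generate_factor_rasters(cfg)
  expect_identical(f1, f2)

  # sd = 0 collapses to a constant field at the mean
  cfg0 <- landscape_config(
    n_rows = 10, n_cols = 10, seed = 3,
    factor_specs = tibble::tibble(name = "flat", mean = 5, sd = 0,
                                  autocorrelation = 4))
  expect_true(all(generate_factor_rasters(cfg0)$flat$values == 5))

  # autocorrelation 0 gives i.i.d. cells with the stated sd (10^4 cells)
  cfg_iid <- landscape_config(
    n_rows = 100, n_cols = 100, seed = 5,
    factor_specs = tibble::tibble(name = "iid", mean = 2, sd = 3,
                                  autocorrelation = 0))
  v <- generate_factor_rasters(cfg_iid)$iid$values
  expect_lt(abs(stats::sd(v) - 3) / 3, 0.1)
  expect_lt(abs(mean(v) - 2), 0.15)
})

test_that("config validation rejects bad grids and proportions", {
  expect_error(landscape_config(n_rows = 0), "config error")
  expect_error(landscape_config(
    landcover_classes = tibble::tibble(class_id = 1, label = "a",
                                       proportion = 0.5)),
    "proportions")
})

test_that("true suitability is the weighted membership sum", {
  truth <- ground_truth()
  # all factors pinned inside their plateaus -> suitability exactly 1
  mp <- truth$membership
  factors <- lapply(seq_len(nrow(mp)), function(i)
    eco_raster(matrix((mp$b[i] + mp$c[i]) / 2, 5, 5)))
  names(factors) <- mp$factor
  suit <- simulate_true_suitability(factors, truth)
  expect_equal(suit$values, matrix(1, 5, 5))

  # weight 1 on one factor -> suitability equals that factor's membership
  w1 <- stats::setNames(c(1, 0, 0, 0, 0), mp$factor)
  truth1 <- ground_truth(weights = w1)
  factors$precip_april <- eco_raster(matrix(seq(0, 150, length.out = 25), 5, 5))
  suit1 <- simulate_true_suitability(factors, truth1)
  p <- params_from_table(mp, "precip_april")
  expect_equal(suit1$values, kt_membership(factors$precip_april$values, p))

  # hand-computed single cell
  vals <- c(precip_april = 80, precip_june = 170, temp_feb = 3,
            temp_aug = 25, altitude = 1400)
  factors2 <- lapply(vals, function(v) eco_raster(matrix(v, 1, 1)))
  suit2 <- simulate_true_suitability(factors2, truth)
  by_hand <- sum(vapply(names(vals), function(nm)
    truth$weights[[nm]] * kt_membership(vals[[nm]], params_from_table(mp, nm)),
    0))
  expect_equal(suit2$values[1, 1], by_hand, tolerance = 1e-12)
})

test_that("presence sampling follows the suitability surface", {
  # a single nonzero cell receives every point
  s <- eco_raster(matrix(0, 4, 4)); s$values[2, 3] <- 0.8
  pts <- sample_presence_points(s, 25, seed = 9)
  expect_true(all(pts$x == 2.5) && all(pts$y == 2.5))

  # uniform suitability -> uniform cell frequencies (chi-squared, alpha 0.01)
  u <- eco_raster(matrix(1, 5, 5))
  pts <- sample_presence_points(u, 1e4, seed = 21)
  counts <- table(factor(paste(pts$x, pts$y), levels = paste(
    as_tibble(u)$x, as_tibble(u)$y)))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)

  expect_identical(sample_presence_points(u, 50, seed = 4),
                   sample_presence_points(u, 50, seed = 4))
  expect_error(sample_presence_points(eco_raster(matrix(0, 3, 3)), 5),
               "sampling error")
})

test_that("simulated contents track the true composite suitability", {
  land <- small_landscape(seed = 2, n = 40, n_points = 200)
  truth0 <- ground_truth(noise_sd = 0)
  pts0 <- simulate_contents(land$points[c("point_id", "x", "y")],
                            land$factors, truth0, seed = 5)
  # noiseless: every content is an exact positive multiple of the truth
  expect_equal(pts0$shikimic, 40 * pts0$true_suitability, tolerance = 1e-12)
  expect_equal(pts0$lignans, 5 * pts0$true_suitability, tolerance = 1e-12)

  # at the study noise level the contents stay strongly correlated with truth
  expect_gt(stats::cor(land$points$flavonoids, land$points$true_suitability), 0.9)

  again <- simulate_contents(land$points[c("point_id", "x", "y")],
                             land$factors, land$truth,
                             seed = split_seed(2, 2002L))
  expect_identical(again$procyanidins, land$points$procyanidins)
})

test_that("land cover respects class proportions and determinism", {
  cfg <- landscape_config(n_rows = 60, n_cols = 60, seed = 8)
  lc <- generate_landcover(cfg)
  expect_identical(lc, generate_landcover(cfg))
  shares <- as.vector(table(lc$values)) / 3600
  expect_equal(shares, cfg$landcover_classes$proportion, tolerance = 0.05)
})
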