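# Published February-temperature calibration: a=-42.4, b=5, c=8, d=33.6, K=13.
feb <- membership_params(a = -42.4, b = 5, c = 8, d = 33.6, K = 13)

test_that("K-t evaluation matches hand-worked values of the piecewise form", {
  expect_equal(kt_membership(6.5, feb), 1)          # inside the plateau
  expect_equal(kt_membership(33.6, feb), 0)         # at the support edge d
  # falling-limb midpoint: ((33.6-20.8)/(33.6-8))^13 = 0.5^13
  expect_equal(kt_membership(20.8, feb), 0.5^13, tolerance = 1e-12)

  apr <- membership_params(a = -63.9, b = 98.8, c = 113.8, d = 191.3, K = 1.62)
  expect_equal(kt_membership(17.45, apr), 0.5^1.62, tolerance = 1e-12)
})

test_that("membership is bounded, unimodal, and NA-propagating", {
  x <- seq(-100, 100, length.out = 2001)
  mu <- kt_membership(x, feb)
  expect_true(all(mu >= 0 & mu <= 1))
  below <- x <= feb$b
  expect_true(all(diff(mu[below]) >= -1e-12))
  above <- x >= feb$c
  expect_true(all(diff(mu[above]) <= 1e-12))
  expect_true(is.na(kt_membership(NA, feb)))
})

test_that("thresholds invert the membership limbs in closed form", {
  expect_equal(unname(membership_thresholds(feb, 1)), c(feb$b, feb$c))
  thr <- membership_thresholds(feb, 0.5^13)
  expect_equal(thr[["x_high"]], 20.8, tolerance = 1e-9)
  expect_equal(kt_membership(thr[["x_low"]], feb), 0.5^13, tolerance = 1e-9)
  # cutoff -> 0 approaches the support (a, d)
  thr0 <- membership_thresholds(feb, 1e-60)
  expect_equal(unname(thr0), c(feb$a, feb$d), tolerance = 1e-3)
  # mutual inversion across random cutoffs on both limbs
  for (cut in c(0.05, 0.2, 0.5, 0.9, 0.99)) {
    th <- membership_thresholds(feb, cut)
    expect_equal(kt_membership(th[["x_low"]], feb), cut, tolerance = 1e-9)
    expect_equal(kt_membership(th[["x_high"]], feb), cut, tolerance = 1e-9)
  }
})

test_that("parameter validation enforces ordering and positivity", {
  expect_error(membership_params(a = 5, b = 3, c = 8, d = 9), "a <= b")
  expect_error(membership_params(a = 1, b = 2, c = 3, d = 4, K = -1), "K")
  expect_warning(kt_membership(0.5, membership_params(a = 0, b = 0, c = 1, d = 2)),
                 "degenerate")
})

test_that("noiseless data reproduce their generating parameters", {
  p <- membership_params(a = 20, b = 40, c = 60, d = 90, K = 2)
  x <- seq(0, 110, length.out = 200)
  y <- kt_membership(x, p)
  fit <- fit_membership(x, y, bin = FALSE)
  span <- diff(range(x))
  expect_lt(abs(fit$params$b - p$b) / span, 0.01)
  expect_lt(abs(fit$params$c - p$c) / span, 0.01)
  # the optimum can be no worse than the truth
  expect_lte(fit$goodness, sum((kt_membership(x, p) - y)^2) + 1e-9)
})

test_that("noisy single-factor data recover the plateau within 5% of range", {
  p <- membership_params(a = 20, b = 40, c = 60, d = 90, K = 2)
  set.seed(100)
  errs <- replicate(20, {
    x <- stats::runif(200, 0, 110)
    y <- pmin(pmax(kt_membership(x, p) + stats::rnorm(200, 0, 0.05), 0), 1)
    fit <- suppressWarnings(fit_membership(x, y))
    c(abs(fit$params$b - p$b), abs(fit$params$c - p$c)) / 110
  })
  expect_lt(mean(errs), 0.05)
  expect_lt(max(errs), 0.05)
})

test_that("degenerate fits are caught and constant indicators handled", {
  expect_error(fit_membership(1:5, rep(0.5, 5)), "at least 8")
  expect_error(fit_membership(rep(2, 10), stats::runif(10)), "identical")
  expect_error(fit_membership(1:10, rep(2, 10)), "\\[0, 1\\]")
  # indicator constant 1: plateau must cover the observed factor range
  fit <- suppressWarnings(fit_membership(seq(0, 10, length.out = 20),
                                         rep(1, 20), bin = FALSE))
  expect_lte(fit$params$b, 0.5)
  expect_gte(fit$params$c, 9.5)
})

test_that("raster standardization applies the membership cellwise", {
  plateau <- eco_raster(matrix(6.5, 3, 3))
  expect_equal(standardize_raster(plateau, feb)$values, matrix(1, 3, 3))
  high <- eco_raster(matrix(40, 3, 3))
  expect_equal(standardize_raster(high, feb)$values, matrix(0, 3, 3))

  set.seed(33)
  r <- eco_raster(matrix(stats::runif(100, -50, 50), 10, 10))
  r$values[c(4, 40)] <- NA
  std <- standardize_raster(r, feb)
  idx <- sample(setdiff(1:100, c(4, 40)), 50)
  expect_equal(std$values[idx], kt_membership(r$values[idx], feb))
  expect_true(all(is.na(std$values[c(4, 40)])))
})

test_that("family selection prefers the generating family on clean data", {
  set.seed(44)
  x <- stats::runif(300, -10, 10)
  y <- stats::plogis((x - 1) / 2)
  best <- select_membership_family(x, y, bin = FALSE)
  cmp <- attr(best, "comparison")
  expect_s3_class(cmp, "tbl_df")
  expect_equal(cmp$penalized[cmp$family == best$family], min(cmp$penalized))
  expect_identical(best$family, "sigmoid_rise")
})

test_that("membership parameter tables round-trip through CSV", {
  tbl <- masson_membership_params()
  f <- withr::local_tempfile(fileext = ".csv")
  write_membership_params(tbl, f)
  back <- read_membership_params(f)
  expect_equal(back$a, tbl$a)
  expect_equal(back$K, tbl$K)
  p <- params_from_table(back, "temp_feb")
  expect_equal(kt_membership(20.8, p), 0.5^13, tolerance = 1e-12)
})

test_that("alternative families evaluate within [0, 1] and invert", {
  g <- membership_params("gaussian", alpha = 5, beta = 2)
  expect_equal(membership_value(5, g), 1)
  th <- membership_thresholds(g, 0.5)
  expect_equal(membership_value(th[["x_low"]], g), 0.5, tolerance = 1e-12)
  tr <- membership_params("trapezoidal", a = 0, b = 1, c = 2, d = 4)
  expect_equal(membership_value(0.5, tr), 0.5)
  expect_equal(membership_value(3, tr), 0.5)
  sf <- membership_params("sigmoid_fall", alpha = 0, beta = 1)
  expect_equal(membership_value(0, sf), 0.5)
  expect_true(all(diff(membership_value(seq(-5, 5, 0.5), sf)) < 0))
})
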