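# Small in-code fixtures shared across test files.

# A deterministic raster with a simple analytic field.
analytic_raster <- function(n = 10, f = function(x, y) x, cellsize = 1) {
  r <- eco_raster(matrix(0, n, n), xll = 0, yll = 0, cellsize = cellsize)
  tb <- as_tibble(r)
  r$values <- matrix(f(tb$x, tb$y), n, n)
  r
}

# A compact synthetic landscape for pipeline-level tests: fewer cells and
# points than the full study conditions, same structure.
small_landscape <- function(seed = 1L, n = 50L, n_points = 120L) {
  cfg <- landscape_config(n_rows = n, n_cols = n, seed = seed)
  truth <- ground_truth()
  factors <- generate_factor_rasters(cfg)
  suit <- simulate_true_suitability(factors, truth)
  pts <- sample_presence_points(suit, n_points, seed = split_seed(seed, 2001L))
  pts <- simulate_contents(pts, factors, truth, seed = split_seed(seed, 2002L))
  list(cfg = cfg, truth = truth, factors = factors, suit = suit, points = pts)
}

# Presence/background tables drawn from a known one-variable Gibbs model:
# background x on a regular grid, presence sampled with p ~ exp(lambda * x).
gibbs_fixture <- function(lambda = 2, n_background = 2000, n_presence = 2000,
                          seed = 1L) {
  x <- seq(0, 1, length.out = n_background)
  p <- exp(lambda * x); p <- p / sum(p)
  set.seed(seed)
  idx <- sample.int(n_background, n_presence, replace = TRUE, prob = p)
  list(presence = data.frame(x = x[idx]), background = data.frame(x = x))
}

expect_raster_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize),
               tolerance = tol)
}
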