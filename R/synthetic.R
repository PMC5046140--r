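#' Synthetic landscape configuration
#'
#' Describes the synthetic study system used to exercise and validate the
#' pipeline end to end: a common analysis grid, a set of spatially
#' autocorrelated continuous ecological-factor fields, and a categorical
#' land-cover layer. The defaults emulate the study conditions the package
#' was built around: a 100 x 100 grid, the five retained factors
#' (April/June precipitation, February/August mean temperature, altitude)
#' with means and spreads placed against the published K-t calibration
#' ([masson_membership_params()]), and a land-cover mosaic dominated by
#' coniferous forest with farmland, water and urban classes to mask out.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cellsize cell size in map units.
#' @param xll,yll lower-left corner.
#' @param factor_specs tibble with columns `name`, `mean`, `sd`,
#'   `autocorrelation` (Gaussian smoothing length in cells, >= 0).
#' @param landcover_classes tibble with columns `class_id`, `label`,
#'   `proportion` (proportions sum to 1).
#' @param seed integer master seed; every stochastic operation derives its
#'   stream from it through [split_seed()].
#' @return A `landscape_config` object (a list).
#' @export
landscape_config <- function(n_rows = 100, n_cols = 100, cellsize = 1,
                             xll = 0, yll = 0,
                             factor_specs = default_factor_specs(),
                             landcover_classes = default_landcover_classes(),
                             seed = 1L) {
  if (n_rows < 1 || n_cols < 1)
    stop("config error: grid dimensions must be positive", call. = FALSE)
  stopifnot(all(c("name", "mean", "sd", "autocorrelation") %in% names(factor_specs)),
            all(c("class_id", "label", "proportion") %in% names(landcover_classes)))
  if (any(factor_specs$autocorrelation < 0))
    stop("config error: autocorrelation length must be >= 0", call. = FALSE)
  if (abs(sum(landcover_classes$proportion) - 1) > 1e-9)
    stop("config error: land-cover proportions must sum to 1", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cellsize = cellsize, xll = xll, yll = yll,
                 factor_specs = factor_specs,
                 landcover_classes = landcover_classes,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_factor_specs <- function() {
  tibble::tibble(
    name = c("precip_april", "precip_june", "temp_feb", "temp_aug", "altitude"),
    mean = c(100, 170, 6, 24, 1000),
    sd = c(30, 60, 6, 4, 400),
    autocorrelation = c(8, 8, 8, 8, 8)
  )
}

#' @rdname landscape_config
#' @export
default_landcover_classes <- function() {
  tibble::tibble(
    class_id = 1:4,
    label = c("coniferous_forest", "farmland", "water", "urban"),
    proportion = c(0.6, 0.25, 0.1, 0.05)
  )
}

#' Ground truth for the synthetic system
#'
#' The known data-generating truth behind a synthetic landscape: the true
#' K-t membership parameters per factor, the true factor weights (summing
#' to 1), and the per-compound observation model for the four quality
#' compounds. All four compound contents are scaled versions of one
#' composite suitability (plus noise), so the equal-weight aggregative
#' indicator is a well-posed estimate of that composite.
#'
#' Defaults: the published K-t calibration as true memberships, the
#' published contributions normalized as true weights
#' (0.034, 0.139, 0.258, 0.439, 0.130), content scales in the order
#' shikimic acid, procyanidins, flavonoids, lignans, and a noise standard
#' deviation of 0.05 on the suitability scale.
#'
#' @param membership tibble of true membership parameters (layout of
#'   [masson_membership_params()]).
#' @param weights named vector of true factor weights (>= 0, sum 1).
#' @param content_scales named vector of per-compound multiplicative
#'   scales (content units per unit suitability).
#' @param noise_sd noise standard deviation on the suitability scale
#'   (applied per compound as `noise_sd * scale`), >= 0.
#' @return A `ground_truth` object (a list).
#' @export
ground_truth <- function(membership = masson_membership_params(),
                         weights = NULL,
                         content_scales = c(shikimic = 40, procyanidins = 8,
                                            flavonoids = 25, lignans = 5),
                         noise_sd = 0.05) {
  if (is.null(weights)) {
    ct <- masson_contributions()
    weights <- stats::setNames(ct$contribution / sum(ct$contribution), ct$variable)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(all(names(weights) %in% membership$factor))
  structure(list(membership = membership, weights = weights,
                 content_scales = content_scales, noise_sd = noise_sd),
            class = "ground_truth")
}

#' Derive a stream seed from the master seed
#'
#' All randomness in the synthetic module flows from one integer seed; each
#' operation draws from stream `k` via
#' `(seed * 10007 + k * 97) mod (2^31 - 1)`.
#'
#' @param seed master integer seed.
#' @param k stream index.
#' @return An integer seed.
#' @export
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 10007 + as.double(k) * 97) %% 2147483647)
}

# Gaussian random field: white noise smoothed by a separable Gaussian
# kernel, normalized so the marginal variance is preserved, then scaled to
# the requested mean/sd. Padding keeps the field stationary at the edges.
gaussian_random_field <- function(n_rows, n_cols, mean, sd, length_scale) {
  if (sd == 0) return(matrix(mean, n_rows, n_cols))
  if (length_scale <= 0)
    return(matrix(stats::rnorm(n_rows * n_cols, mean, sd), n_rows, n_cols))
  half <- max(1L, ceiling(3 * length_scale))
  k <- stats::dnorm(seq(-half, half), sd = length_scale)
  k <- k / sqrt(sum(k^2))          # preserves white-noise variance
  pr <- n_rows + 2L * half; pc <- n_cols + 2L * half
  z <- matrix(stats::rnorm(pr * pc), pr, pc)
  # separable convolution via banded smoothing matrices
  Sr <- matrix(0, n_rows, pr)
  for (i in seq_len(n_rows)) Sr[i, i:(i + 2L * half)] <- k
  Sc <- matrix(0, pc, n_cols)
  for (j in seq_len(n_cols)) Sc[j:(j + 2L * half), j] <- k
  sm <- Sr %*% z %*% Sc
  mean + sd * sm
}

#' Generate spatially autocorrelated factor rasters
#'
#' One continuous raster per factor spec: Gaussian white noise convolved
#' with a Gaussian kernel of the stated autocorrelation length (in cells),
#' variance-normalized and rescaled to the stated mean and standard
#' deviation. Deterministic given the config seed.
#'
#' @param config a [landscape_config()].
#' @return A named list of [eco_raster()] layers.
#' @export
generate_factor_rasters <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  specs <- config$factor_specs
  out <- purrr::imap(split(specs, seq_len(nrow(specs))), function(sp, i) {
    set.seed(split_seed(config$seed, as.integer(i)))
    vals <- gaussian_random_field(config$n_rows, config$n_cols,
                                  sp$mean, sp$sd, sp$autocorrelation)
    eco_raster(vals, xll = config$xll, yll = config$yll,
               cellsize = config$cellsize)
  })
  stats::setNames(out, specs$name)
}

#' Generate a categorical land-cover raster
#'
#' Thresholds one smoothed Gaussian field at the quantiles implied by the
#' class proportions, yielding contiguous patches whose areal shares match
#' the config proportions (up to cell quantization). Deterministic given
#' the config seed.
#'
#' @param config a [landscape_config()].
#' @return An [eco_raster()] of integer class ids.
#' @export
generate_landcover <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  cls <- config$landcover_classes
  set.seed(split_seed(config$seed, 1000L))
  z <- gaussian_random_field(config$n_rows, config$n_cols, 0, 1, 6)
  qs <- stats::quantile(z, probs = cumsum(cls$proportion), names = FALSE)
  ids <- matrix(cls$class_id[1], config$n_rows, config$n_cols)
  for (i in seq_len(nrow(cls) - 1L))
    ids[z > qs[i]] <- cls$class_id[i + 1L]
  eco_raster(ids, xll = config$xll, yll = config$yll, cellsize = config$cellsize)
}

#' True composite suitability of a synthetic landscape
#'
#' Cellwise weighted sum of the true K-t memberships of each factor,
#' `sum_i w_i * mu_i(factor_i)`; values lie in \[0, 1\]. This is the ground
#' truth the pipeline is asked to recover.
#'
#' @param factors named list of aligned factor rasters.
#' @param truth a [ground_truth()].
#' @return An [eco_raster()] of true suitability.
#' @export
simulate_true_suitability <- function(factors, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  w <- truth$weights
  if (!all(names(w) %in% names(factors)))
    stop("alignment error: factors must cover all weighted variables", call. = FALSE)
  tmpl <- factors[[names(w)[1]]]
  for (v in names(w))
    if (!same_grid(factors[[v]], tmpl))
      stop("alignment error: factor rasters are not on a common grid", call. = FALSE)
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  for (v in names(w)) {
    p <- params_from_table(truth$membership, v)
    acc <- acc + w[[v]] * membership_value(factors[[v]]$values, p)
  }
  eco_raster(acc, xll = tmpl$xll, yll = tmpl$yll, cellsize = tmpl$cellsize)
}

#' Sample presence points proportional to suitability
#'
#' Draws `n` sample sites with per-cell probability proportional to the
#' suitability value (nodata counts as 0), emulating field sampling
#' concentrated where the species thrives. Points are placed at cell
#' centers. Deterministic given the seed.
#'
#' @param suitability an [eco_raster()] with non-negative values.
#' @param n number of points (>= 1).
#' @param seed integer seed.
#' @return A tibble with columns `point_id`, `x`, `y`.
#' @export
sample_presence_points <- function(suitability, n, seed = 1L) {
  stopifnot(is_eco_raster(suitability), n >= 1)
  p <- as.vector(suitability$values)
  p[is.na(p) | p < 0] <- 0
  if (sum(p) <= 0)
    stop("sampling error: suitability is zero or nodata everywhere", call. = FALSE)
  set.seed(seed)
  nr <- nrow(suitability$values)
  idx <- sample.int(length(p), size = n, replace = TRUE, prob = p)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  xy <- rowcol_to_xy(suitability, row, col)
  tibble::tibble(point_id = sprintf("pt%04d", seq_len(n)), x = xy$x, y = xy$y)
}

#' Simulate compound contents at sample points
#'
#' Attaches the four quality-compound contents to each point: every
#' compound is its scale times the true composite suitability at the
#' point, plus Gaussian noise of standard deviation
#' `noise_sd * scale`, truncated at zero. An `altitude` column is filled
#' from the altitude factor when present. Deterministic given the seed.
#'
#' @param points tibble with `point_id`, `x`, `y`.
#' @param factors named list of aligned factor rasters.
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @return The points tibble with columns `altitude`, `shikimic`,
#'   `procyanidins`, `flavonoids`, `lignans` added, plus the hidden truth
#'   in column `true_suitability`.
#' @export
simulate_contents <- function(points, factors, truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  suit <- simulate_true_suitability(factors, truth)
  mu <- extract_at_points(suit, points)
  if (anyNA(mu))
    stop("points outside the factor extent", call. = FALSE)
  out <- points
  out$altitude <- if ("altitude" %in% names(factors))
    extract_at_points(factors[["altitude"]], points) else NA_real_
  set.seed(seed)
  for (cmp in names(truth$content_scales)) {
    sc <- truth$content_scales[[cmp]]
    out[[cmp]] <- pmax(0, sc * mu + stats::rnorm(length(mu), 0, truth$noise_sd * sc))
  }
  out$true_suitability <- mu
  out
}
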