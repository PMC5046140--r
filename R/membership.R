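#' Fuzzy membership parameters
#'
#' Constructs the parameter set of a fuzzy membership function used to
#' standardize an ecological factor onto a \[0, 1\] suitability scale. The
#' default family is the K-t (K-th parabolic, "ridge") distribution:
#' membership is 0 outside the support `(a, d)`, rises as
#' `((x - a)/(b - a))^K` on `(a, b)`, holds a plateau of 1 on `[b, c]`,
#' and falls as `((d - x)/(d - c))^K` on `(c, d)`. Negative `a` for a
#' physically non-negative factor (precipitation, altitude) simply means
#' the fitted rising limb extends below the observed range.
#'
#' Alternative families (used for family selection by curve fitting) are
#' parameterized by `alpha` (location) and `beta` (scale):
#' `trapezoidal` (linear limbs over `a,b,c,d`), `gaussian`
#' (`exp(-((x - alpha)/beta)^2)`), `sigmoid_rise`
#' (`1/(1 + exp(-(x - alpha)/beta))`) and `sigmoid_fall` (its mirror).
#'
#' @param family one of `"kt"`, `"trapezoidal"`, `"gaussian"`,
#'   `"sigmoid_rise"`, `"sigmoid_fall"`.
#' @param a,b,c,d breakpoints in factor units, `a <= b <= c <= d`
#'   (K-t and trapezoidal families).
#' @param K limb exponent, > 0 (K-t family).
#' @param alpha,beta location and scale of the gaussian/sigmoid families
#'   (`beta` > 0).
#' @return A `membership_params` object.
#' @examples
#' # February mean temperature, published calibration for Masson's pine
#' p <- membership_params(a = -42.4, b = 5, c = 8, d = 33.6, K = 13)
#' kt_membership(c(6.5, 20.8, 33.6), p)
#' @export
membership_params <- function(family = c("kt", "trapezoidal", "gaussian",
                                         "sigmoid_rise", "sigmoid_fall"),
                              a = NA, b = NA, c = NA, d = NA, K = 1,
                              alpha = NA, beta = NA) {
  family <- match.arg(family)
  if (family %in% c("kt", "trapezoidal")) {
    if (anyNA(c(a, b, c, d)))
      stop("a, b, c, d are required for the ", family, " family", call. = FALSE)
    if (!(a <= b && b <= c && c <= d))
      stop("invalid membership parameters: need a <= b <= c <= d", call. = FALSE)
    if (family == "kt" && (!is.finite(K) || K <= 0))
      stop("invalid membership parameters: K must be > 0", call. = FALSE)
  } else {
    if (anyNA(c(alpha, beta)) || beta <= 0)
      stop("alpha and beta (> 0) are required for the ", family, " family",
           call. = FALSE)
  }
  structure(list(family = family, a = a, b = b, c = c, d = d, K = K,
                 alpha = alpha, beta = beta),
            class = "membership_params")
}

#' @export
print.membership_params <- function(x, ...) {
  if (x$family %in% c("kt", "trapezoidal"))
    cat(sprintf("<membership_params> %s: a=%g b=%g c=%g d=%g K=%g\n",
                x$family, x$a, x$b, x$c, x$d, x$K))
  else
    cat(sprintf("<membership_params> %s: alpha=%g beta=%g\n",
                x$family, x$alpha, x$beta))
  invisible(x)
}

#' K-t membership function
#'
#' Evaluates the K-t fuzzy distribution: 0 for `x <= a` or `x >= d`, a
#' power-K rising limb on `(a, b)`, 1 on the plateau `[b, c]`, and a
#' power-K falling limb on `(c, d)`. Degenerate limbs (`b == a` or
#' `d == c`) become step edges and raise a warning.
#'
#' @param x factor values (vectorized).
#' @param params a [membership_params()] of family `"kt"`.
#' @return Membership values in \[0, 1\]; `NA` propagates.
#' @export
kt_membership <- function(x, params) {
  stopifnot(inherits(params, "membership_params"), params$family == "kt")
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d; K <- params$K
  if (b == a || d == cc)
    warning("degenerate K-t limb (b == a or d == c): membership steps 0 -> 1",
            call. = FALSE)
  mu <- numeric(length(x))
  mu[is.na(x)] <- NA_real_
  rise <- !is.na(x) & x > a & x < b
  if (any(rise)) mu[rise] <- ((x[rise] - a) / (b - a))^K
  plat <- !is.na(x) & x >= b & x <= cc
  mu[plat] <- 1
  fall <- !is.na(x) & x > cc & x < d
  if (any(fall)) mu[fall] <- ((d - x[fall]) / (d - cc))^K
  out <- pmin(pmax(mu, 0), 1)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Evaluate a membership function of any supported family
#'
#' @inheritParams kt_membership
#' @param params a [membership_params()].
#' @return Membership values in \[0, 1\].
#' @export
membership_value <- function(x, params) {
  stopifnot(inherits(params, "membership_params"))
  switch(params$family,
    kt = kt_membership(x, params),
    trapezoidal = {
      a <- params$a; b <- params$b; cc <- params$c; d <- params$d
      mu <- numeric(length(x))
      mu[is.na(x)] <- NA_real_
      rise <- !is.na(x) & x > a & x < b
      if (any(rise)) mu[rise] <- (x[rise] - a) / (b - a)
      mu[!is.na(x) & x >= b & x <= cc] <- 1
      fall <- !is.na(x) & x > cc & x < d
      if (any(fall)) mu[fall] <- (d - x[fall]) / (d - cc)
      out <- pmin(pmax(mu, 0), 1)
      if (!is.null(dim(x))) dim(out) <- dim(x)
      out
    },
    gaussian = exp(-((x - params$alpha) / params$beta)^2),
    sigmoid_rise = stats::plogis((x - params$alpha) / params$beta),
    sigmoid_fall = stats::plogis(-(x - params$alpha) / params$beta)
  )
}

#' Solve membership thresholds in closed form
#'
#' Returns the factor interval on which membership is at least `cutoff`,
#' obtained by inverting each monotone limb analytically (for the K-t
#' family, `x_low = a + (b - a) * cutoff^(1/K)` and
#' `x_high = d - (d - c) * cutoff^(1/K)`).
#'
#' @param params a [membership_params()].
#' @param cutoff membership cutoff in (0, 1].
#' @return A named numeric vector `c(x_low, x_high)`.
#' @export
membership_thresholds <- function(params, cutoff) {
  stopifnot(inherits(params, "membership_params"),
            is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  out <- switch(params$family,
    kt = {
      s <- cutoff^(1 / params$K)
      c(params$a + (params$b - params$a) * s,
        params$d - (params$d - params$c) * s)
    },
    trapezoidal = c(params$a + (params$b - params$a) * cutoff,
                    params$d - (params$d - params$c) * cutoff),
    gaussian = {
      w <- params$beta * sqrt(-log(cutoff))
      c(params$alpha - w, params$alpha + w)
    },
    sigmoid_rise = c(params$alpha + params$beta * stats::qlogis(cutoff), Inf),
    sigmoid_fall = c(-Inf, params$alpha - params$beta * stats::qlogis(cutoff))
  )
  stats::setNames(out, c("x_low", "x_high"))
}

# RSS of a family against (x, y) points, given an unconstrained parameter
# vector theta. Parameterization enforces a <= b <= c <= d (log-gap) and
# K > 0, beta > 0 (log).
theta_to_params <- function(theta, family) {
  if (family %in% c("kt", "trapezoidal")) {
    a <- theta[1]
    b <- a + exp(theta[2]); cc <- b + exp(theta[3]); d <- cc + exp(theta[4])
    K <- if (family == "kt") exp(theta[5]) else 1
    membership_params(family, a = a, b = b, c = cc, d = d, K = K)
  } else {
    membership_params(family, alpha = theta[1], beta = exp(theta[2]))
  }
}

n_theta <- function(family) {
  switch(family, kt = 5L, trapezoidal = 4L, 2L)
}

#' Fit a membership function to factor/indicator data
#'
#' Fits a fuzzy membership function to the relationship between one
#' ecological factor and the quality indicator by nonlinear least squares.
#' The indicator is first stabilized by quantile binning on the factor
#' (`n_bins` bins, bin means of both variables); because the indicator at a
#' site also reflects the other factors, the per-factor conditional mean is
#' an affine compression of the factor's own membership curve, so the
#' binned response is min-max rescaled to \[0, 1\] before fitting
#' (`rescale = FALSE` fits the raw pairs instead). Optimization is
#' Nelder-Mead on a constrained parameterization (`a <= b <= c <= d`,
#' `K > 0`), multi-started from `n_starts` initializations derived from
#' data quantiles; the best residual sum of squares is kept.
#'
#' @param factor_values numeric factor values at the sample sites.
#' @param indicator_values aggregative indicator at the same sites, in \[0, 1\].
#' @param family membership family to fit (see [membership_params()]).
#' @param bin quantile-bin the data before fitting (default TRUE).
#' @param n_bins number of quantile bins (default 20).
#' @param rescale min-max rescale the (binned) indicator to \[0, 1\] before
#'   fitting (default TRUE).
#' @param n_starts number of multi-start initializations (default 10).
#' @return A `fitted_membership` object with elements `params`
#'   ([membership_params()]), `goodness` (residual sum of squares on the
#'   fitted scale) and `n_points`.
#' @export
fit_membership <- function(factor_values, indicator_values,
                           family = c("kt", "trapezoidal", "gaussian",
                                      "sigmoid_rise", "sigmoid_fall"),
                           bin = TRUE, n_bins = 20, rescale = TRUE,
                           n_starts = 10) {
  family <- match.arg(family)
  ok <- is.finite(factor_values) & is.finite(indicator_values)
  x <- factor_values[ok]; y <- indicator_values[ok]
  if (length(x) < 8L)
    stop("fit error: need at least 8 points with finite factor and indicator values",
         call. = FALSE)
  if (any(y < -1e-9) || any(y > 1 + 1e-9))
    stop("fit error: indicator values must lie in [0, 1]", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("fit error: all factor values are identical", call. = FALSE)
  n_obs <- length(x)

  if (bin && n_obs > n_bins) {
    brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(brk) > 2L) {
      g <- cut(x, breaks = brk, include.lowest = TRUE)
      x <- tapply(x, g, mean)
      y <- tapply(y, g, mean)
      keep <- is.finite(x) & is.finite(y)
      x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
    }
  }
  if (rescale) {
    ry <- range(y)
    if (diff(ry) > 0) y <- (y - ry[1]) / diff(ry) else y <- rep(1, length(y))
  }
  if (length(x) < n_theta(family))
    stop("fit error: fewer points than parameters", call. = FALSE)

  rx <- range(x); span <- diff(rx)
  # keep the support within reach of the data: limbs may extend past the
  # observed range (the published calibration has a < 0 for precipitation)
  # but not arbitrarily far, and K stays in a sane band
  lo_bound <- rx[1] - 2 * span
  hi_bound <- rx[2] + 2 * span
  rss_fn <- function(theta) {
    p <- try(theta_to_params(theta, family), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    pen <- 0
    if (family %in% c("kt", "trapezoidal")) {
      if (p$a < lo_bound) pen <- pen + ((lo_bound - p$a) / span)^2
      if (p$d > hi_bound) pen <- pen + ((p$d - hi_bound) / span)^2
      if (family == "kt") pen <- pen + max(0, abs(log(p$K)) - log(50))^2
    } else if (p$beta > 2 * span) pen <- pen + ((p$beta - 2 * span) / span)^2
    mu <- suppressWarnings(membership_value(x, p))
    sum((mu - y)^2) + 100 * pen
  }
  qs <- stats::quantile(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  starts <- list()
  # spread plateau guesses across the data quantiles; K guesses around 1-3
  widths <- span * c(0.1, 0.25, 0.5)
  centers <- qs[c(2, 3, 4)]
  k0 <- c(0, log(2), log(5))
  i <- 0L
  for (w in widths) for (ct in centers) {
    i <- i + 1L
    if (i > n_starts) break
    if (family %in% c("kt", "trapezoidal")) {
      a0 <- ct - w; b0 <- ct - w / 4; c0 <- ct + w / 4; d0 <- ct + w
      th <- c(a0, log(b0 - a0), log(max(c0 - b0, 1e-6)), log(d0 - c0))
      if (family == "kt") th <- c(th, k0[(i - 1L) %% 3L + 1L])
    } else {
      th <- c(ct, log(max(w, 1e-6)))
    }
    starts[[i]] <- th
  }
  # one wide start covering the full observed range
  if (length(starts) < n_starts) {
    if (family %in% c("kt", "trapezoidal")) {
      th <- c(rx[1] - 0.5 * span, log(0.5 * span), log(span), log(0.5 * span))
      if (family == "kt") th <- c(th, log(1.5))
    } else th <- c(mean(rx), log(span / 2))
    starts[[length(starts) + 1L]] <- th
  }

  best <- NULL
  for (th in starts) {
    fit <- try(stats::optim(th, rss_fn, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("fit error: optimization failed for every start", call. = FALSE)

  structure(list(params = theta_to_params(best$par, family),
                 goodness = best$value, n_points = n_obs,
                 family = family),
            class = "fitted_membership")
}

#' @export
print.fitted_membership <- function(x, ...) {
  cat(sprintf("<fitted_membership> family %s, RSS %.4g over %d points\n",
              x$family, x$goodness, x$n_points))
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fitted_membership <- function(x, ...) {
  p <- x$params
  vals <- c(a = p$a, b = p$b, c = p$c, d = p$d, K = p$K,
            alpha = p$alpha, beta = p$beta)
  vals <- vals[!is.na(vals)]
  tibble::tibble(term = names(vals), estimate = unname(vals))
}

#' @exportS3Method generics::glance
glance.fitted_membership <- function(x, ...) {
  tibble::tibble(family = x$family, rss = x$goodness, n_points = x$n_points)
}

#' Choose a membership family by penalized curve fitting
#'
#' Fits every candidate family to the same factor/indicator data and keeps
#' the one with the smallest parsimony-penalized residual sum of squares,
#' `RSS * n / (n - p)` where `p` is the family's parameter count.
#'
#' @inheritParams fit_membership
#' @param families candidate families to compare.
#' @return The winning `fitted_membership`, with the comparison table in
#'   attribute `"comparison"`.
#' @export
select_membership_family <- function(factor_values, indicator_values,
                                     families = c("kt", "trapezoidal", "gaussian",
                                                  "sigmoid_rise", "sigmoid_fall"),
                                     ...) {
  fits <- purrr::map(families, function(fam) {
    try(fit_membership(factor_values, indicator_values, family = fam, ...),
        silent = TRUE)
  })
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("fit error: no candidate family could be fitted", call. = FALSE)
  fits <- fits[ok]; families <- families[ok]
  score <- vapply(fits, function(f) {
    p <- n_theta(f$family)
    n <- f$n_points
    f$goodness * n / max(n - p, 1)
  }, 0)
  cmp <- tibble::tibble(family = families, rss = vapply(fits, `[[`, 0, "goodness"),
                        penalized = score)
  best <- fits[[which.min(score)]]
  attr(best, "comparison") <- cmp
  best
}

#' Standardize a factor raster to \[0, 1\] suitability
#'
#' Applies a membership function cellwise, turning a raw ecological-factor
#' raster into a suitability layer in \[0, 1\]. Nodata propagates.
#'
#' @param raster an [eco_raster()] of raw factor values.
#' @param params a [membership_params()].
#' @return An `eco_raster` of membership values.
#' @export
standardize_raster <- function(raster, params) {
  raster_map(raster, membership_value, params = params)
}

#' Read and write membership-parameter tables
#'
#' A membership-parameter table mirrors the published calibration layout:
#' one row per factor with columns
#' `factor, family, a, b, c, d, K, alpha, beta`.
#'
#' @param params_tbl tibble with those columns (`alpha`, `beta` optional).
#' @param path CSV path.
#' @return `read_membership_params()` returns a tibble;
#'   `write_membership_params()` returns `path` invisibly.
#' @export
write_membership_params <- function(params_tbl, path) {
  readr::write_csv(params_tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_membership_params
#' @export
read_membership_params <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert a membership-parameter table row to parameters
#'
#' @param params_tbl a membership-parameter tibble (see
#'   [write_membership_params()]).
#' @param factor_name the `factor` value of the row to extract.
#' @return A [membership_params()].
#' @export
params_from_table <- function(params_tbl, factor_name) {
  row <- params_tbl[params_tbl$factor == factor_name, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("expected exactly one row for factor '", factor_name, "'", call. = FALSE)
  fam <- if ("family" %in% names(row)) row$family else "kt"
  membership_params(fam, a = row$a, b = row$b, c = row$c, d = row$d,
                    K = if ("K" %in% names(row)) row$K else 1,
                    alpha = if ("alpha" %in% names(row)) row$alpha else NA,
                    beta = if ("beta" %in% names(row)) row$beta else NA)
}

#' Plot a membership function
#'
#' @param params a [membership_params()].
#' @param from,to x-range of the plot (defaults to the support, padded).
#' @param n number of evaluation points.
#' @return A ggplot object.
#' @export
plot_membership <- function(params, from = NULL, to = NULL, n = 400) {
  if (is.null(from) || is.null(to)) {
    if (params$family %in% c("kt", "trapezoidal")) {
      pad <- 0.05 * (params$d - params$a)
      from <- from %||% (params$a - pad); to <- to %||% (params$d + pad)
    } else {
      from <- from %||% (params$alpha - 4 * params$beta)
      to <- to %||% (params$alpha + 4 * params$beta)
    }
  }
  x <- seq(from, to, length.out = n)
  df <- tibble::tibble(x = x, membership = membership_value(x, params))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$membership)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "membership")
}
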