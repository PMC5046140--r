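#' Normalize contributions into overlay weights
#'
#' Turns a percent-contribution table into objective overlay weights by
#' dividing each contribution by the total, preserving row order. This is
#' the "objective weight" route: factor weights come from the maximum
#' entropy model's variable contributions rather than expert judgement.
#'
#' @param contributions tibble with `variable` and `contribution` columns
#'   (contributions >= 0, not all zero).
#' @return A tibble with `variable` and `weight` columns; weights sum to 1.
#' @export
normalize_weights <- function(contributions) {
  stopifnot(all(c("variable", "contribution") %in% names(contributions)))
  w <- contributions$contribution
  if (any(w < 0) || sum(w) <= 0)
    stop("contributions must be non-negative with a positive total", call. = FALSE)
  tibble::tibble(variable = contributions$variable, weight = w / sum(w))
}

#' Weighted overlay of suitability layers
#'
#' Cellwise weighted mean of aligned \[0, 1\] suitability rasters, the grid
#' computation producing the composite suitability surface. Nodata in any
#' layer propagates to the output; the result is a convex combination, so
#' it is bounded by the inputs.
#'
#' @param rasters named list of aligned suitability rasters.
#' @param weights tibble with `variable` and `weight` columns
#'   (see [normalize_weights()]); names must match the raster list.
#' @return An [eco_raster()] composite.
#' @export
weighted_overlay <- function(rasters, weights) {
  stopifnot(all(c("variable", "weight") %in% names(weights)))
  if (!setequal(weights$variable, names(rasters)))
    stop("weight variables and raster names do not match", call. = FALSE)
  if (abs(sum(weights$weight) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  tmpl <- rasters[[weights$variable[1]]]
  for (v in weights$variable)
    if (!same_grid(rasters[[v]], tmpl))
      stop("alignment error: rasters are not on a common grid", call. = FALSE)
  acc <- matrix(0, nrow(tmpl$values), ncol(tmpl$values))
  for (i in seq_len(nrow(weights)))
    acc <- acc + weights$weight[i] * rasters[[weights$variable[i]]]$values
  eco_raster(acc, xll = tmpl$xll, yll = tmpl$yll, cellsize = tmpl$cellsize,
             nodata = tmpl$nodata, crs = tmpl$crs)
}

#' Mask a suitability raster by land cover
#'
#' Removes cells whose land-cover class cannot host the target vegetation
#' (farmland, water, urban, ...): any cell whose class is not in
#' `allowed_classes` becomes nodata.
#'
#' @param composite an [eco_raster()] suitability layer.
#' @param landcover an aligned categorical [eco_raster()] of class ids.
#' @param allowed_classes vector of class ids to keep (e.g. the coniferous
#'   forest class).
#' @return The masked [eco_raster()].
#' @export
mask_landcover <- function(composite, landcover, allowed_classes) {
  if (!same_grid(composite, landcover))
    stop("alignment error: composite and land-cover grids differ", call. = FALSE)
  out <- composite
  out$values[!(landcover$values %in% allowed_classes)] <- NA_real_
  out
}

#' Combine growth and quality suitability
#'
#' Overlays the growth-suitability map (distribution model) and the
#' quality-suitability map (fuzzy composite) into one production map. The
#' default rule is the cellwise minimum — a site must satisfy both — with
#' product and mean as alternatives.
#'
#' @param growth,quality aligned [eco_raster()] layers in \[0, 1\].
#' @param method `"min"` (default), `"product"` or `"mean"`.
#' @return An [eco_raster()].
#' @export
combine_suitability <- function(growth, quality,
                                method = c("min", "product", "mean")) {
  method <- match.arg(method)
  if (!same_grid(growth, quality))
    stop("alignment error: growth and quality grids differ", call. = FALSE)
  out <- growth
  out$values <- switch(method,
    min = pmin(growth$values, quality$values),
    product = growth$values * quality$values,
    mean = (growth$values + quality$values) / 2
  )
  out
}

#' Three-class suitability regionalization
#'
#' Reclassifies a composite suitability raster into highly suitable
#' (class 1, value >= `t_high`), marginally suitable (class 2,
#' `t_low` <= value < `t_high`) and unsuitable (class 3, otherwise), and
#' tabulates per-class cell counts, areas (count x cellsize^2, in the
#' grid's own units) and percentages of the classified (non-nodata) area.
#'
#' @param composite an [eco_raster()] in \[0, 1\].
#' @param t_high,t_low class cutoffs, `0 <= t_low < t_high <= 1`.
#' @param quantiles alternative to fixed cutoffs: when TRUE, `t_high` and
#'   `t_low` are interpreted as upper-tail quantile levels of the
#'   classified cells (e.g. 0.9 / 0.7).
#' @return A `classification` object: list with `raster` (class ids,
#'   nodata preserved), `stats` (tibble: class, label, n_cells, area,
#'   percent) and the cutoffs used.
#' @export
classify_suitability <- function(composite, t_high = 0.7, t_low = 0.4,
                                 quantiles = FALSE) {
  if (!(is.numeric(t_low) && is.numeric(t_high) &&
        t_low >= 0 && t_high <= 1 && t_low < t_high))
    stop("config error: need 0 <= t_low < t_high <= 1", call. = FALSE)
  v <- composite$values
  if (quantiles) {
    qs <- stats::quantile(v, probs = c(t_low, t_high), na.rm = TRUE, names = FALSE)
    t_low <- qs[1]; t_high <- qs[2]
  }
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[!is.na(v)] <- 3
  cls[!is.na(v) & v >= t_low] <- 2
  cls[!is.na(v) & v >= t_high] <- 1
  n_classified <- sum(!is.na(v))
  if (n_classified == 0) stop("no classified cells (all nodata)", call. = FALSE)
  counts <- vapply(1:3, function(k) sum(cls == k, na.rm = TRUE), 0L)
  stats <- tibble::tibble(
    class = 1:3,
    label = c("highly suitable", "marginally suitable", "unsuitable"),
    n_cells = counts,
    area = counts * composite$cellsize^2,
    percent = 100 * counts / n_classified
  )
  out <- composite
  out$values <- cls
  structure(list(raster = out, stats = stats,
                 t_high = t_high, t_low = t_low),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> cutoffs: high >= %.3g, low >= %.3g\n",
              x$t_high, x$t_low))
  print(x$stats)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.classification <- function(x, ...) x$stats

#' @exportS3Method ggplot2::autoplot
autoplot.classification <- function(object, ...) {
  df <- as_tibble.eco_raster(object$raster)
  df$class <- factor(df$value, levels = 1:3,
                     labels = c("highly suitable", "marginally suitable",
                                "unsuitable"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c("#1a9850", "#fee08b", "#d73027"),
                               na.value = "grey90", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}

#' Area statistics report
#'
#' Per-class area/percentage rows plus a derived "suitable total" row: the
#' union of the highly and marginally suitable classes (the figure
#' reported as the share of territory usable for production). Accepts a
#' [classify_suitability()] result or a per-class stats tibble with
#' `label`, `area` and optionally `percent`/`n_cells` columns.
#'
#' @param result a `classification` or a per-class stats tibble.
#' @return A tibble with the per-class rows and a `suitable total` row.
#' @export
area_stats_report <- function(result) {
  stats <- if (inherits(result, "classification")) result$stats else result
  stopifnot(all(c("label", "area") %in% names(stats)))
  if (!"percent" %in% names(stats))
    stats$percent <- 100 * stats$area / sum(stats$area)
  suit <- stats[stats$label %in% c("highly suitable", "marginally suitable"), ]
  total <- tibble::tibble(
    class = NA_integer_,
    label = "suitable total",
    n_cells = if ("n_cells" %in% names(stats)) sum(suit$n_cells) else NA_integer_,
    area = sum(suit$area),
    percent = sum(suit$percent)
  )
  dplyr::bind_rows(
    stats[, intersect(c("class", "label", "n_cells", "area", "percent"),
                      names(stats))],
    total[, intersect(names(total),
                      c(intersect(c("class", "label", "n_cells", "area", "percent"),
                                  names(stats))))]
  )
}
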