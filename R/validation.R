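#' Root mean square error
#'
#' `sqrt(mean((predicted - observed)^2))` between predicted suitability and
#' the observed indicator, both on the \[0, 1\] scale.
#'
#' @param predicted,observed numeric vectors of equal length >= 1.
#' @return RMSE, a non-negative number.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  if (length(predicted) < 1L) stop("need at least one pair", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Validate a suitability map against observed indicators
#'
#' Extracts the suitability map at the sample sites and compares it with
#' the observed aggregative indicator by RMSE. Sites falling on nodata
#' cells (or outside the extent) are excluded and reflected in `n_points`.
#'
#' @param suitability an [eco_raster()] in \[0, 1\].
#' @param points tibble with `point_id`, `x`, `y`.
#' @param indicator_table tibble with `point_id` and `indicator` columns
#'   (see [normalize_contents()]).
#' @return A `validation_report`: list with `rmse`, `n_points` and a
#'   per-point tibble (`point_id`, `predicted`, `observed`, `residual`).
#' @export
validate_map <- function(suitability, points, indicator_table) {
  stopifnot(all(c("point_id", "x", "y") %in% names(points)),
            all(c("point_id", "indicator") %in% names(indicator_table)))
  df <- dplyr::inner_join(
    tibble::tibble(point_id = points$point_id,
                   predicted = extract_at_points(suitability, points)),
    indicator_table[, c("point_id", "indicator")],
    by = "point_id"
  ) |>
    dplyr::rename(observed = "indicator") |>
    dplyr::filter(!is.na(.data$predicted), !is.na(.data$observed)) |>
    dplyr::mutate(residual = .data$predicted - .data$observed)
  if (nrow(df) < 1L)
    stop("no sample point has both a prediction and an observation", call. = FALSE)
  structure(list(rmse = rmse(df$predicted, df$observed),
                 n_points = nrow(df), points = df),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> RMSE %.4f over %d point(s)\n",
              x$rmse, x$n_points))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, n_points = x$n_points)
}
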