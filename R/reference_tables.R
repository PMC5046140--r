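#' Published calibration tables for Masson's pine needle quality
#'
#' Reference tables from the published habitat-suitability regionalization
#' of Masson's pine (*Pinus massoniana*), the system this package was built
#' around. They serve as worked-example inputs and as defaults for the
#' synthetic-landscape ground truth.
#'
#' `masson_membership_params()` returns the fitted K-t membership
#' parameters (a, b, c, d, K) of the five retained ecological factors:
#' precipitation in April and June (mm), monthly mean temperature in
#' February and August (deg C), and altitude (m). Negative `a` values mean
#' the fitted rising limb extends below the physical range of the factor.
#'
#' `masson_contributions()` returns the per-factor percent contributions to
#' habitat suitability for the aggregative quality indicator, with each
#' factor tagged by type (climatic or topographical) and by variable group
#' (precipitation, temperature, altitude).
#'
#' `masson_area_table()` returns the published per-class areas and
#' percentages of the three-class production regionalization (highly
#' suitable, marginally suitable, unsuitable), in the source's own area
#' units.
#'
#' @return A tibble (layout described above).
#' @name masson_reference
NULL

#' @rdname masson_reference
#' @export
masson_membership_params <- function() {
  tibble::tibble(
    factor = c("precip_april", "precip_june", "temp_feb", "temp_aug", "altitude"),
    label = c("Precipitation in April (mm)", "Precipitation in June (mm)",
              "Monthly avg. temperature, February (°C)",
              "Monthly avg. temperature, August (°C)", "Altitude (m)"),
    family = "kt",
    a = c(-63.9, -63.7, -42.4, 20, -900),
    b = c(98.8, 149.2, 5, 22, 800),
    c = c(113.8, 194.2, 8, 24, 1181),
    d = c(191.3, 427.4, 33.6, 36.1, 2195),
    K = c(1.62, 2.51, 13, 2.93, 2.9)
  )
}

#' @rdname masson_reference
#' @export
masson_contributions <- function() {
  tibble::tibble(
    variable = c("precip_april", "precip_june", "temp_feb", "temp_aug", "altitude"),
    type = c("climatic", "climatic", "climatic", "climatic", "topographical"),
    group = c("precipitation", "precipitation", "temperature", "temperature",
              "altitude"),
    contribution = c(3.4, 13.9, 25.8, 43.9, 13.0)
  )
}

#' @rdname masson_reference
#' @export
masson_area_table <- function() {
  tibble::tibble(
    class = 1:3,
    label = c("highly suitable", "marginally suitable", "unsuitable"),
    area = c(14769.86, 49966.0986, 809140.01),
    percent = c(1.69, 5.72, 92.59)
  )
}

#' Aggregate percent contributions by factor group
#'
#' Sums a contribution table over a grouping column (factor `type` or
#' variable `group`), e.g. to compare the overall influence of climatic
#' versus topographical factors, or temperature versus precipitation.
#'
#' @param contributions tibble with a `contribution` column and the
#'   grouping column.
#' @param by name of the grouping column (default `"type"`).
#' @return A tibble with columns `by` and `contribution` (summed).
#' @export
contribution_by_group <- function(contributions, by = "type") {
  stopifnot(by %in% names(contributions), "contribution" %in% names(contributions))
  contributions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(contribution = sum(.data$contribution), .groups = "drop")
}
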