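#' Aggregative quality indicator from compound contents
#'
#' Builds the composite chemical-quality indicator from the four compound
#' contents measured at each sample site (shikimic acid, procyanidins,
#' total flavonoids, total lignans). Each compound is normalized to
#' \[0, 1\] across sites (min-max by default, z-score squashed through the
#' standard normal CDF as an alternative) and the composite is their
#' weighted mean — equal weights by default, since the four compounds are
#' treated as equally important.
#'
#' @param points tibble of sample points containing the four compound
#'   columns (`shikimic`, `procyanidins`, `flavonoids`, `lignans`) and a
#'   `point_id` column; >= 2 rows.
#' @param compounds names of the compound columns.
#' @param method `"minmax"` (default) or `"zscore"`.
#' @param weights per-compound weights (default equal); normalized to sum
#'   to 1.
#' @return A tibble with `point_id`, one `norm_*` column per compound
#'   (each in \[0, 1\]) and the composite `indicator` in \[0, 1\].
#' @export
normalize_contents <- function(points,
                               compounds = c("shikimic", "procyanidins",
                                             "flavonoids", "lignans"),
                               method = c("minmax", "zscore"),
                               weights = NULL) {
  method <- match.arg(method)
  if (nrow(points) < 2L)
    stop("need at least 2 sample points to normalize contents", call. = FALSE)
  if (!all(compounds %in% names(points)))
    stop("missing compound column(s): ",
         paste(setdiff(compounds, names(points)), collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(compounds))
  weights <- weights / sum(weights)

  norm_one <- function(v, name) {
    if (diff(range(v, na.rm = TRUE)) == 0) {
      warning("compound '", name, "' is constant across points; normalized to 0.5",
              call. = FALSE)
      return(rep(0.5, length(v)))
    }
    switch(method,
      minmax = (v - min(v, na.rm = TRUE)) /
               (max(v, na.rm = TRUE) - min(v, na.rm = TRUE)),
      zscore = stats::pnorm((v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE))
    )
  }

  out <- tibble::tibble(point_id = points$point_id)
  for (cmp in compounds)
    out[[paste0("norm_", cmp)]] <- norm_one(points[[cmp]], cmp)
  out$indicator <- aggregative_indicator(out, compounds = compounds,
                                         weights = weights)
  out
}

#' Composite of normalized compound values
#'
#' The weighted mean (equal weights by default) of the normalized compound
#' columns of an indicator table.
#'
#' @param table tibble with `norm_<compound>` columns (see
#'   [normalize_contents()]).
#' @param compounds compound names.
#' @param weights per-compound weights, normalized to sum to 1.
#' @return Numeric vector of composite indicator values in \[0, 1\].
#' @export
aggregative_indicator <- function(table,
                                  compounds = c("shikimic", "procyanidins",
                                                "flavonoids", "lignans"),
                                  weights = NULL) {
  cols <- paste0("norm_", compounds)
  if (!all(cols %in% names(table)))
    stop("missing normalized column(s): ",
         paste(setdiff(cols, names(table)), collapse = ", "), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(compounds))
  weights <- weights / sum(weights)
  as.numeric(as.matrix(table[cols]) %*% weights)
}
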