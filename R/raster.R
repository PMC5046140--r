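#' Gridded raster layers
#'
#' `habsuit` represents every gridded layer (an ecological factor, a
#' land-cover class map, a suitability score) as an `eco_raster`: a numeric
#' matrix of cell values plus a georeferencing header following the ESRI
#' ASCII grid convention. Row 1 of the matrix is the northernmost row;
#' `(xll, yll)` is the lower-left corner of the grid; cells are square.
#' Missing cells are stored as `NA` internally and mapped to the header's
#' nodata value only on write.
#'
#' @param values numeric matrix of cell values, row 1 = north. `NA` marks
#'   nodata cells.
#' @param xll,yll map coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length in map units (> 0); cells are square.
#' @param nodata value used to encode missing cells in files (default -9999).
#' @param crs free-text coordinate reference tag carried along, never
#'   interpreted (the package does not reproject).
#' @return An `eco_raster` object.
#' @examples
#' r <- eco_raster(matrix(1:6, nrow = 2, byrow = TRUE), xll = 0, yll = 0, cellsize = 10)
#' r
#' @export
eco_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                       nodata = -9999, crs = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata, crs = crs),
    class = "eco_raster"
  )
}

#' @export
print.eco_raster <- function(x, ...) {
  v <- x$values
  fin <- v[is.finite(v)]
  cat(sprintf("<eco_raster> %d rows x %d cols, cellsize %g\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize))
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d nodata cell(s)\n",
                min(fin), max(fin), sum(is.na(v))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
dim.eco_raster <- function(x) dim(x$values)

is_eco_raster <- function(x) inherits(x, "eco_raster")

n_cells <- function(r) length(r$values)

#' Convert between cell indices and map coordinates
#'
#' Cell `(row, col)` (row 1 = north) maps to the coordinates of its center;
#' the two functions are mutual inverses for points inside the extent.
#' `xy_to_rowcol()` returns `NA` rows for out-of-extent points.
#'
#' @param raster an [eco_raster()].
#' @param row,col cell indices (1-based, row 1 = northern edge).
#' @param x,y map coordinates.
#' @return A tibble with columns `x`, `y` (for `rowcol_to_xy`) or
#'   `row`, `col` (for `xy_to_rowcol`).
#' @export
rowcol_to_xy <- function(raster, row, col) {
  nr <- nrow(raster$values)
  tibble::tibble(
    x = raster$xll + (col - 0.5) * raster$cellsize,
    y = raster$yll + (nr - row + 0.5) * raster$cellsize
  )
}

#' @rdname rowcol_to_xy
#' @export
xy_to_rowcol <- function(raster, x, y) {
  nr <- nrow(raster$values)
  nc <- ncol(raster$values)
  col <- floor((x - raster$xll) / raster$cellsize) + 1L
  row <- nr - floor((y - raster$yll) / raster$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Tidy a raster into a tibble of cell centers
#'
#' @param x an [eco_raster()].
#' @param ... unused.
#' @return A tibble with columns `x`, `y`, `value`, one row per cell
#'   (nodata cells carry `NA`).
#' @exportS3Method tibble::as_tibble
as_tibble.eco_raster <- function(x, ...) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xy <- rowcol_to_xy(x, idx$row, idx$col)
  vals <- x$values[cbind(idx$row, idx$col)]
  tibble::tibble(x = xy$x, y = xy$y, value = vals)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' optional `NODATA_value`) followed by `nrows` rows of values, the first
#' row being the northernmost. Nodata cells become `NA`.
#'
#' @param path file path.
#' @return An [eco_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  repeat {
    if (i > length(lines)) stop("ESRI ASCII parse error: header runs past end of file", call. = FALSE)
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    key <- tolower(parts[[1]])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                     "yllcorner", "yllcenter", "cellsize", "nodata_value")))
      break
    if (length(parts) != 2L)
      stop("ESRI ASCII parse error in header key '", key, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(parts[[2]]))
    if (is.na(val))
      stop("ESRI ASCII parse error: non-numeric value for header key '", key, "'", call. = FALSE)
    hdr[[key]] <- val
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]]))
      stop("ESRI ASCII parse error: missing header key '", key, "'", call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (nc < 1L || nr < 1L)
    stop("ESRI ASCII parse error: non-positive dimensions in header", call. = FALSE)
  cs <- hdr$cellsize
  if (cs <= 0) stop("ESRI ASCII parse error: non-positive value for header key 'cellsize'", call. = FALSE)
  # llcenter variants shift by half a cell to the corner convention
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cs / 2
         else stop("ESRI ASCII parse error: missing header key 'xllcorner'", call. = FALSE)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cs / 2
         else stop("ESRI ASCII parse error: missing header key 'yllcorner'", call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value

  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) != nr)
    stop(sprintf("dimension error: expected %d data rows, found %d", nr, length(body)),
         call. = FALSE)
  rows <- lapply(body, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (length(v) != nc || anyNA(v))
      stop(sprintf("dimension error: data row with %d values, expected %d numeric values",
                   length(v), nc), call. = FALSE)
    v
  })
  values <- do.call(rbind, rows)
  values[values == nodata] <- NA_real_
  eco_raster(values, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Finite values round-trip through [read_ascii_grid()] losslessly at the
#' written precision (9 significant digits); `NA` cells are written as the
#' raster's nodata value.
#'
#' @param raster an [eco_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(is_eco_raster(raster))
  v <- raster$values
  nodata <- raster$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.9g", raster$xll),
    sprintf("yllcorner %.9g", raster$yll),
    sprintf("cellsize %.9g", raster$cellsize),
    sprintf("NODATA_value %.9g", nodata)
  )
  body <- apply(v, 1L, function(row) {
    row[is.na(row)] <- nodata
    paste(sprintf("%.9g", row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Align rasters onto one analysis grid
#'
#' Resamples a set of overlapping rasters onto a common grid covering their
#' shared extent. The target cell size defaults to the coarsest (maximum)
#' input cell size, matching the GIS practice of setting the analysis grid
#' to the largest input grid. Continuous layers are resampled bilinearly,
#' categorical layers (land cover) by nearest neighbour. Aligning layers
#' that already share a grid returns them unchanged, so the operation is
#' idempotent.
#'
#' @param rasters a (optionally named) list of [eco_raster()] objects.
#' @param target_cellsize target cell size; default `max` of the inputs.
#' @param categorical logical vector (recycled) flagging layers to resample
#'   by nearest neighbour instead of bilinear interpolation.
#' @return A list of aligned `eco_raster`s with a common header.
#' @export
align_rasters <- function(rasters, target_cellsize = NULL, categorical = FALSE) {
  stopifnot(length(rasters) >= 1L, all(vapply(rasters, is_eco_raster, TRUE)))
  categorical <- rep_len(categorical, length(rasters))
  cs <- if (is.null(target_cellsize)) max(vapply(rasters, `[[`, 0, "cellsize"))
        else target_cellsize
  if (cs <= 0) stop("target cell size must be positive", call. = FALSE)

  xmin <- max(vapply(rasters, `[[`, 0, "xll"))
  ymin <- max(vapply(rasters, `[[`, 0, "yll"))
  xmax <- min(vapply(rasters, function(r) r$xll + ncol(r$values) * r$cellsize, 0))
  ymax <- min(vapply(rasters, function(r) r$yll + nrow(r$values) * r$cellsize, 0))
  if (xmax - xmin < cs - 1e-12 || ymax - ymin < cs - 1e-12)
    stop("alignment error: raster extents are disjoint or overlap by less than one cell",
         call. = FALSE)

  nc <- max(1L, floor((xmax - xmin) / cs + 1e-9))
  nr <- max(1L, floor((ymax - ymin) / cs + 1e-9))
  target <- eco_raster(matrix(NA_real_, nr, nc), xll = xmin, yll = ymin, cellsize = cs)

  if (all(vapply(rasters, same_grid, TRUE, b = target)))
    return(rasters)

  out <- purrr::map2(rasters, categorical, function(r, cat) {
    vals <- resample_to(r, target, method = if (cat) "nearest" else "bilinear")
    eco_raster(vals, xll = xmin, yll = ymin, cellsize = cs,
               nodata = r$nodata, crs = r$crs)
  })
  names(out) <- names(rasters)
  out
}

# Resample source raster onto the target grid; returns a matrix.
resample_to <- function(src, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nr <- nrow(target$values); nc <- ncol(target$values)
  cx <- target$xll + (seq_len(nc) - 0.5) * target$cellsize
  cy <- target$yll + (nr - seq_len(nr) + 0.5) * target$cellsize
  snr <- nrow(src$values); snc <- ncol(src$values)
  # fractional position in the source's cell-center frame
  fc <- (cx - src$xll) / src$cellsize + 0.5   # 1..snc at cell centers
  fr <- snr - (cy - src$yll) / src$cellsize + 0.5

  if (method == "nearest") {
    ic <- pmin(pmax(round(fc), 1L), snc)
    ir <- pmin(pmax(round(fr), 1L), snr)
    return(src$values[ir, ic, drop = FALSE])
  }

  c0 <- pmin(pmax(floor(fc), 1L), snc - 1L); c0 <- pmax(c0, 1L)
  r0 <- pmin(pmax(floor(fr), 1L), snr - 1L); r0 <- pmax(r0, 1L)
  if (snc == 1L) c0 <- rep(1L, nc)
  if (snr == 1L) r0 <- rep(1L, nr)
  tx <- pmin(pmax(fc - c0, 0), 1)
  ty <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1L, snc); r1 <- pmin(r0 + 1L, snr)

  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    v00 <- src$values[cbind(r0, rep(c0[j], nr))]
    v01 <- src$values[cbind(r0, rep(c1[j], nr))]
    v10 <- src$values[cbind(r1, rep(c0[j], nr))]
    v11 <- src$values[cbind(r1, rep(c1[j], nr))]
    w00 <- (1 - tx[j]) * (1 - ty); w01 <- tx[j] * (1 - ty)
    w10 <- (1 - tx[j]) * ty;       w11 <- tx[j] * ty
    num <- cbind(v00 * w00, v01 * w01, v10 * w10, v11 * w11)
    den <- cbind(w00 * !is.na(v00), w01 * !is.na(v01),
                 w10 * !is.na(v10), w11 * !is.na(v11))
    s <- rowSums(den)
    val <- rowSums(num, na.rm = TRUE) / s
    val[s == 0] <- NA_real_
    out[, j] <- val
  }
  out
}

#' Extract raster values at sample points
#'
#' Returns the value of the cell containing each point (nearest-cell rule,
#' no interpolation, matching the GIS "extract values to points" default).
#' Points outside the raster extent, or over nodata cells, yield `NA`.
#'
#' @param raster an [eco_raster()].
#' @param points a data frame with numeric `x` and `y` columns.
#' @return A numeric vector, one value per point (`NA` = missing).
#' @export
extract_at_points <- function(raster, points) {
  stopifnot(is_eco_raster(raster), all(c("x", "y") %in% names(points)))
  rc <- xy_to_rowcol(raster, points$x, points$y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc$row)
  out[ok] <- raster$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Read and write sample-point tables
#'
#' Sample points are tabular: one row per field sample with coordinates,
#' altitude and the contents of the four quality compounds (shikimic acid,
#' procyanidins, total flavonoids, total lignans). The CSV header is
#' `point_id,x,y,altitude,shikimic,procyanidins,flavonoids,lignans`.
#'
#' @param path CSV file path.
#' @param points tibble of sample points.
#' @return `read_points()` returns a tibble; `write_points()` returns
#'   `path` invisibly.
#' @export
read_points <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  readr::write_csv(points, path, progress = FALSE)
  invisible(path)
}

#' Map a function over raster cells
#'
#' Applies a vectorized function to the cell values of a raster, preserving
#' the header; `NA` (nodata) cells propagate.
#'
#' @param raster an [eco_raster()].
#' @param f a vectorized function of cell values.
#' @param ... passed to `f`.
#' @return An `eco_raster` with transformed values.
#' @export
raster_map <- function(raster, f, ...) {
  out <- raster
  keep <- !is.na(raster$values)
  out$values[keep] <- f(raster$values[keep], ...)
  out
}

#' Plot a raster with ggplot2
#'
#' @param object an [eco_raster()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eco_raster <- function(object, ...) {
  df <- as_tibble.eco_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL)
}
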