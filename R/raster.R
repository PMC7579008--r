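#' Lightweight single-band georeferenced grid
#'
#' A `grid_raster` stores one band of values on a regular geographic grid:
#' a numeric matrix whose first row is the northernmost row, together with
#' the lower-left corner of the grid (`xll`, `yll`, degrees), the square
#' cell size in degrees, and a nodata convention. Nodata cells are held as
#' `NA` in memory and serialised as the `nodata` sentinel on disk
#' (ESRI ASCII grid format).
#'
#' @param values numeric matrix; row 1 is the northernmost row.
#' @param xll,yll longitude/latitude of the lower-left grid corner (degrees).
#' @param cellsize cell edge length in degrees (default 1/120, i.e. 30
#'   arc-seconds, about 1 km at the equator).
#' @param nodata sentinel written to disk for `NA` cells.
#' @param levels optional character vector naming integer categories for a
#'   categorical band.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll, yll, cellsize = 1 / 120,
                        nodata = -9999, levels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid_raster: values must have positive dimensions", call. = FALSE)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("grid_raster: cellsize must be > 0", call. = FALSE)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata, levels = levels),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, cellsize %.6g deg, origin (%.4f, %.4f)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  nodata cells: %d; value range: %s\n",
              sum(is.na(x$values)),
              paste(signif(range(x$values, na.rm = TRUE), 4), collapse = " .. ")))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Grid geometry shared by co-registered rasters
#'
#' @param x a `grid_raster` or a `raster_stack`.
#' @return list with `xll`, `yll`, `cellsize`, `nrow`, `ncol`.
#' @export
grid_spec <- function(x) {
  if (inherits(x, "raster_stack")) x <- x[[1L]]
  stopifnot(inherits(x, "grid_raster"))
  list(xll = x$xll, yll = x$yll, cellsize = x$cellsize,
       nrow = nrow(x$values), ncol = ncol(x$values))
}

#' Make a blank grid definition
#'
#' @param nrow,ncol grid dimensions.
#' @param xll,yll lower-left corner (degrees).
#' @param cellsize cell size in degrees.
#' @param fill initial cell value.
#' @return a `grid_raster` filled with `fill`.
#' @export
empty_grid <- function(nrow, ncol, xll = 0, yll = 0, cellsize = 1 / 120,
                       fill = NA_real_) {
  grid_raster(matrix(fill, nrow, ncol), xll = xll, yll = yll,
              cellsize = cellsize)
}

same_grid <- function(a, b, tol = 1e-9) {
  ga <- grid_spec(a); gb <- grid_spec(b)
  abs(ga$xll - gb$xll) < tol && abs(ga$yll - gb$yll) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol &&
    ga$nrow == gb$nrow && ga$ncol == gb$ncol
}

#' Assert that rasters share one grid definition
#'
#' @param ... named `grid_raster` objects (or one `raster_stack`).
#' @return invisibly TRUE; errors naming the offending raster otherwise.
#' @export
check_coregistered <- function(...) {
  rs <- list(...)
  if (length(rs) == 1L && inherits(rs[[1L]], "raster_stack")) rs <- unclass(rs[[1L]])
  if (length(rs) < 2L) return(invisible(TRUE))
  nms <- names(rs)
  if (is.null(nms)) nms <- paste0("raster", seq_along(rs))
  for (i in seq_along(rs)[-1L]) {
    if (!same_grid(rs[[1L]], rs[[i]]))
      stop(sprintf("rasters '%s' and '%s' are not co-registered (grid mismatch)",
                   nms[1L], nms[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Bundle co-registered single-band rasters
#'
#' @param ... named `grid_raster` layers, or a single named list of them.
#' @return a `raster_stack` (named list) after validating co-registration.
#' @export
raster_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) &&
      !inherits(layers[[1L]], "grid_raster"))
    layers <- layers[[1L]]
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("raster_stack: every layer must be named", call. = FALSE)
  for (nm in names(layers))
    if (!inherits(layers[[nm]], "grid_raster"))
      stop(sprintf("raster_stack: layer '%s' is not a grid_raster", nm),
           call. = FALSE)
  out <- structure(layers, class = "raster_stack")
  check_coregistered(out)
  out
}

#' Map point coordinates to grid cells
#'
#' Cell membership uses half-open intervals:
#' `col = floor((lon - xll)/cellsize) + 1`, rows analogous from the south
#' edge; points lying exactly on the northern or eastern grid boundary are
#' assigned to the last row/column.
#'
#' @param grid a `grid_raster` or grid spec list.
#' @param lon,lat point coordinates (degrees).
#' @return data.frame with `row` (1 = northernmost), `col`, and logical
#'   `inside`; `row`/`col` are `NA` for points outside the extent.
#' @export
cell_index <- function(grid, lon, lat) {
  g <- if (is.list(grid) && !inherits(grid, "grid_raster")) grid else grid_spec(grid)
  col <- floor((lon - g$xll) / g$cellsize) + 1
  rowb <- floor((lat - g$yll) / g$cellsize) + 1  # counted from the south edge
  # max-boundary points belong to the last cell
  on_e <- abs(lon - (g$xll + g$ncol * g$cellsize)) < 1e-12
  on_n <- abs(lat - (g$yll + g$nrow * g$cellsize)) < 1e-12
  col[on_e] <- g$ncol
  rowb[on_n] <- g$nrow
  inside <- col >= 1 & col <= g$ncol & rowb >= 1 & rowb <= g$nrow &
    is.finite(lon) & is.finite(lat)
  row <- g$nrow - rowb + 1
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Cell-center coordinates
#'
#' @param grid a `grid_raster` or grid spec list.
#' @param row,col cell indices (row 1 = northernmost).
#' @return data.frame with `lon`, `lat` of the cell centers.
#' @export
cell_center <- function(grid, row, col) {
  g <- if (is.list(grid) && !inherits(grid, "grid_raster")) grid else grid_spec(grid)
  data.frame(lon = g$xll + (col - 0.5) * g$cellsize,
             lat = g$yll + (g$nrow - row + 0.5) * g$cellsize)
}

#' Look up raster values at points
#'
#' @param raster a `grid_raster`.
#' @param lon,lat point coordinates.
#' @return numeric vector of cell values; `NA` for points outside the extent
#'   or hitting nodata.
#' @export
extract_at <- function(raster, lon, lat) {
  idx <- cell_index(raster, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- idx$inside
  out[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Write a grid as an ESRI ASCII grid (.asc)
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from
#' north to south.
#'
#' @param x a `grid_raster`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_ascii_grid <- function(x, path) {
  stopifnot(inherits(x, "grid_raster"))
  v <- x$values
  v[is.na(v)] <- x$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.12g", x$cellsize),
    sprintf("NODATA_value %.10g", x$nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return a `grid_raster`; nodata cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == vals[["nodata_value"]]] <- NA_real_
  grid_raster(v, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
              cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}
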