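#' Construct a GridLayer
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll lower-left corner of the extent (degrees, WGS84).
#' @param res cell size in decimal degrees.
#' @return A [GridLayer-class].
#' @export
gridLayer <- function(values, xll, yll, res) {
  new("GridLayer", values = values, xll = xll, yll = yll, res = res)
}

#' Construct an EnvStack from matrices sharing one grid
#'
#' @param layers named list of numeric matrices.
#' @param period period label.
#' @param xll,yll,res grid geometry (degrees).
#' @return An [EnvStack-class].
#' @export
envStack <- function(layers, period, xll, yll, res) {
  new("EnvStack", period = period, layers = layers, xll = xll, yll = yll,
      res = res)
}

#' @export
setMethod("dim", "GridLayer", function(x) dim(x@values))

#' @export
setMethod("dim", "EnvStack", function(x) dim(x@layers[[1L]]))

#' Grid geometry accessors
#'
#' `gridRes` returns the cell size in degrees; `gridOrigin` the lower-left
#' corner `c(xll, yll)`; `layerNames` the variable names of a stack;
#' `getLayer` one layer matrix; `stackPeriod` the period label.
#'
#' @param x a [GridLayer-class] or [EnvStack-class].
#' @param name layer name for `getLayer`.
#' @rdname grid-accessors
#' @export
gridRes <- function(x) x@res

#' @rdname grid-accessors
#' @export
gridOrigin <- function(x) c(x@xll, x@yll)

#' @rdname grid-accessors
#' @export
layerNames <- function(x) names(x@layers)

#' @rdname grid-accessors
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
}

#' @rdname grid-accessors
#' @export
stackPeriod <- function(x) x@period

setMethod("show", "GridLayer", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridLayer: %d x %d cells, %.4g deg, origin (%.4g, %.4g)\n",
              d[1L], d[2L], object@res, object@xll, object@yll))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(is.na(object@values))))
})

setMethod("show", "EnvStack", function(object) {
  d <- dim(object@layers[[1L]])
  cat(sprintf("EnvStack '%s': %d layer(s) [%s], %d x %d cells @ %.4g deg\n",
              object@period, length(object@layers),
              paste(names(object@layers), collapse = ", "),
              d[1L], d[2L], object@res))
})

## ---- cell arithmetic (shared by layers and stacks) ----

#' Map points to grid cells and back
#'
#' `cellIndex` returns the (row, col) of each lon/lat point under half-open
#' cell intervals, with NA for points outside the extent. `cellCenter`
#' returns the lon/lat of cell centers. `rowLat`/`colLon` give center
#' coordinates of whole rows/columns.
#'
#' @param x a [GridLayer-class] or [EnvStack-class] (anything with xll, yll,
#'   res and a grid dimension).
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @param row,col integer vectors of cell indices (row 1 = north).
#' @return `cellIndex`: a 2-column integer matrix (row, col);
#'   `cellCenter`: a 2-column numeric matrix (lon, lat).
#' @export
cellIndex <- function(x, lon, lat) {
  d <- dim(x)
  col <- floor((lon - x@xll) / x@res) + 1
  rowFromS <- floor((lat - x@yll) / x@res) + 1  # 1 = southernmost
  row <- d[1L] - rowFromS + 1
  bad <- col < 1 | col > d[2L] | row < 1 | row > d[1L] |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' @rdname cellIndex
#' @export
cellCenter <- function(x, row, col) {
  d <- dim(x)
  lon <- x@xll + (col - 0.5) * x@res
  lat <- x@yll + (d[1L] - row + 0.5) * x@res
  cbind(lon = lon, lat = lat)
}

#' @rdname cellIndex
#' @export
rowLat <- function(x, row) {
  d <- dim(x)
  x@yll + (d[1L] - row + 0.5) * x@res
}

#' @rdname cellIndex
#' @export
colLon <- function(x, col) x@xll + (col - 0.5) * x@res

sameGrid <- function(a, b, tol = 1e-9) {
  identical(dim(a), dim(b)) && abs(a@res - b@res) < tol &&
    abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol
}

## ---- ESRI ASCII grid I/O ----
## Plain-text single-band raster: 6 header lines then rows north->south.

#' Read and write ESRI ASCII grid rasters
#'
#' The package's native raster format is the plain-text ESRI ASCII grid
#' (`.asc`): a 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` whitespace-separated rows,
#' northernmost first.
#'
#' @param path file path.
#' @param x a [GridLayer-class] to write.
#' @param nodata nodata sentinel written in place of NA.
#' @return `readAsciiGrid` returns a [GridLayer-class].
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ascii grid header in ", path)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc) stop("grid body size mismatch in ", path)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  gridLayer(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
            res = vals[["cellsize"]])
}

#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  d <- dim(x@values)
  hdr <- c(paste("ncols", d[2L]), paste("nrows", d[1L]),
           paste("xllcorner", format(x@xll, digits = 15)),
           paste("yllcorner", format(x@yll, digits = 15)),
           paste("cellsize", format(x@res, digits = 15)),
           paste("NODATA_value", nodata))
  m <- x@values
  m[is.na(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(format(r, digits = 10, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
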