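## Geographic post-processing of predictions: land-class masking, dispersal
## buffers around the minimum convex polygon, and clipping maps to the
## accessible region.

#' Mask a suitability map to occupied land classes
#'
#' Cells whose land-cover class is not among the classes occupied by the
#' species (the classes observed at its occurrence records) are set to 0
#' (unsuitable). Records landing on nodata land cover are ignored for class
#' collection with a warning.
#'
#' @param suitability numeric matrix (suitability or binary map).
#' @param landcover integer matrix of land-cover classes, co-registered.
#' @param occupied_classes integer vector; if missing, derived from
#'   `records`.
#' @param records optional occurrence data.frame (lon/lat) used with `grid`
#'   to derive the occupied classes.
#' @param grid grid object ([GridLayer-class]/[EnvStack-class]) locating the
#'   records in the land-cover matrix.
#' @return masked matrix.
#' @export
landClassMask <- function(suitability, landcover, occupied_classes = NULL,
                          records = NULL, grid = NULL) {
  if (!identical(dim(suitability), dim(landcover)))
    stop("land cover is not co-registered with the suitability map")
  if (is.null(occupied_classes)) {
    if (is.null(records) || is.null(grid))
      stop("supply occupied_classes, or records plus grid to derive them")
    ci <- cellIndex(grid, records$lon, records$lat)
    ok <- !is.na(ci[, 1L])
    cls <- landcover[cbind(ci[ok, 1L], ci[ok, 2L])]
    if (anyNA(cls)) {
      warning(sum(is.na(cls)),
              " record(s) on nodata land cover ignored for class collection")
      cls <- cls[!is.na(cls)]
    }
    occupied_classes <- sort(unique(cls))
  }
  out <- suitability
  out[!is.na(landcover) & !(landcover %in% occupied_classes)] <- 0
  out
}

#' Dispersal distance accumulated since the present period
#'
#' Future accessibility grows linearly: the buffer distance is the species'
#' annual dispersal distance multiplied by the years elapsed from the
#' midpoint of the present climate period (1950-2000), taken as 1975.
#'
#' @param annual_km annual dispersal distance (km/year, > 0).
#' @param target_year projection year (e.g. 2055 for the 2050s).
#' @param present_year reference year (default 1975).
#' @return distance in km (0 with a warning when `target_year` is not after
#'   the reference).
#' @export
futureBufferDistance <- function(annual_km, target_year,
                                 present_year = 1975) {
  stopifnot(annual_km > 0)
  if (target_year <= present_year) {
    warning("target year not after the present reference (", present_year,
            "); buffer distance 0")
    return(0)
  }
  annual_km * (target_year - present_year)
}

#' Build the dispersal-buffered clip region for a species
#'
#' The accessible region is the minimum convex polygon of the occurrence
#' records buffered outward by a dispersal distance: for the current period
#' one year of dispersal (configurable multiplier), for a future period the
#' distance from [futureBufferDistance()]. Degenerate point/line record sets
#' are buffered by at least one grid cell.
#'
#' @param records occurrence data.frame (lon/lat).
#' @param buffer_km buffer distance in km.
#' @param min_buffer_km floor applied to degenerate (point/line) hulls.
#' @return a ring matrix (lon/lat) delimiting the clip region.
#' @export
clipRegion <- function(records, buffer_km, min_buffer_km = 2) {
  mcp <- minimumConvexPolygon(records$lon, records$lat)
  if (isTRUE(attr(mcp, "degenerate")))
    buffer_km <- max(buffer_km, min_buffer_km)
  if (buffer_km > 0) bufferKm(mcp, buffer_km) else mcp
}

#' Clip a map to a polygon
#'
#' Cells whose centers fall outside the polygon are set to `outside`
#' (0 for suitability/binary maps). An empty intersection yields an
#' all-`outside` map with a warning.
#'
#' @param map numeric matrix on a known grid.
#' @param grid grid object giving the map's geometry.
#' @param polygon clip polygon (ring matrix or multipart list).
#' @param outside value assigned outside the polygon (default 0).
#' @return clipped matrix.
#' @export
clipMap <- function(map, grid, polygon, outside = 0) {
  d <- dim(map)
  if (nrow(normPolygon(polygon)[[1L]][[1L]]) < 3L) {
    warning("degenerate clip polygon; all cells set outside")
    out <- map
    out[!is.na(out)] <- outside
    return(out)
  }
  lon <- colLon(grid, col(map))
  lat <- rowLat(grid, row(map))
  inside <- pointInPolygon(as.vector(lon), as.vector(lat), polygon)
  out <- map
  sel <- !inside & !is.na(as.vector(map))
  out[matrix(sel, d[1L], d[2L])] <- outside
  if (!any(inside))
    warning("clip polygon does not intersect the map extent")
  out
}

#' Threshold a suitability map into a binary range map
#'
#' @param suitability numeric matrix.
#' @param tau threshold from [threshold10ptp()].
#' @return integer matrix (1 presence, 0 absence, NA nodata).
#' @export
binarizeMap <- function(suitability, tau) {
  out <- ifelse(suitability >= tau, 1L, 0L)
  out[is.na(suitability)] <- NA_integer_
  out
}

#' Union binary maps of sub-populations
#'
#' Species modelled as separate sub-population record subsets are merged by
#' the cellwise union (max) of their binary outputs, producing the single
#' combined range map.
#'
#' @param maps list of binary matrices on one grid.
#' @return binary matrix.
#' @export
unionBinaryMaps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  d <- dim(maps[[1L]])
  for (m in maps) if (!identical(dim(m), d)) stop("grid mismatch in union")
  Reduce(function(a, b) {
    out <- pmax(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA_integer_
    out
  }, maps)
}

#' Read a dispersal table
#'
#' Expected header: `species,annual_km,provenance` with provenance in
#' observed/literature/group_average.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readDispersal <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "annual_km", "provenance")
  if (!all(need %in% names(x)))
    stop("dispersal CSV must have columns ", paste(need, collapse = ", "))
  if (any(x$annual_km <= 0)) stop("annual dispersal distances must be > 0")
  x
}
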