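## Occurrence quality control: taxonomy resolution, range-polygon screening,
## spatial-resolution filtering, period assignment and grid deduplication.
## Records travel as a data.frame with columns
##   species, lon, lat, year, precision_km, source
## (the on-disk CSV uses the same header). Each filter attaches a `qc`
## attribute accumulating counts of dropped records per step.

qcNote <- function(records, step, dropped) {
  qc <- attr(records, "qc")
  if (is.null(qc)) qc <- data.frame(step = character(), dropped = integer())
  attr(records, "qc") <- rbind(qc, data.frame(step = step,
                                              dropped = as.integer(dropped)))
  records
}

#' Read and write occurrence CSV files
#'
#' Occurrence CSVs carry the header
#' `species,lon,lat,year,precision_km,source`. Missing years/precisions are
#' empty fields (read as NA).
#'
#' @param path CSV file.
#' @param records occurrence data.frame.
#' @return `readOccurrences` returns a data.frame.
#' @export
readOccurrences <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "year", "precision_km", "source")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("occurrence CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- x$lon < -180 | x$lon > 180 | x$lat < -90 | x$lat > 90
  if (any(bad, na.rm = TRUE)) stop("coordinates outside WGS84 bounds")
  x
}

#' @rdname readOccurrences
#' @export
writeOccurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve record names against an accepted taxonomy
#'
#' Records whose name is already accepted are retained; names present in the
#' synonym map are remapped to their accepted name; anything else is dropped
#' and counted.
#'
#' @param records occurrence data.frame.
#' @param accepted_names character vector of accepted species names.
#' @param synonym_map named character vector: synonym -> accepted name.
#' @return filtered data.frame (with a `qc` attribute of drop counts).
#' @export
resolveTaxonomy <- function(records, accepted_names,
                            synonym_map = character()) {
  if (length(accepted_names) == 0L)
    stop("accepted_names must not be empty")
  if (length(synonym_map) &&
      !all(synonym_map %in% accepted_names))
    stop("synonym_map values must all be accepted names")
  nm <- records$species
  is_syn <- nm %in% names(synonym_map)
  nm[is_syn] <- unname(synonym_map[nm[is_syn]])
  keep <- nm %in% accepted_names
  out <- records[keep, , drop = FALSE]
  out$species <- nm[keep]
  rownames(out) <- NULL
  qcNote(out, "taxonomy", sum(!keep))
}

#' Screen records against a species range polygon
#'
#' Keeps records inside the polygon or within `tolerance_km` (geodesic) of
#' its boundary; anything farther is treated as spatially erroneous.
#'
#' @param records occurrence data.frame (one species).
#' @param polygon range polygon (ring matrix, list of rings, or multipart).
#' @param tolerance_km allowed geodesic distance outside the boundary (km).
#' @return filtered data.frame.
#' @export
filterByRangePolygon <- function(records, polygon, tolerance_km = 0) {
  polygon <- validatePolygon(polygon)
  if (nrow(records) == 0L) return(qcNote(records, "range_polygon", 0L))
  d <- distanceToPolygonKm(records$lon, records$lat, polygon)
  keep <- d <= tolerance_km
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  qcNote(out, "range_polygon", sum(!keep))
}

#' Drop coarse-resolution records
#'
#' Records whose stated coordinate precision exceeds `max_precision_km` are
#' removed (the boundary itself is kept). Records with missing precision are
#' dropped by default; set `keep_missing = TRUE` to retain them.
#'
#' @param records occurrence data.frame.
#' @param max_precision_km inclusive precision cut in km (default 2).
#' @param keep_missing retain records with NA precision?
#' @return filtered data.frame.
#' @export
filterResolution <- function(records, max_precision_km = 2,
                             keep_missing = FALSE) {
  stopifnot(max_precision_km > 0)
  p <- records$precision_km
  keep <- ifelse(is.na(p), keep_missing, p <= max_precision_km)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  qcNote(out, "resolution", sum(!keep))
}

#' Assign temporal periods to records
#'
#' Records with year before the cutoff are tagged `pre1950`, those at or
#' after it `post1950`. Records with missing year are dropped by default, or
#' assigned `post1950` when `missing_year = "post1950"`.
#'
#' @param records occurrence data.frame.
#' @param cutoff_year period split (default 1950).
#' @param missing_year "drop" or "post1950".
#' @return data.frame with a `period` column added.
#' @export
assignPeriod <- function(records, cutoff_year = 1950,
                         missing_year = c("drop", "post1950")) {
  missing_year <- match.arg(missing_year)
  y <- records$year
  period <- ifelse(is.na(y), NA_character_,
                   ifelse(y < cutoff_year, "pre1950", "post1950"))
  if (missing_year == "post1950") period[is.na(period)] <- "post1950"
  keep <- !is.na(period)
  out <- records[keep, , drop = FALSE]
  out$period <- period[keep]
  rownames(out) <- NULL
  qcNote(out, "period", sum(!keep))
}

#' Eliminate duplicate records within grid cells
#'
#' A duplicate is a second record of the same species in the same raster
#' cell and the same temporal period; records of the same cell in different
#' periods are all retained. Within a duplicate group the earliest-year
#' record wins, ties broken by lexicographic source, so output is
#' deterministic and order-independent.
#'
#' @param records period-tagged occurrence data.frame.
#' @param grid a [GridLayer-class] or [EnvStack-class] defining cells; or a
#'   single numeric cell size in degrees (grid snapped to the origin).
#' @return deduplicated data.frame.
#' @export
deduplicate <- function(records, grid) {
  if (is.null(records$period)) stop("records must carry periods; run ",
                                    "assignPeriod() first")
  if (nrow(records) == 0L) return(qcNote(records, "duplicates", 0L))
  if (is.numeric(grid) && length(grid) == 1L) {
    cr <- floor(records$lat / grid)
    cc <- floor(records$lon / grid)
  } else {
    ci <- cellIndex(grid, records$lon, records$lat)
    cr <- ci[, 1L]; cc <- ci[, 2L]
  }
  key <- paste(records$species, cr, cc, records$period, sep = "\r")
  yr <- ifelse(is.na(records$year), Inf, records$year)
  src <- ifelse(is.na(records$source), "", records$source)
  ord <- order(key, yr, src)
  keep_first <- !duplicated(key[ord])
  keep <- sort(ord[keep_first])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  qcNote(out, "duplicates", nrow(records) - length(keep))
}

#' Run the full occurrence QC chain for one species
#'
#' Applies taxonomy resolution, range-polygon screening, the resolution cut,
#' period assignment and grid deduplication in order, and returns the
#' cleaned records together with the per-step drop counts.
#'
#' @param records raw occurrence data.frame for one species (synonyms
#'   allowed).
#' @param accepted_names,synonym_map see [resolveTaxonomy()].
#' @param polygon optional range polygon; skipped when NULL.
#' @param grid grid (or cell size in degrees) for deduplication.
#' @param max_precision_km resolution cut (km).
#' @param tolerance_km range-polygon tolerance (km).
#' @param cutoff_year period split.
#' @return list with elements `records` (clean data.frame) and `report`
#'   (data.frame step/dropped).
#' @export
qcSpecies <- function(records, accepted_names, synonym_map = character(),
                      polygon = NULL, grid = 0.1, max_precision_km = 2,
                      tolerance_km = 0, cutoff_year = 1950) {
  x <- resolveTaxonomy(records, accepted_names, synonym_map)
  if (!is.null(polygon)) x <- filterByRangePolygon(x, polygon, tolerance_km)
  x <- filterResolution(x, max_precision_km)
  x <- assignPeriod(x, cutoff_year)
  x <- deduplicate(x, grid)
  list(records = x, report = attr(x, "qc"))
}

#' Period counts of a cleaned dataset
#'
#' @param records period-tagged data.frame.
#' @return named integer vector `c(pre1950 = , post1950 = )`.
#' @export
periodCounts <- function(records) {
  c(pre1950 = sum(records$period == "pre1950"),
    post1950 = sum(records$period == "post1950"))
}
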