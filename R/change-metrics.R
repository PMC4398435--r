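## Per-period range metrics and between-period change summaries. Cell areas
## use the spherical formula per latitude band (area of a res x res cell at
## latitude phi ~ R^2 * res_rad^2 * cos(phi)), accurate to well under 0.5%
## of the spheroidal value at these resolutions.

cellAreaKm2 <- function(lat, res) {
  res_rad <- res * pi / 180
  EARTH_RADIUS_KM^2 * res_rad * cos(lat * pi / 180) *
    (2 * sin(res_rad / 2))
}

#' Range size, mean latitude and elevation statistics of a binary map
#'
#' Area sums latitude-corrected cell areas over presence cells; mean
#' latitude is the area-weighted mean of presence-cell latitudes; elevation
#' statistics (min/mean/max) are taken over presence cells of the
#' co-registered elevation raster. With zero presence cells the species is
#' flagged extinct in that scenario and the metrics are NA.
#'
#' @param binary integer matrix (1/0/NA) on a known grid.
#' @param grid grid object for the map.
#' @param elevation optional co-registered elevation matrix (m).
#' @param period period label carried through.
#' @return one-row data.frame: period, n_cells, area_km2, mean_latitude,
#'   min_elev, mean_elev, max_elev, extinct.
#' @export
rangeMetrics <- function(binary, grid, elevation = NULL, period = NA) {
  if (!is.null(elevation) && !identical(dim(elevation), dim(binary)))
    stop("elevation raster is not co-registered with the range map")
  pres <- which(binary == 1L)
  if (length(pres) == 0L)
    return(data.frame(period = period, n_cells = 0L, area_km2 = 0,
                      mean_latitude = NA_real_, min_elev = NA_real_,
                      mean_elev = NA_real_, max_elev = NA_real_,
                      extinct = TRUE))
  lat <- rowLat(grid, row(binary))[pres]
  a <- cellAreaKm2(lat, gridRes(grid))
  out <- data.frame(period = period, n_cells = length(pres),
                    area_km2 = sum(a),
                    mean_latitude = sum(a * lat) / sum(a),
                    min_elev = NA_real_, mean_elev = NA_real_,
                    max_elev = NA_real_, extinct = FALSE)
  if (!is.null(elevation)) {
    e <- elevation[pres]
    e <- e[!is.na(e)]
    if (length(e)) {
      out$min_elev <- min(e); out$mean_elev <- mean(e); out$max_elev <- max(e)
    }
  }
  out
}

#' Between-period change summary for one species
#'
#' Range change is the percentage change in area; poleward movement is the
#' mean-latitude difference signed so that movement toward the species'
#' pole is positive (hemisphere "N": north positive, "S": south positive);
#' elevational changes are plain differences in metres. A species with no
#' presence cells in the later period is the extinction case: range change
#' -100%, latitude/elevation changes undefined.
#'
#' @param metrics_t0,metrics_t1 rows from [rangeMetrics()].
#' @param hemisphere "N" or "S"; if missing, taken from the sign of the
#'   earlier period's mean latitude (flagged).
#' @return one-row data.frame: range_change_pct, poleward_deg,
#'   min_elev_change_m, mean_elev_change_m, max_elev_change_m, extinct,
#'   hemisphere.
#' @export
changeSummary <- function(metrics_t0, metrics_t1, hemisphere = NULL) {
  if (metrics_t0$extinct)
    stop("baseline period has no presence cells; change undefined")
  if (is.null(hemisphere)) {
    hemisphere <- if (metrics_t0$mean_latitude >= 0) "N" else "S"
    warning("hemisphere not supplied; inferred '", hemisphere,
            "' from the baseline mean latitude")
  }
  hemisphere <- match.arg(hemisphere, c("N", "S"))
  if (metrics_t1$extinct)
    return(data.frame(range_change_pct = -100, poleward_deg = NA_real_,
                      min_elev_change_m = NA_real_,
                      mean_elev_change_m = NA_real_,
                      max_elev_change_m = NA_real_, extinct = TRUE,
                      hemisphere = hemisphere))
  sgn <- if (hemisphere == "N") 1 else -1
  data.frame(
    range_change_pct = 100 * (metrics_t1$area_km2 - metrics_t0$area_km2) /
      metrics_t0$area_km2,
    poleward_deg = sgn * (metrics_t1$mean_latitude -
                            metrics_t0$mean_latitude),
    min_elev_change_m = metrics_t1$min_elev - metrics_t0$min_elev,
    mean_elev_change_m = metrics_t1$mean_elev - metrics_t0$mean_elev,
    max_elev_change_m = metrics_t1$max_elev - metrics_t0$max_elev,
    extinct = FALSE, hemisphere = hemisphere)
}

#' Species richness raster and richness change
#'
#' `richnessMap` sums the binary maps cellwise (NA in every map keeps NA);
#' `richnessChange` subtracts a past richness raster from a future one and
#' can mask as uncertain (NA) the cells occupied only by species excluded
#' from modelling.
#'
#' @param maps list of binary matrices (one per species) on one grid.
#' @param past,future richness matrices.
#' @param uncertain_mask optional logical matrix; TRUE cells are masked NA
#'   in the change raster (areas occupied only by unmodellable species).
#' @return integer matrix.
#' @export
richnessMap <- function(maps) {
  stopifnot(length(maps) >= 1L)
  d <- dim(maps[[1L]])
  for (m in maps) if (!identical(dim(m), d))
    stop("grid mismatch between species maps")
  allNA <- Reduce(`&`, lapply(maps, is.na))
  out <- Reduce(`+`, lapply(maps, function(m) {
    m[is.na(m)] <- 0L
    m
  }))
  out[allNA] <- NA_integer_
  out
}

#' @rdname richnessMap
#' @export
richnessChange <- function(past, future, uncertain_mask = NULL) {
  if (!identical(dim(past), dim(future))) stop("grid mismatch")
  out <- future - past
  if (!is.null(uncertain_mask)) out[uncertain_mask] <- NA_integer_
  out
}
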