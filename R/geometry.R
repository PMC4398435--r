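## Vector geometry on WGS84: polygons are lists of rings, each ring a
## 2-column (lon, lat) matrix, exterior ring first, unclosed (first vertex
## not repeated). A multipolygon is a list of such polygons.

EARTH_RADIUS_KM <- 6371.0088  # mean Earth radius

#' Read range polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features and
#' returns a named list of polygons keyed by the given property (default
#' `species`). Each polygon is a list of rings; each ring a 2-column
#' lon/lat matrix.
#'
#' @param path GeoJSON file.
#' @param key feature property used as the name.
#' @return named list; each element a list of polygon parts, each part a
#'   list of ring matrices.
#' @export
readRangePolygons <- function(path, key = "species") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  ring_mat <- function(r)
    do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
  for (f in gj$features) {
    nm <- as.character(f$properties[[key]])
    g <- f$geometry
    parts <- switch(g$type,
      Polygon = list(lapply(g$coordinates, ring_mat)),
      MultiPolygon = lapply(g$coordinates,
                            function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", g$type))
    # drop closing vertex if rings are closed
    parts <- lapply(parts, function(p) lapply(p, function(m) {
      n <- nrow(m)
      if (n > 1L && all(m[1L, ] == m[n, ])) m[-n, , drop = FALSE] else m
    }))
    out[[nm]] <- parts
  }
  out
}

#' Write a polygon to GeoJSON
#'
#' @param parts polygon parts as returned by [readRangePolygons()] (a single
#'   polygon: list of parts, each a list of ring matrices). A bare ring
#'   matrix or list of rings is promoted.
#' @param path output file.
#' @param properties named list written as the feature's properties.
#' @export
writeGeoJSONPolygon <- function(parts, path, properties = list()) {
  parts <- normPolygon(parts)
  close_ring <- function(m) rbind(m, m[1L, , drop = FALSE])
  coords <- lapply(parts, function(p) lapply(p, function(m) {
    m <- close_ring(m)
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1L], m[i, 2L]))
  }))
  geom <- if (length(coords) == 1L)
    list(type = "Polygon", coordinates = coords[[1L]])
  else list(type = "MultiPolygon", coordinates = coords)
  gj <- list(type = "FeatureCollection",
             features = list(list(type = "Feature",
                                  properties = properties,
                                  geometry = geom)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Promote a ring matrix or list of rings to the canonical multipart form:
# list(parts), part = list(rings), ring = matrix.
normPolygon <- function(poly) {
  if (is.matrix(poly)) return(list(list(poly)))
  if (is.list(poly) && is.matrix(poly[[1L]])) return(list(poly))
  poly
}

validatePolygon <- function(poly) {
  poly <- normPolygon(poly)
  for (part in poly) for (ring in part) {
    if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L)
      stop("invalid polygon: rings need >= 3 lon/lat vertices")
    if (any(!is.finite(ring))) stop("invalid polygon: non-finite vertex")
    if (selfIntersects(ring)) stop("invalid polygon: self-intersecting ring")
  }
  poly
}

# O(n^2) proper segment intersection test, adequate for QC-sized rings.
selfIntersects <- function(ring) {
  n <- nrow(ring)
  seg <- cbind(ring, ring[c(2:n, 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorized over points; holes (interior rings) and multipart polygons are
#' handled by the even-odd rule. Points exactly on a boundary edge count as
#' inside.
#'
#' @param lon,lat numeric vectors.
#' @param poly polygon (ring matrix, list of rings, or multipart list).
#' @return logical vector.
#' @export
pointInPolygon <- function(lon, lat, poly) {
  poly <- normPolygon(poly)
  inside <- rep(FALSE, length(lon))
  onEdge <- rep(FALSE, length(lon))
  eps <- 1e-12
  for (part in poly) for (ring in part) {
    n <- nrow(ring)
    x1 <- ring[, 1L]; y1 <- ring[, 2L]
    x2 <- ring[c(2:n, 1L), 1L]; y2 <- ring[c(2:n, 1L), 2L]
    for (e in seq_len(n)) {
      xa <- x1[e]; ya <- y1[e]; xb <- x2[e]; yb <- y2[e]
      crosses <- ((ya > lat) != (yb > lat)) &
        (lon < (xb - xa) * (lat - ya) / (yb - ya) + xa)
      inside <- xor(inside, crosses & !is.na(crosses))
      # collinear-and-within-bbox => on the edge
      d <- abs((xb - xa) * (lat - ya) - (yb - ya) * (lon - xa))
      onEdge <- onEdge | (d < eps &
        lon >= pmin(xa, xb) - eps & lon <= pmax(xa, xb) + eps &
        lat >= pmin(ya, yb) - eps & lat <= pmax(ya, yb) + eps)
    }
  }
  inside | onEdge
}

#' Geodesic distance from points to a polygon boundary
#'
#' Great-circle distance (km) from each point to the nearest boundary vertex
#' or edge of the polygon; 0 for points inside.
#'
#' @inheritParams pointInPolygon
#' @return numeric vector of distances in km.
#' @export
distanceToPolygonKm <- function(lon, lat, poly) {
  poly <- normPolygon(poly)
  inside <- pointInPolygon(lon, lat, poly)
  out <- numeric(length(lon))
  segs <- do.call(rbind, lapply(poly, function(part)
    do.call(rbind, lapply(part, function(ring)
      rbind(ring, ring[1L, , drop = FALSE])))))
  idx <- which(!inside)
  if (length(idx)) {
    d <- geosphere::dist2Line(cbind(lon[idx], lat[idx]), segs)
    out[idx] <- d[, 1L] / 1000
  }
  out
}

#' Minimum convex polygon of occurrence points
#'
#' Convex hull of the points in lon/lat. With fewer than three distinct
#' non-collinear points the hull is degenerate; the point/line is returned
#' with a `degenerate` attribute so callers can buffer it by at least one
#' cell.
#'
#' @param lon,lat numeric vectors (degrees).
#' @return a ring matrix (counter-clockwise) with attribute `degenerate`
#'   (TRUE/FALSE).
#' @export
minimumConvexPolygon <- function(lon, lat) {
  pts <- unique(cbind(lon = lon, lat = lat))
  if (nrow(pts) < 3L) {
    attr(pts, "degenerate") <- TRUE
    return(pts)
  }
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  ring <- pts[rev(h), , drop = FALSE]  # chull is clockwise; reverse to CCW
  degen <- nrow(ring) < 3L
  attr(ring, "degenerate") <- degen
  ring
}

## ---- azimuthal equidistant projection (spherical) ----

aeqdForward <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c <- acos(cosc)
  k <- ifelse(c < 1e-12, 1, c / sin(c))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

aeqdInverse <- function(x, y, lon0, lat0) {
  rad <- pi / 180
  phi0 <- lat0 * rad; lam0 <- lon0 * rad
  rho <- sqrt(x^2 + y^2)
  c <- rho / EARTH_RADIUS_KM
  sinc <- sin(c); cosc <- cos(c)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  cbind(lon = lam / rad, lat = phi / rad)
}

#' Buffer a (convex) polygon or point set outward by a distance in km
#'
#' The geometry is projected to an azimuthal equidistant projection centered
#' on its centroid, dilated by the Minkowski sum with a disc (the disc
#' approximated by a regular polygon of `n_arc` vertices), and reprojected.
#' For convex input (the minimum convex polygon case) the result is exact up
#' to disc discretization; concave input is convexified.
#'
#' @param ring a 2-column lon/lat matrix (>= 1 vertex; degenerate point/line
#'   inputs are buffered into discs/capsules).
#' @param km buffer distance in km (>= 0). `km = 0` returns the input.
#' @param n_arc vertices used to approximate the disc (default 72: area
#'   within 0.15 percent of the true disc).
#' @return a ring matrix (lon, lat).
#' @export
bufferKm <- function(ring, km, n_arc = 72L) {
  stopifnot(is.matrix(ring), ncol(ring) == 2L, km >= 0)
  if (km == 0) return(ring)
  lon0 <- mean(ring[, 1L]); lat0 <- mean(ring[, 2L])
  xy <- aeqdForward(ring[, 1L], ring[, 2L], lon0, lat0)
  if (any(abs(ring[, 1L] - lon0) > 90))
    stop("buffer would span more than a hemisphere (antimeridian handling ",
         "not supported); split the geometry first")
  theta <- seq(0, 2 * pi, length.out = n_arc + 1L)[-(n_arc + 1L)]
  circ <- cbind(km * cos(theta), km * sin(theta))
  pts <- do.call(rbind, lapply(seq_len(nrow(xy)), function(i)
    cbind(xy[i, 1L] + circ[, 1L], xy[i, 2L] + circ[, 2L])))
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull <- pts[rev(h), , drop = FALSE]
  out <- aeqdInverse(hull[, 1L], hull[, 2L], lon0, lat0)
  colnames(out) <- c("lon", "lat")
  out
}

#' Geodesic polygon area in km^2
#'
#' @param ring 2-column lon/lat ring matrix (unclosed).
#' @return area in km^2.
#' @export
polygonAreaKm2 <- function(ring) {
  abs(geosphere::areaPolygon(ring)) / 1e6
}

#' Haversine great-circle distance in km
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorized).
#' @return distance in km.
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}
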