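test_that("land-class masking zeroes exactly the unoccupied classes", {
  suit <- matrix(runif(16), 4, 4)
  lc <- matrix(rep(1:4, each = 4), 4, 4)
  expect_equal(landClassMask(suit, lc, occupied_classes = 1:4), suit)
  none <- landClassMask(suit, lc, occupied_classes = integer())
  expect_true(all(none == 0))
  two <- landClassMask(suit, lc, occupied_classes = c(2L, 4L))
  for (i in 1:4) for (j in 1:4)
    expect_equal(two[i, j], if (lc[i, j] %in% c(2, 4)) suit[i, j] else 0)
  expect_error(landClassMask(suit, lc[1:2, ], 1L), "co-registered")
})

test_that("occupied classes are derived from records, warning on nodata cover", {
  g <- tinyStacks()$post1950
  lc <- matrix(1L, 10, 10); lc[, 6:10] <- 2L
  lc[1, 1] <- NA
  cc <- rbind(cellCenter(g, 1, 1), cellCenter(g, 3, 3))
  recs <- data.frame(lon = cc[, 1], lat = cc[, 2])
  suit <- matrix(1, 10, 10)
  expect_warning(out <- landClassMask(suit, lc, records = recs, grid = g),
                 "nodata")
  expect_equal(out[2, 2], 1)   # class 1 occupied
  expect_equal(out[2, 8], 0)   # class 2 never occupied
})

test_that("minimum convex polygons match a brute-force hull", {
  tri <- minimumConvexPolygon(c(0, 2, 1), c(0, 0, 2))
  expect_equal(nrow(tri), 3L)
  expect_false(attr(tri, "degenerate"))
  sq <- minimumConvexPolygon(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  expect_equal(nrow(sq), 4L)  # interior point excluded
  set.seed(41)
  for (i in 1:5) {
    pts <- cbind(runif(50), runif(50))
    h <- minimumConvexPolygon(pts[, 1], pts[, 2])
    bh <- bruteHull(pts)
    expect_setequal(paste(h[, 1], h[, 2]), paste(bh[, 1], bh[, 2]))
  }
  pt <- minimumConvexPolygon(1, 1)
  expect_true(attr(pt, "degenerate"))
})

test_that("km buffering produces geodesic discs and nested regions", {
  ring <- matrix(c(12, 47), 1, 2)
  expect_identical(bufferKm(ring, 0), ring)
  disc <- bufferKm(ring, 10)
  expect_equal(polygonAreaKm2(disc), pi * 100, tolerance = 0.01)
  # every vertex ~10 km from the center (haversine oracle)
  d <- haversineKm(12, 47, disc[, 1], disc[, 2])
  expect_true(all(abs(d - 10) < 0.05))
  tri <- matrix(c(10, 40, 10.5, 40, 10.2, 40.4), ncol = 2, byrow = TRUE)
  b5 <- bufferKm(tri, 5); b10 <- bufferKm(tri, 10)
  expect_true(all(pointInPolygon(b5[, 1], b5[, 2], b10)))
  expect_true(all(pointInPolygon(tri[, 1], tri[, 2], b5)))
})

test_that("future buffer distance is dispersal times years since 1975", {
  expect_equal(futureBufferDistance(0.5, 2055), 40)
  expect_equal(futureBufferDistance(1, 2025), 50)
  expect_warning(d <- futureBufferDistance(2, 1975), "not after")
  expect_equal(d, 0)
})

test_that("clipping keeps exactly the cell centers inside the polygon", {
  g <- tinyStacks()$post1950
  m <- matrix(1L, 10, 10)
  full <- matrix(c(-1, -1, 6, -1, 6, 6, -1, 6), ncol = 2, byrow = TRUE)
  expect_equal(clipMap(m, g, full), m)
  # half-plane: lon < 2.5 (cols 1..5 at 0.5 deg resolution)
  half <- matrix(c(-1, -1, 2.5, -1, 2.5, 6, -1, 6), ncol = 2, byrow = TRUE)
  cl <- clipMap(m, g, half)
  for (i in 1:10) for (j in 1:10) {
    inside <- pointInPolygon(colLon(g, j), rowLat(g, i), half)
    expect_equal(cl[i, j], if (inside) 1L else 0L)
  }
  # clipping never adds presences
  set.seed(42)
  mm <- matrix(rbinom(100, 1, 0.5), 10, 10)
  cl2 <- clipMap(mm, g, half)
  expect_true(all(cl2 <= mm))
  away <- matrix(c(50, 50, 51, 50, 51, 51), ncol = 2, byrow = TRUE)
  expect_warning(out <- clipMap(m, g, away), "does not intersect")
  expect_true(all(out == 0))
})

test_that("future clip regions are nested over scenario horizons", {
  set.seed(43)
  recs <- data.frame(lon = runif(30, 5, 6), lat = runif(30, 45, 46))
  r20 <- clipRegion(recs, futureBufferDistance(0.8, 2025))
  r50 <- clipRegion(recs, futureBufferDistance(0.8, 2055))
  r80 <- clipRegion(recs, futureBufferDistance(0.8, 2085))
  expect_true(all(pointInPolygon(r20[, 1], r20[, 2], r50)))
  expect_true(all(pointInPolygon(r50[, 1], r50[, 2], r80)))
})

test_that("sub-population binary maps merge by cellwise union", {
  a <- matrix(c(1L, 0L, NA, 0L), 2, 2)
  b <- matrix(c(0L, 0L, NA, 1L), 2, 2)
  u <- unionBinaryMaps(list(a, b))
  expect_equal(u, matrix(c(1L, 0L, NA, 1L), 2, 2))
  expect_error(unionBinaryMaps(list(a, matrix(0L, 3, 3))), "mismatch")
})

test_that("range polygons round-trip through GeoJSON", {
  ring <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), ncol = 2, byrow = TRUE)
  f <- tempfile(fileext = ".geojson")
  writeGeoJSONPolygon(ring, f, properties = list(species = "spA"))
  back <- readRangePolygons(f)
  expect_equal(names(back), "spA")
  expect_equal(back$spA[[1]][[1]], ring)
})
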