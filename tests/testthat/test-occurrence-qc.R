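test_that("taxonomy resolution keeps accepted names, remaps synonyms, drops the rest", {
  r <- rbind(rec(1, 1, species = "Lepus alpha"),
             rec(2, 2, species = "Lepus beta_old"),
             rec(3, 3, species = "Unknown gamma"))
  out <- resolveTaxonomy(r, accepted_names = c("Lepus alpha", "Lepus beta"),
                         synonym_map = c("Lepus beta_old" = "Lepus beta"))
  expect_equal(out$species, c("Lepus alpha", "Lepus beta"))
  expect_equal(attr(out, "qc")$dropped, 1L)
  expect_error(resolveTaxonomy(r, character()), "empty")
  expect_error(resolveTaxonomy(r, "Lepus alpha",
                               c("x" = "Lepus nonexistent")), "accepted")
})

test_that("range-polygon screen respects geodesic tolerance", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  inside <- rec(0.5, 0.5)
  far <- rec(6, 0.5)        # ~ 500 km east of the boundary
  expect_equal(nrow(filterByRangePolygon(inside, sq, 0)), 1L)
  expect_equal(nrow(filterByRangePolygon(far, sq, 0)), 0L)
  # a point ~5 km outside the eastern edge: shift longitude by
  # 5 km / (111.32 cos(lat)) degrees, verified with the haversine oracle
  dlon <- 5 / (111.32 * cos(0.5 * pi / 180))
  near <- rec(1 + dlon, 0.5)
  d_oracle <- haversineKm(1, 0.5, 1 + dlon, 0.5)
  expect_lt(abs(d_oracle - 5), 0.05)
  expect_equal(nrow(filterByRangePolygon(near, sq, tolerance_km = 10)), 1L)
  expect_equal(nrow(filterByRangePolygon(near, sq, tolerance_km = 1)), 0L)
  bowtie <- matrix(c(0, 0, 1, 1, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(filterByRangePolygon(inside, bowtie), "self-intersecting")
})

test_that("resolution filter is inclusive at the cut and configurable for missing", {
  r <- rbind(rec(1, 1, precision = 1), rec(2, 2, precision = 2.5),
             rec(3, 3, precision = 2), rec(4, 4, precision = NA))
  out <- filterResolution(r)
  expect_equal(out$precision_km, c(1, 2))
  out2 <- filterResolution(r, keep_missing = TRUE)
  expect_equal(nrow(out2), 3L)
})

test_that("period assignment splits at the cutoff year", {
  r <- rbind(rec(1, 1, year = 1949), rec(2, 2, year = 1950),
             rec(3, 3, year = 2000), rec(4, 4, year = NA))
  out <- assignPeriod(r)
  expect_equal(out$period, c("pre1950", "post1950", "post1950"))
  out2 <- assignPeriod(r, missing_year = "post1950")
  expect_equal(out2$period[4], "post1950")
})

test_that("deduplication keeps one record per cell and period, earliest year first", {
  r <- assignPeriod(rbind(
    rec(0.51, 0.52, year = 1980, source = "b"),
    rec(0.53, 0.58, year = 1960, source = "a"),   # same 0.1-deg cell
    rec(0.51, 0.52, year = 1930),                  # same cell, pre1950
    rec(0.72, 0.52, year = 1980)))                 # adjacent cell
  out <- deduplicate(r, 0.1)
  expect_equal(nrow(out), 3L)
  kept_post <- out[out$period == "post1950" & out$lon < 0.6, ]
  expect_equal(kept_post$year, 1960)  # earliest year wins
})

test_that("deduplication matches a set-based oracle and the chain is idempotent", {
  set.seed(7)
  for (i in 1:5) {
    n <- 60
    r <- rec(runif(n, 0, 1), runif(n, 0, 1),
             year = sample(c(1900:1949, 1950:2000), n, replace = TRUE),
             precision = runif(n, 0.5, 4))
    r <- assignPeriod(r)
    out <- deduplicate(r, 0.25)
    key <- paste(floor(r$lat / 0.25), floor(r$lon / 0.25), r$period)
    expect_equal(nrow(out), length(unique(key)))
    # idempotence and no fabrication
    again <- deduplicate(out, 0.25)
    expect_equal(nrow(again), nrow(out))
    expect_true(all(paste(out$lon, out$lat, out$year) %in%
                      paste(r$lon, r$lat, r$year)))
  }
})

test_that("the full QC chain reports per-step drops and round-trips via CSV", {
  r <- rbind(rec(0.5, 0.5, year = 1980, precision = 1),
             rec(0.5, 0.5, year = 1981, precision = 1),
             rec(0.2, 0.2, year = 1930, precision = 5),
             rec(0.8, 0.8, year = NA, precision = 1),
             rec(0.3, 0.3, year = 1990, precision = 1,
                 species = "nobody"))
  res <- qcSpecies(r, accepted_names = "spA", grid = 0.5)
  expect_equal(sum(res$report$dropped), 4L)
  expect_equal(nrow(res$records), 1L)
  expect_setequal(res$report$step,
                  c("taxonomy", "resolution", "period", "duplicates"))
  f <- tempfile(fileext = ".csv")
  writeOccurrences(res$records, f)
  back <- readOccurrences(f)
  expect_equal(back$lon, res$records$lon)
  expect_equal(unname(periodCounts(res$records)), c(0L, 1L))
})
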