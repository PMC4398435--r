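# Shared in-code fixtures. Everything is generated at test time; the only
# state is a lazily built small world reused by the slower tests.

# tiny two-period stack pair on a 10 x 10 grid at 0.5 degree
tinyStacks <- function(base = 10) {
  m1 <- matrix(base + seq_len(100) / 10, 10, 10)        # varies by cell
  m2 <- matrix(rev(seq_len(100)) / 25, 10, 10)
  cur <- envStack(list(temp = m1, prec = m2), "current1950_2000",
                  xll = 0, yll = 0, res = 0.5)
  past <- envStack(list(temp = m1 - 1, prec = m2 + 2), "past1900_1949",
                   xll = 0, yll = 0, res = 0.5)
  list(pre1950 = past, post1950 = cur)
}

# occurrence table builder
rec <- function(lon, lat, year = 2000, species = "spA", precision = 1,
                source = "t") {
  data.frame(species = species, lon = lon, lat = lat, year = year,
             precision_km = precision, source = source)
}

# brute-force O(n^3) convex hull: a point is a hull vertex iff it is an
# endpoint of an edge with all other points on one side
bruteHull <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- sign((pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
                (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1]))
    s <- s[-c(i, j)]
    if (all(s >= 0) || all(s <= 0)) on_hull[c(i, j)] <- TRUE
  }
  pts[on_hull, , drop = FALSE]
}

# trapezoidal area under the empirical ROC curve
rocAreaOracle <- function(score_pos, score_neg) {
  thr <- sort(unique(c(score_pos, score_neg, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(score_neg >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# small world reused across pipeline tests (built once per test run)
smallWorld <- local({
  w <- NULL
  function() {
    if (is.null(w))
      w <<- genWorld(n_species = 9L, n_presences = 120L,
                     dims = c(120L, 120L), seed = 101L)
    w
  }
})
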