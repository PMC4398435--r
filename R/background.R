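#' Target-group eligible cells per period
#'
#' A grid cell is eligible as background for a period if at least one record
#' of any species of the target group falls in it during that period. This
#' is the target-group background device: drawing pseudo-absences only from
#' surveyed sites cancels survey bias shared across the group.
#'
#' @param all_records period-tagged records of every species in the group.
#' @param grid a [GridLayer-class]/[EnvStack-class] defining the cells.
#' @return list with integer matrices `pre1950` and `post1950`, each two
#'   columns (row, col) of unique eligible cells.
#' @export
targetGroupCells <- function(all_records, grid) {
  if (nrow(all_records) == 0L) stop("no records supplied")
  if (is.null(all_records$period)) stop("records must carry periods")
  ci <- cellIndex(grid, all_records$lon, all_records$lat)
  ok <- !is.na(ci[, 1L])
  out <- list()
  for (p in c("pre1950", "post1950")) {
    sel <- ok & all_records$period == p
    cells <- unique(ci[sel, , drop = FALSE])
    # deterministic order irrespective of record order
    cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
    out[[p]] <- cells
  }
  out
}

#' Sample a temporally stratified target-group background
#'
#' Draws `n_points` background cells without replacement from the eligible
#' cell sets, allocating `round(n_points * f)` to the pre-1950 period where
#' `f` is the focal species' fraction of pre-1950 records (round-half-to-even,
#' remainder to post-1950), so the background matches the focal species'
#' temporal sampling profile. Points are placed at cell centers and their
#' environmental values read from the period-matched stack.
#'
#' @param eligible output of [targetGroupCells()].
#' @param focal_counts named vector `c(pre1950=, post1950=)` for the focal
#'   species (see [periodCounts()]).
#' @param stacks named list of [EnvStack-class] keyed by period.
#' @param n_points total background size (default 10000).
#' @param seed integer seed; the draw is a pure function of
#'   (eligible, focal_counts, n_points, seed).
#' @return SWD data.frame with `label = "background"`.
#' @export
sampleBackground <- function(eligible, focal_counts, stacks,
                             n_points = 10000L, seed = 1L) {
  stopifnot(n_points >= 1L)
  tot <- sum(focal_counts)
  if (tot == 0L) stop("focal species has no records")
  f <- unname(focal_counts[["pre1950"]]) / tot
  n_pre <- round(n_points * f)          # round-half-to-even
  n_post <- n_points - n_pre
  draw <- function(cells, n, label) {
    if (n == 0L) return(cells[0L, , drop = FALSE])
    if (nrow(cells) == 0L)
      stop("no eligible background cells for a period with positive ",
           "allocation")
    if (nrow(cells) < n) {
      warning("only ", nrow(cells), " eligible ", label,
              " cells for a request of ", n, "; sampling all")
      return(cells)
    }
    cells[sample.int(nrow(cells), n), , drop = FALSE]
  }
  set.seed(seed)
  pre <- draw(eligible$pre1950, n_pre, "pre1950")
  post <- draw(eligible$post1950, n_post, "post1950")
  mk <- function(cells, period) {
    if (nrow(cells) == 0L) return(NULL)
    cc <- cellCenter(stacks[[period]], cells[, 1L], cells[, 2L])
    data.frame(lon = cc[, 1L], lat = cc[, 2L], period = period)
  }
  pts <- rbind(mk(pre, "pre1950"), mk(post, "post1950"))
  extractSWD(pts, stacks, label = "background")
}
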