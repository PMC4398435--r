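#' Load co-registered rasters into an EnvStack
#'
#' Reads one ESRI ASCII grid per variable and verifies that every layer
#' shares the same grid. Misaligned grids raise an error; there is no
#' silent resampling.
#'
#' @param paths named character vector: variable name -> `.asc` file.
#' @param period_label period label for the stack.
#' @return An [EnvStack-class].
#' @export
loadStack <- function(paths, period_label) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by variable")
  layers <- lapply(paths, readAsciiGrid)
  ref <- layers[[1L]]
  for (i in seq_along(layers)[-1L])
    if (!sameGrid(ref, layers[[i]]))
      stop("grid mismatch between '", names(paths)[1L], "' and '",
           names(paths)[i], "' (dimensions, cell size or origin differ)")
  # propagate a common nodata mask so all extractions agree
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l@values)))
  mats <- lapply(layers, function(l) {
    v <- l@values
    v[mask] <- NA_real_
    v
  })
  envStack(mats, period_label, xll = ref@xll, yll = ref@yll, res = ref@res)
}

#' Compute a derived layer from an algebraic expression
#'
#' Evaluates an elementwise expression over the stack's layers. Supported
#' operations: `+`, `-`, `*`, `/`, `mean(...)`, `min(...)`, `max(...)`,
#' `abs(x)` (mean/min/max act across layers, cell by cell). Nodata cells
#' stay nodata; division by zero produces nodata with a warning reporting
#' the affected cell count.
#'
#' @param stack an [EnvStack-class].
#' @param expression character scalar, e.g. `"(tmax + tmin) / 2"` or
#'   `"mean(g1, g2, g3)"`.
#' @return numeric matrix on the stack's grid.
#' @export
deriveLayer <- function(stack, expression) {
  expr <- str2lang(expression)
  allowed <- c("+", "-", "*", "/", "(", "mean", "min", "max", "abs")
  check <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!fn %in% allowed)
        stop("unsupported operation in expression: ", fn)
      for (a in as.list(e)[-1L]) check(a)
    } else if (is.name(e)) {
      if (!as.character(e) %in% names(stack@layers))
        stop("expression references unknown layer: ", as.character(e))
    } else if (!is.numeric(e)) stop("unsupported token in expression")
  }
  check(expr)
  env <- new.env(parent = baseenv())
  for (nm in names(stack@layers)) assign(nm, stack@layers[[nm]], envir = env)
  assign("mean", function(...) {
    args <- list(...)
    Reduce(`+`, args) / length(args)
  }, envir = env)
  assign("min", function(...) Reduce(pmin, list(...)), envir = env)
  assign("max", function(...) Reduce(pmax, list(...)), envir = env)
  out <- eval(expr, env)
  nz <- sum(is.infinite(out) | is.nan(out), na.rm = TRUE)
  if (nz > 0) {
    warning(nz, " cell(s) produced non-finite values (division by zero); ",
            "set to nodata")
    out[is.infinite(out) | is.nan(out)] <- NA_real_
  }
  out
}

#' @rdname deriveLayer
#' @param name layer name for the derived result.
#' @return `addDerivedLayer` returns the stack with the new layer appended.
#' @export
addDerivedLayer <- function(stack, name, expression) {
  m <- deriveLayer(stack, expression)
  stack@layers[[name]] <- m
  methods::validObject(stack)
  stack
}

#' Extract a samples-with-data (SWD) table
#'
#' Pairs each period-tagged record with the environmental values of its grid
#' cell read from the period-matched stack (pre-1950 records from the past
#' stack, post-1950 from the current stack). Rows falling on nodata cells or
#' outside the grid are dropped and counted in the `dropped` attribute.
#'
#' @param records period-tagged occurrence data.frame (needs lon, lat,
#'   period).
#' @param stacks named list of [EnvStack-class], keyed by period
#'   (`pre1950`, `post1950`).
#' @param label value for the SWD `label` column (default "presence").
#' @return data.frame `label, period, lon, lat, <var1>, ...` with attribute
#'   `dropped` (count of nodata/out-of-grid rows).
#' @export
extractSWD <- function(records, stacks, label = "presence") {
  periods <- unique(records$period)
  miss <- setdiff(periods, names(stacks))
  if (length(miss))
    stop("no stack supplied for period(s): ", paste(miss, collapse = ", "))
  vars <- names(stacks[[1L]]@layers)
  for (s in stacks) if (!identical(names(s@layers), vars))
    stop("stacks must share the same variable set and order")
  n <- nrow(records)
  vals <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (p in periods) {
    sel <- which(records$period == p)
    st <- stacks[[p]]
    ci <- cellIndex(st, records$lon[sel], records$lat[sel])
    ok <- !is.na(ci[, 1L])
    for (j in seq_along(vars)) {
      m <- st@layers[[j]]
      v <- rep(NA_real_, length(sel))
      v[ok] <- m[cbind(ci[ok, 1L], ci[ok, 2L])]
      vals[sel, j] <- v
    }
  }
  complete <- stats::complete.cases(vals)
  out <- data.frame(label = label, period = records$period[complete],
                    lon = records$lon[complete], lat = records$lat[complete],
                    vals[complete, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!complete)
  out
}

#' Write / read an SWD table as CSV
#'
#' @param swd SWD data.frame.
#' @param path CSV path.
#' @export
writeSWD <- function(swd, path) {
  utils::write.csv(swd, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSWD
#' @export
readSWD <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
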