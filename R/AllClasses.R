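#' @import methods
NULL

#' Single-band geographic raster on a regular WGS84 grid
#'
#' A `GridLayer` stores one variable on a regular longitude/latitude grid
#' with cell-center registration. Row 1 is the northernmost row; values are
#' a plain numeric matrix with `NA` marking nodata (sea, missing coverage).
#' The grid is described by the lower-left corner of the extent (`xll`,
#' `yll`, degrees) and a square cell size `res` (degrees). A point with
#' longitude x falls in column `floor((x - xll)/res) + 1` (half-open cell
#' intervals), symmetrically for latitude.
#'
#' @slot values numeric matrix, row 1 = north.
#' @slot xll,yll numeric(1), lower-left corner of the extent in degrees.
#' @slot res numeric(1), cell size in decimal degrees (> 0).
#' @export
setClass("GridLayer",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 res = "numeric"))

setValidity("GridLayer", function(object) {
  msg <- character()
  if (length(object@res) != 1L || !is.finite(object@res) || object@res <= 0)
    msg <- c(msg, "res must be a single positive number")
  if (length(object@xll) != 1L || length(object@yll) != 1L ||
      !is.finite(object@xll) || !is.finite(object@yll))
    msg <- c(msg, "xll/yll must be single finite numbers")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' Co-registered multi-layer environmental stack for one time period
#'
#' An `EnvStack` holds named environmental layers that share one grid.
#' All layers must have identical dimensions and an identical nodata (NA)
#' mask so that extraction and algebra never mix grids silently.
#'
#' @slot period character(1) period label, e.g. "current1950_2000".
#' @slot layers named list of numeric matrices (row 1 = north).
#' @slot xll,yll,res grid geometry as in [GridLayer-class].
#' @export
setClass("EnvStack",
  representation(period = "character", layers = "list", xll = "numeric",
                 yll = "numeric", res = "numeric"))

setValidity("EnvStack", function(object) {
  msg <- character()
  if (length(object@layers) < 1L) msg <- c(msg, "stack needs >= 1 layer")
  nm <- names(object@layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    msg <- c(msg, "layers must have unique non-empty names")
  dims <- lapply(object@layers, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all layers must share the same grid dimensions")
  if (length(object@layers) > 1L) {
    mask <- is.na(object@layers[[1L]])
    for (i in seq_along(object@layers)[-1L])
      if (!identical(mask, is.na(object@layers[[i]]))) {
        msg <- c(msg, "nodata masks differ between layers")
        break
      }
  }
  if (object@res <= 0) msg <- c(msg, "res must be positive")
  if (length(msg)) msg else TRUE
})

#' Penalized presence-background suitability model
#'
#' The background-normalized exponential (Gibbs) model fitted by L1-penalized
#' maximum likelihood: raw output at covariates z is exp(beta'z)/Z where Z
#' normalizes over the training background, so raw values sum to 1 on the
#' training background. Slots record the feature expansion (kinds, operands,
#' training min/max used to scale each feature into [0,1]), the fitted
#' coefficients, the log normalizer, the entropy of the fitted background
#' distribution (used by the cloglog output transform), and convergence
#' diagnostics.
#'
#' @slot baseVars character, ordered base variable names.
#' @slot featKind character, "linear"/"quadratic"/"product" per feature.
#' @slot featOps list of character operand names per feature.
#' @slot scaleMin,scaleMax numeric per feature, training scaling bounds.
#' @slot beta numeric coefficients per feature.
#' @slot logZ numeric(1) log normalizer over training background.
#' @slot entropy numeric(1) entropy of fitted background distribution.
#' @slot regLambda numeric per-feature L1 penalty weights.
#' @slot betaReg numeric(1) global regularization multiplier.
#' @slot converged logical(1); @slot gradNorm numeric(1) final stationarity.
#' @export
setClass("PBModel",
  representation(baseVars = "character", featKind = "character",
                 featOps = "list", scaleMin = "numeric", scaleMax = "numeric",
                 beta = "numeric", logZ = "numeric", entropy = "numeric",
                 regLambda = "numeric", betaReg = "numeric",
                 converged = "logical", gradNorm = "numeric"))

setValidity("PBModel", function(object) {
  p <- length(object@featKind)
  if (length(object@beta) != p || length(object@scaleMin) != p ||
      length(object@scaleMax) != p || length(object@regLambda) != p)
    return("feature-indexed slots must have equal length")
  if (any(!is.finite(object@beta))) return("coefficients must be finite")
  TRUE
})

#' Replicated model set (bootstrap or cross-validation)
#'
#' @slot scheme "bootstrap10" or "cv4fold".
#' @slot models list of [PBModel-class] replicate fits.
#' @slot testIdx list of integer vectors: held-out presence row indices per
#'   replicate (out-of-bag rows for bootstrap, the test fold for CV).
#' @slot seed integer(1) seed used for the resampling.
#' @export
setClass("ReplicateSet",
  representation(scheme = "character", models = "list", testIdx = "list",
                 seed = "integer"))

setValidity("ReplicateSet", function(object) {
  if (!object@scheme %in% c("bootstrap10", "cv4fold"))
    return("scheme must be bootstrap10 or cv4fold")
  want <- if (object@scheme == "bootstrap10") 10L else 4L
  if (length(object@models) != want)
    return(sprintf("%s requires %d replicates", object@scheme, want))
  if (length(object@testIdx) != length(object@models))
    return("one test index set per replicate required")
  if (object@scheme == "cv4fold") {
    all_idx <- sort(unlist(object@testIdx))
    if (anyDuplicated(all_idx)) return("cv folds must be disjoint")
  }
  TRUE
})

#' Phylogenetic generalized least-squares fit with Pagel's lambda
#'
#' @slot coefTable data.frame with columns term, beta, se, t, p.
#' @slot lambda numeric(1) ML estimate in [0, 1].
#' @slot logLik numeric(1) maximized log-likelihood.
#' @slot aicc numeric(1).
#' @slot lrt0,lrt1 numeric(1) likelihood-ratio p-values against lambda fixed
#'   at 0 and at 1.
#' @slot n,k integer(1): observations and estimated parameters
#'   (coefficients + sigma^2 + lambda).
#' @slot sigma2 numeric(1) ML residual variance.
#' @slot y,X,Vlambda fitted data and lambda-transformed covariance, kept for
#'   residual diagnostics.
#' @export
setClass("PGLSFit",
  representation(coefTable = "data.frame", lambda = "numeric",
                 logLik = "numeric", aicc = "numeric", lrt0 = "numeric",
                 lrt1 = "numeric", n = "integer", k = "integer",
                 sigma2 = "numeric", y = "numeric", X = "matrix",
                 Vlambda = "matrix"))

setValidity("PGLSFit", function(object) {
  if (object@lambda < -1e-12 || object@lambda > 1 + 1e-12)
    return("lambda must lie in [0, 1]")
  if (object@n <= object@k - 1L) return("n must exceed k - 1")
  TRUE
})
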