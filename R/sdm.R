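## Presence-background suitability modelling. The estimator is the
## background-normalized exponential (Gibbs) model: the probability mass the
## model puts on background location x is exp(beta'z(x)) / Z with Z summing
## exp(beta'z) over the training background. Coefficients maximize the
## presence log-likelihood under this density minus per-feature L1 penalties,
## so at the optimum each fitted background-expected feature matches the
## presence mean to within its penalty weight. Features are linear,
## quadratic and pairwise-product terms of the base variables, each scaled
## into [0,1] by its training range.

#' Expand base variables into linear, quadratic and product features
#'
#' Builds the feature matrix used by the suitability model: all linear
#' terms, then all quadratic terms, then pairwise products in lexicographic
#' pair order (by base-variable position). Each feature is scaled into
#' [0, 1] by its min/max over the training rows. Base variables that are
#' constant on the training data carry no information and cannot be scaled;
#' they are excluded from the expansion with a warning.
#'
#' @param data data.frame or matrix containing the base variables.
#' @param base_vars ordered character vector of base variable names.
#' @param expansion optional existing expansion (a [PBModel-class] or the
#'   list returned here) to re-apply to new data; feature values are then
#'   clamped into the training [0, 1] range (extrapolation guard).
#' @return list with `Z` (scaled feature matrix), `featKind`, `featOps`,
#'   `scaleMin`, `scaleMax`, `baseVars`.
#' @export
expandFeatures <- function(data, base_vars, expansion = NULL) {
  X <- as.matrix(as.data.frame(data)[, base_vars, drop = FALSE])
  if (is.null(expansion)) {
    keep <- apply(X, 2L, function(v) diff(range(v)) > 0)
    if (any(!keep))
      warning("constant on training data, excluded from expansion: ",
              paste(base_vars[!keep], collapse = ", "))
    vars <- base_vars[keep]
    if (length(vars) == 0L) stop("no non-constant base variables")
    kind <- c(rep("linear", length(vars)), rep("quadratic", length(vars)))
    ops <- c(lapply(vars, identity), lapply(vars, identity))
    if (length(vars) >= 2L) {
      prs <- utils::combn(vars, 2L, simplify = FALSE)
      kind <- c(kind, rep("product", length(prs)))
      ops <- c(ops, prs)
    }
    raw <- rawFeatures(X, kind, ops)
    mn <- apply(raw, 2L, min)
    mx <- apply(raw, 2L, max)
    Z <- sweep(sweep(raw, 2L, mn), 2L, mx - mn, `/`)
    list(Z = Z, featKind = kind, featOps = ops, scaleMin = mn,
         scaleMax = mx, baseVars = vars)
  } else {
    e <- if (is(expansion, "PBModel"))
      list(featKind = expansion@featKind, featOps = expansion@featOps,
           scaleMin = expansion@scaleMin, scaleMax = expansion@scaleMax,
           baseVars = expansion@baseVars)
    else expansion
    raw <- rawFeatures(X, e$featKind, e$featOps)
    Z <- sweep(sweep(raw, 2L, e$scaleMin), 2L, e$scaleMax - e$scaleMin, `/`)
    Z[Z < 0] <- 0  # clamp outside training range
    Z[Z > 1] <- 1
    c(list(Z = Z), e)
  }
}

rawFeatures <- function(X, kind, ops) {
  cols <- mapply(function(k, op) {
    switch(k,
           linear = X[, op[[1L]]],
           quadratic = X[, op[[1L]]]^2,
           product = X[, op[[1L]]] * X[, op[[2L]]])
  }, kind, ops, SIMPLIFY = FALSE)
  out <- do.call(cbind, cols)
  colnames(out) <- featureLabels(kind, ops)
  out
}

featureLabels <- function(kind, ops) {
  mapply(function(k, op) switch(k,
    linear = op[[1L]],
    quadratic = paste0(op[[1L]], "^2"),
    product = paste0(op[[1L]], "*", op[[2L]])), kind, ops,
    USE.NAMES = FALSE)
}

#' Choose the replication scheme from the presence count
#'
#' Species with fewer than 30 records are validated by 10-replicate
#' bootstrapping (maximizing points used for both training and testing);
#' species with 30 or more records by 4-fold cross-validation (about 8
#' points per test fold, the accepted minimum). Below `min_records` the
#' species cannot be modelled at all.
#'
#' @param n_presences number of presence records.
#' @param min_records minimum modellable record count (default 8).
#' @param cv_cut record count at which CV replaces bootstrapping (default 30).
#' @return "bootstrap10", "cv4fold", or "insufficient".
#' @export
chooseReplication <- function(n_presences, min_records = 8L, cv_cut = 30L) {
  if (n_presences < min_records) return("insufficient")
  if (n_presences < cv_cut) "bootstrap10" else "cv4fold"
}

# Per-feature-class regularization multipliers interpolated by presence
# sample size (the reference presence-background program's published
# defaults for linear/quadratic/product features).
regMultiplier <- function(kind, np) {
  tab <- list(
    linear = list(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05)),
    quadratic = list(x = c(10, 17, 30, 100), y = c(1.3, 0.8, 0.5, 0.05)),
    product = list(x = c(10, 17, 30, 100), y = c(2.6, 1.6, 0.9, 0.05)))
  vapply(kind, function(k) {
    t <- tab[[k]]
    stats::approx(t$x, t$y, xout = np, rule = 2)$y
  }, numeric(1))
}

#' Fit the penalized presence-background model
#'
#' Maximizes the L1-penalized presence log-likelihood of the
#' background-normalized exponential model by proximal gradient descent
#' (FISTA with backtracking and restart). The per-feature penalty is
#' `beta_reg * m_class(n) * sd_k / sqrt(n)` where `m_class` is the
#' feature-class default multiplier interpolated at the presence count and
#' `sd_k` the presence standard deviation of the scaled feature, so each
#' fitted background-expected feature matches the presence mean to within
#' its penalty weight.
#'
#' @param presence,background SWD data.frames (rows with the base variables).
#' @param base_vars character vector of base variable names.
#' @param beta_reg global regularization multiplier (default 1).
#' @param max_iter,tol optimizer controls; convergence is declared when the
#'   infinity norm of the L1 stationarity residual falls below `tol`.
#' @return A [PBModel-class]. Non-convergence raises an error carrying the
#'   final gradient norm.
#' @export
fitPBModel <- function(presence, background, base_vars, beta_reg = 1,
                       max_iter = 5000L, tol = 1e-6) {
  np <- nrow(presence); nb <- nrow(background)
  if (np < 1L) stop("need at least 1 presence row")
  if (nb < 2L) stop("need at least 2 background rows")
  train <- rbind(as.data.frame(presence)[, base_vars, drop = FALSE],
                 as.data.frame(background)[, base_vars, drop = FALSE])
  exp_tr <- expandFeatures(train, base_vars)
  Zp <- exp_tr$Z[seq_len(np), , drop = FALSE]
  Zb <- exp_tr$Z[np + seq_len(nb), , drop = FALSE]
  K <- ncol(Zp)
  sdp <- apply(Zp, 2L, stats::sd)
  if (np == 1L) sdp <- rep(0.5, K)
  lam <- beta_reg * regMultiplier(exp_tr$featKind, np) *
    pmax(sdp, 1e-3) / sqrt(np)
  zbar <- colMeans(Zp)

  smooth <- function(beta) {
    u <- drop(Zb %*% beta)
    m <- max(u)
    lse <- m + log(sum(exp(u - m)))
    list(val = -sum(zbar * beta) + lse,
         w = exp(u - lse), lse = lse)
  }
  grad <- function(s) drop(crossprod(Zb, s$w)) - zbar
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  beta <- numeric(K); ycur <- beta; tk <- 1; L <- 1
  s <- smooth(ycur)
  for (it in seq_len(max_iter)) {
    g <- grad(s)
    repeat {
      cand <- soft(ycur - g / L, lam / L)
      sc <- smooth(cand)
      dv <- cand - ycur
      if (sc$val <= s$val + sum(g * dv) + L / 2 * sum(dv^2) + 1e-12) break
      L <- L * 2
    }
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    ynew <- cand + (tk - 1) / tnew * (cand - beta)
    # restart acceleration when the momentum points uphill
    if (sum((ycur - cand) * (cand - beta)) > 0) {
      ynew <- cand
      tnew <- 1
    }
    beta <- cand; ycur <- ynew; tk <- tnew
    s <- smooth(ycur)
    gfull <- grad(smooth(beta))
    resid <- ifelse(beta != 0, abs(gfull + lam * sign(beta)),
                    pmax(abs(gfull) - lam, 0))
    if (max(resid) < tol) break
    L <- max(L / 2, 1e-4)
  }
  gfull <- grad(smooth(beta))
  resid <- ifelse(beta != 0, abs(gfull + lam * sign(beta)),
                  pmax(abs(gfull) - lam, 0))
  conv <- max(resid) < tol * 10
  if (!conv && max(resid) > 1e-3)
    stop("presence-background fit did not converge: stationarity residual ",
         format(max(resid)), " after ", max_iter, " iterations")
  sb <- smooth(beta)
  w <- sb$w
  H <- -sum(w * log(pmax(w, 1e-300)))
  new("PBModel", baseVars = exp_tr$baseVars, featKind = exp_tr$featKind,
      featOps = exp_tr$featOps, scaleMin = exp_tr$scaleMin,
      scaleMax = exp_tr$scaleMax, beta = beta, logZ = sb$lse, entropy = H,
      regLambda = lam, betaReg = beta_reg, converged = conv,
      gradNorm = max(resid))
}

setMethod("show", "PBModel", function(object) {
  cat(sprintf(
    "PBModel: %d features over %d base variables (beta_reg = %g)\n",
    length(object@beta), length(object@baseVars), object@betaReg))
  nz <- sum(object@beta != 0)
  cat(sprintf("  %d non-zero coefficients; converged: %s (residual %.2e)\n",
              nz, object@converged, object@gradNorm))
})

#' Raw and cloglog suitability at data rows
#'
#' `predictPB` evaluates the model at new rows: `raw` is the
#' background-normalized density exp(beta'z)/Z (summing to 1 over the
#' training background); `cloglog` is `1 - exp(-exp(H) * raw)` with H the
#' entropy of the fitted background distribution, mapping raw density to a
#' [0, 1] suitability index.
#'
#' @param model a [PBModel-class].
#' @param newdata data.frame with the base variables.
#' @param type "cloglog" (default) or "raw".
#' @return numeric vector.
#' @export
predictPB <- function(model, newdata, type = c("cloglog", "raw")) {
  type <- match.arg(type)
  Z <- expandFeatures(newdata, model@baseVars, expansion = model)$Z
  raw <- exp(drop(Z %*% model@beta) - model@logZ)
  if (type == "raw") raw else 1 - exp(-exp(model@entropy) * raw)
}

#' Fit replicate models under the chosen scheme
#'
#' `bootstrap10`: ten replicates, each trained on a with-replacement
#' resample of the presences (same n, background fixed); held-out rows are
#' the out-of-bag presences. `cv4fold`: presences split into four
#' random folds stratified by period; each replicate trains on three folds
#' and holds out the fourth.
#'
#' @param scheme "bootstrap10" or "cv4fold" (see [chooseReplication()]).
#' @param presence,background SWD data.frames.
#' @param base_vars base variable names.
#' @param beta_reg regularization multiplier.
#' @param seed integer seed controlling resampling.
#' @return A [ReplicateSet-class].
#' @export
fitReplicates <- function(scheme, presence, background, base_vars,
                          beta_reg = 1, seed = 1L) {
  np <- nrow(presence)
  set.seed(seed)
  if (scheme == "bootstrap10") {
    models <- vector("list", 10L); test <- vector("list", 10L)
    for (r in 1:10) {
      idx <- sample.int(np, np, replace = TRUE)
      oob <- setdiff(seq_len(np), unique(idx))
      models[[r]] <- fitPBModel(presence[idx, , drop = FALSE], background,
                                base_vars, beta_reg)
      test[[r]] <- as.integer(oob)
    }
  } else if (scheme == "cv4fold") {
    if (np < 4L) stop("too few presences for 4-fold CV; use bootstrap")
    fold <- integer(np)
    for (p in unique(presence$period)) {
      sel <- which(presence$period == p)
      fold[sel] <- sample(rep_len(1:4, length(sel)))
    }
    if (any(tabulate(fold, 4L) == 0L))
      stop("a CV fold has no test presences; use bootstrap instead")
    models <- vector("list", 4L); test <- vector("list", 4L)
    for (r in 1:4) {
      tr <- which(fold != r)
      models[[r]] <- fitPBModel(presence[tr, , drop = FALSE], background,
                                base_vars, beta_reg)
      test[[r]] <- which(fold == r)
    }
  } else stop("unknown scheme: ", scheme)
  new("ReplicateSet", scheme = scheme, models = models, testIdx = test,
      seed = as.integer(seed))
}

setMethod("show", "ReplicateSet", function(object) {
  cat(sprintf("ReplicateSet: %s, %d replicate models (seed %d)\n",
              object@scheme, length(object@models), object@seed))
})

#' Predict a suitability map over an environmental stack
#'
#' Evaluates the model (or the arithmetic mean over a replicate set's
#' models) at every grid cell of the stack. Feature scaling is clamped to
#' the training [0, 1] range so projections never extrapolate feature
#' values. Nodata cells propagate.
#'
#' @param model a [PBModel-class] or [ReplicateSet-class].
#' @param stack an [EnvStack-class] containing all base variables.
#' @param type "cloglog" (default) or "raw".
#' @return numeric matrix of suitabilities on the stack's grid.
#' @export
predictMap <- function(model, stack, type = "cloglog") {
  if (is(model, "ReplicateSet")) {
    preds <- lapply(model@models, predictMap, stack = stack, type = type)
    return(Reduce(`+`, preds) / length(preds))
  }
  miss <- setdiff(model@baseVars, names(stack@layers))
  if (length(miss)) stop("stack lacks base variable(s): ",
                         paste(miss, collapse = ", "))
  d <- dim(stack)
  df <- as.data.frame(lapply(stack@layers[model@baseVars], as.vector))
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok)) out[ok] <- predictPB(model, df[ok, , drop = FALSE], type)
  matrix(out, d[1L], d[2L])
}

#' Suitability at SWD rows under a replicate set
#'
#' Mean over replicate models of the suitability at each row; used for
#' thresholding and evaluation at points rather than over maps.
#'
#' @param reps a [ReplicateSet-class] (or single [PBModel-class]).
#' @param swd SWD data.frame.
#' @param type "cloglog" or "raw".
#' @return numeric vector.
#' @export
predictRows <- function(reps, swd, type = "cloglog") {
  if (is(reps, "PBModel")) return(predictPB(reps, swd, type))
  preds <- lapply(reps@models, predictPB, newdata = swd, type = type)
  Reduce(`+`, preds) / length(preds)
}
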