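## Phylogenetically controlled regression machinery. The PGLS model is
## y = X beta + e, e ~ N(0, sigma^2 V(lambda)) with V the Brownian-motion
## covariance (shared root-to-MRCA path lengths) and Pagel's lambda scaling
## the off-diagonal entries. lambda is estimated by profile maximum
## likelihood on [0, 1] (21-point grid pre-scan, then bounded refinement)
## and tested against the fixed boundaries 0 and 1 by likelihood ratio.

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly regresses each trait on the others and drops the trait with
#' the largest VIF (1/(1-R^2)) while any VIF exceeds the cut. Perfectly
#' collinear traits (infinite VIF) are dropped immediately.
#'
#' @param traits numeric data.frame/matrix of continuous traits.
#' @param vif_cut removal threshold (default 5, i.e. tolerance 0.2).
#' @return list with `retained` (names), `dropped` (names in drop order),
#'   `vif` (final VIFs of the retained traits).
#' @export
vifScreen <- function(traits, vif_cut = 5) {
  X <- as.data.frame(traits)
  stopifnot(ncol(X) >= 2L)
  dropped <- character()
  vifs_of <- function(X) {
    vapply(seq_along(X), function(j) {
      # a perfectly collinear fit is expected here; it maps to infinite VIF
      r2 <- suppressWarnings(
        summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  repeat {
    if (ncol(X) < 2L) break
    v <- vifs_of(X)
    if (all(v <= vif_cut)) break
    worst <- which.max(v)
    dropped <- c(dropped, names(X)[worst])
    X <- X[-worst]
  }
  v <- if (ncol(X) >= 2L) vifs_of(X) else rep(1, ncol(X))
  names(v) <- names(X)
  list(retained = names(X), dropped = dropped, vif = v)
}

#' Brownian-motion covariance and the lambda transform
#'
#' `bmCovariance` returns V with V_ij the shared root-to-MRCA path length of
#' tips i and j (diagonal = root-to-tip depth). `lambdaTransform` multiplies
#' the off-diagonal entries by lambda, leaving the diagonal untouched.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param V covariance matrix.
#' @param lambda scalar in [0, 1].
#' @return numeric matrix.
#' @export
bmCovariance <- function(tree) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  ape::vcv.phylo(tree)
}

#' @rdname bmCovariance
#' @export
lambdaTransform <- function(V, lambda) {
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# Profile GLS log-likelihood pieces at fixed V
glsProfile <- function(y, X, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e)
    stop("phylogenetic covariance is not positive definite"))
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular design after whitening; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, yw)
  r <- yw - Xw %*% beta
  rss <- sum(r^2)
  sigma2 <- rss / n
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) - sum(log(diag(R)))
  list(beta = beta, sigma2 = sigma2, logLik = ll, rss = rss,
       XtVinvX_inv = solve(crossprod(Xw)),
       resid_w = drop(r), Xw = Xw, yw = yw)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param logLik log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (must exceed k + 1).
#' @return numeric.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a phylogenetic GLS with Pagel's lambda
#'
#' Estimates lambda in [0, 1] by profile maximum likelihood (21-point grid
#' pre-scan, then bounded 1-D refinement to tolerance 1e-6), computes GLS
#' coefficients and t-tests at the optimum, and likelihood-ratio tests of
#' the estimate against lambda fixed at 0 and at 1. The parameter count for
#' AICc is the number of coefficients plus two (sigma^2 and lambda).
#'
#' @param formula model formula, e.g. `response ~ body_mass + litter_size`.
#' @param data data.frame; rows are matched to tree tips via `species_col`.
#' @param tree `ape::phylo`; every data row must name a tip.
#' @param species_col column holding the tip labels (default "species").
#' @param lambda optional fixed lambda (skips estimation; LRT p-values NA).
#' @return A [PGLSFit-class].
#' @export
pglsFit <- function(formula, data, tree, species_col = "species",
                    lambda = NULL) {
  data <- as.data.frame(data)
  rownames(data) <- NULL  # model.frame rownames must index positions
  if (!species_col %in% names(data))
    stop("data lacks the species column '", species_col, "'")
  spp <- as.character(data[[species_col]])
  miss <- setdiff(spp, tree$tip.label)
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  if (anyDuplicated(spp)) stop("duplicate species rows")
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  kept <- as.integer(rownames(mf))
  spp <- spp[kept]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  k_coef <- ncol(X)
  if (n <= k_coef + 1L) stop("too few species: n must exceed k + 1")
  V <- bmCovariance(tree)[spp, spp]

  ll_at <- function(lam) glsProfile(y, X, lambdaTransform(V, lam))$logLik
  if (is.null(lambda)) {
    grid <- seq(0, 1, length.out = 21L)
    ll_grid <- vapply(grid, ll_at, numeric(1))
    i <- which.max(ll_grid)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(21L, i + 1L)]
    opt <- stats::optimize(ll_at, c(lo, hi), maximum = TRUE, tol = 1e-6)
    lam_hat <- if (opt$objective >= max(ll_grid)) opt$maximum else grid[i]
    lam_hat <- min(1, max(0, lam_hat))
  } else lam_hat <- lambda
  fit <- glsProfile(y, X, lambdaTransform(V, lam_hat))
  # t-tests with the unbiased variance (df = n - k_coef)
  sigma2_u <- fit$rss / (n - k_coef)
  se <- sqrt(pmax(diag(fit$XtVinvX_inv), 0) * sigma2_u)
  tval <- drop(fit$beta) / se
  pval <- 2 * stats::pt(abs(tval), df = n - k_coef, lower.tail = FALSE)
  coefTable <- data.frame(term = colnames(X), beta = drop(fit$beta),
                          se = se, t = tval, p = pval,
                          row.names = NULL)
  if (is.null(lambda)) {
    lrt_p <- function(lam0) {
      stat <- 2 * (fit$logLik - ll_at(lam0))
      stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
    }
    lrt0 <- lrt_p(0); lrt1 <- lrt_p(1)
  } else lrt0 <- lrt1 <- NA_real_
  k <- k_coef + 2L
  new("PGLSFit", coefTable = coefTable, lambda = lam_hat,
      logLik = fit$logLik, aicc = aicc(fit$logLik, k, n), lrt0 = lrt0,
      lrt1 = lrt1, n = as.integer(n), k = as.integer(k),
      sigma2 = fit$sigma2, y = as.numeric(y), X = X,
      Vlambda = lambdaTransform(V, lam_hat))
}

setMethod("show", "PGLSFit", function(object) {
  cat(sprintf("PGLSFit: n = %d, lambda = %.3f (LRT vs 0: p = %.3g, vs 1: p = %.3g)\n",
              object@n, object@lambda, object@lrt0, object@lrt1))
  cat(sprintf("  logLik = %.3f, AICc = %.3f\n", object@logLik, object@aicc))
  print(object@coefTable, digits = 4)
})

#' Externally studentized residuals of a PGLS fit
#'
#' Residuals are computed in the whitened space (V(lambda)^{-1/2}), where
#' the model is an ordinary regression, and studentized externally
#' (leave-one-out variance). Species with |r| > `cut` are flagged.
#'
#' @param fit a [PGLSFit-class].
#' @param cut flag threshold (default 3).
#' @return named numeric vector of studentized residuals with attribute
#'   `flagged` (row indices exceeding the cut).
#' @export
studentizedResiduals <- function(fit, cut = 3) {
  R <- chol(fit@Vlambda)
  yw <- backsolve(R, fit@y, transpose = TRUE)
  Xw <- backsolve(R, fit@X, transpose = TRUE)
  lmfit <- stats::lm.fit(Xw, yw)
  h <- stats::hat(Xw, intercept = FALSE)
  r <- lmfit$residuals
  n <- length(r); k <- ncol(Xw)
  s2 <- sum(r^2) / (n - k)
  s2_i <- ((n - k) * s2 - r^2 / (1 - h)) / (n - k - 1)
  rs <- r / sqrt(pmax(s2_i, 1e-300) * (1 - h))
  names(rs) <- rownames(fit@Vlambda)
  attr(rs, "flagged") <- which(abs(rs) > cut)
  rs
}

#' One-pass outlier removal then refit
#'
#' Flags species with externally studentized residuals beyond the cut,
#' removes them, and refits once. Refuses when removal would leave n <= k+1.
#'
#' @inheritParams pglsFit
#' @param cut studentized-residual threshold (default 3).
#' @return list with `fit` (the refit, or the original when nothing was
#'   flagged) and `removed` (species names).
#' @export
refitWithoutOutliers <- function(formula, data, tree,
                                 species_col = "species", cut = 3) {
  fit <- pglsFit(formula, data, tree, species_col)
  rs <- studentizedResiduals(fit, cut)
  flag <- attr(rs, "flagged")
  if (length(flag) == 0L) return(list(fit = fit, removed = character()))
  bad <- names(rs)[flag]
  keep <- !(as.character(data[[species_col]]) %in% bad)
  k_coef <- ncol(fit@X)
  if (sum(keep) <= k_coef + 1L)
    stop("removing ", length(bad), " outlier(s) would leave too few species")
  list(fit = pglsFit(formula, data[keep, , drop = FALSE], tree, species_col),
       removed = bad)
}

#' Shapiro-Wilk normality of the whitened residuals
#'
#' @param fit a [PGLSFit-class] (needs 3 <= n <= 5000).
#' @return the Shapiro-Wilk p-value.
#' @export
residualNormality <- function(fit) {
  R <- chol(fit@Vlambda)
  yw <- backsolve(R, fit@y, transpose = TRUE)
  Xw <- backsolve(R, fit@X, transpose = TRUE)
  r <- stats::lm.fit(Xw, yw)$residuals
  if (length(r) < 3L || length(r) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(r) < 1e-12) stop("degenerate (constant) residuals")
  stats::shapiro.test(r)$p.value
}

#' All-subsets PGLS ranking by AICc
#'
#' Fits every subset of the full model's terms (intercept always included,
#' each subset refit with its own lambda), ranks by AICc and attaches Akaike
#' weights exp(-delta/2) normalized over the set.
#'
#' @inheritParams pglsFit
#' @return list with `table` (data.frame: model formula string, k, logLik,
#'   aicc, delta, weight, ordered best first) and `fits` (the corresponding
#'   [PGLSFit-class] objects).
#' @export
dredgePGLS <- function(formula, data, tree, species_col = "species") {
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  if (length(labels) > 20L)
    stop("refusing all-subsets search over more than 20 terms")
  response <- as.character(attr(tt, "variables"))[2L]
  subsets <- unlist(lapply(0:length(labels), function(m)
    utils::combn(labels, m, simplify = FALSE)), recursive = FALSE)
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    rhs <- if (length(subsets[[i]])) paste(subsets[[i]], collapse = " + ")
    else "1"
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- pglsFit(f, data, tree, species_col)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(model = rhs, k = fit@k, logLik = fit@logLik,
                            aicc = fit@aicc)
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$aicc - min(tab$aicc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  ord <- order(tab$aicc)
  list(table = tab[ord, ], fits = fits[ord])
}

#' Model-averaged coefficients over a dredge set
#'
#' Full (zero-substituted) averaging by default: each term's coefficient is
#' the Akaike-weight-weighted mean over all models with absent terms
#' contributing zero. Conditional averaging (weights renormalized over the
#' models containing the term) is available with `method = "conditional"`.
#' Relative importance is the summed weight of models containing each term.
#'
#' @param dredged output of [dredgePGLS()].
#' @param method "full" or "conditional".
#' @return data.frame: term, beta_avg, importance.
#' @export
modelAverage <- function(dredged, method = c("full", "conditional")) {
  method <- match.arg(method)
  w <- dredged$table$weight
  terms_all <- unique(unlist(lapply(dredged$fits,
                                    function(f) f@coefTable$term)))
  out <- lapply(terms_all, function(tm) {
    b <- vapply(dredged$fits, function(f) {
      i <- match(tm, f@coefTable$term)
      if (is.na(i)) 0 else f@coefTable$beta[i]
    }, numeric(1))
    has <- vapply(dredged$fits,
                  function(f) tm %in% f@coefTable$term, logical(1))
    beta <- if (method == "full") sum(w * b)
    else sum(w[has] * b[has]) / sum(w[has])
    data.frame(term = tm, beta_avg = beta, importance = sum(w[has]))
  })
  do.call(rbind, out)
}

#' GLS temporal-trend model with AR(1) errors
#'
#' Fits `y ~ group * period` by maximum-likelihood GLS with an AR(1)
#' correlation structure within species (the minimal ARMA structure for
#' serially dependent period metrics) and returns the sequential F-tests
#' for period, group and their interaction.
#'
#' @param data data.frame with columns `species`, `group`, `period`
#'   (numeric index), and the response.
#' @param response response column name.
#' @return list: `fit` (the `nlme::gls` object), `phi` (estimated AR(1)
#'   coefficient), `anova` (F-table).
#' @export
glsTrend <- function(data, response = "y") {
  data <- as.data.frame(data)
  need <- c("species", "group", "period", response)
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  if (length(unique(data$period)) < 2L)
    stop("at least two periods are required for a temporal trend")
  data$group <- factor(data$group)
  one_group <- nlevels(data$group) < 2L
  f <- stats::as.formula(paste(response, if (one_group) "~ period"
                               else "~ group * period"))
  fit <- nlme::gls(f, data = data,
                   correlation = nlme::corAR1(form = ~ period | species),
                   method = "ML")
  phi <- stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)
  list(fit = fit, phi = unname(phi), anova = stats::anova(fit))
}

#' Spearman rank correlation
#'
#' Mid-rank ties, t-approximation p-value; cross-checked in the test suite
#' against a rank-then-Pearson oracle.
#'
#' @param x,y numeric vectors (n >= 4).
#' @return list `rho`, `p`.
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Graft missing species onto a clade of an ultrametric tree
#'
#' Each species is attached at the midpoint of the stem branch of its
#' designated clade (which must be monophyletic), with the pendant branch
#' length chosen to restore ultrametricity. Pre-existing pairwise tip
#' distances are unchanged.
#'
#' @param tree ultrametric `ape::phylo`.
#' @param placements named list: new species name -> character vector of
#'   existing tip labels delimiting the clade (a single tip grafts a
#'   sister species at the midpoint of that tip's branch).
#' @return the expanded `phylo`.
#' @export
graftTips <- function(tree, placements) {
  for (sp in names(placements)) {
    tips <- placements[[sp]]
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss)) stop("placement tips not in tree: ",
                           paste(miss, collapse = ", "))
    if (sp %in% tree$tip.label) stop("tip '", sp, "' already present")
    H <- max(ape::node.depth.edgelength(tree))
    if (length(tips) == 1L) {
      node <- match(tips, tree$tip.label)
    } else {
      if (!ape::is.monophyletic(tree, tips))
        stop("placement clade for '", sp, "' is not monophyletic")
      node <- ape::getMRCA(tree, tips)
    }
    edge_i <- which(tree$edge[, 2L] == node)
    if (length(edge_i) == 0L)
      stop("clade for '", sp, "' is the root; cannot graft on its stem")
    stem <- tree$edge.length[edge_i]
    position <- stem / 2
    depths <- ape::node.depth.edgelength(tree)
    h_node <- depths[node]
    pendant <- H - (h_node - position)
    tree <- phytools::bind.tip(tree, sp, edge.length = pendant,
                               where = node, position = position)
  }
  tree
}
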