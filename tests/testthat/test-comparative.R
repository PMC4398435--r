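test_that("the VIF screen drops collinear traits and matches direct regression", {
  set.seed(61)
  n <- 80
  a <- rnorm(n); b <- rnorm(n); d <- rnorm(n)
  ortho <- data.frame(a = a, b = b, d = d)
  v <- vifScreen(ortho)
  expect_setequal(v$retained, c("a", "b", "d"))
  expect_true(all(v$vif < 1.5))
  dup <- data.frame(a = a, b = b, a2 = a)
  v2 <- vifScreen(dup)
  expect_length(v2$dropped, 1L)
  expect_true(v2$dropped %in% c("a", "a2"))
  # VIFs match 1/(1 - R^2) from explicit regressions
  cor3 <- data.frame(x = a, y = a * 0.8 + rnorm(n, 0, 0.5), z = d)
  r2x <- summary(lm(x ~ y + z, cor3))$r.squared
  v3 <- vifScreen(cor3, vif_cut = 1e9)
  expect_equal(unname(v3$vif["x"]), 1 / (1 - r2x), tolerance = 1e-10)
})

test_that("Brownian covariance and the lambda transform follow path lengths", {
  tre <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- bmCovariance(tre)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(unname(diag(V)), rep(2, 3))
  V0 <- lambdaTransform(V, 0)
  expect_equal(V0, diag(diag(V)), ignore_attr = TRUE)
  star <- ape::stree(5, "star")
  star$edge.length <- rep(3, 5)
  Vs <- bmCovariance(star)
  expect_equal(unname(Vs), diag(3, 5))
  expect_equal(lambdaTransform(Vs, 0.5), Vs, ignore_attr = TRUE)
})

test_that("PGLS on a star tree reproduces ordinary least squares", {
  set.seed(62)
  star <- ape::stree(25, "star")
  star$edge.length <- rep(2, 25)
  star$tip.label <- sprintf("s%02d", 1:25)
  d <- data.frame(species = star$tip.label, x = rnorm(25))
  d$y <- 1 + 0.7 * d$x + rnorm(25)
  f <- pglsFit(y ~ x, d, star)
  ols <- lm(y ~ x, d)
  expect_equal(f@coefTable$beta, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f@coefTable$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
})

test_that("PGLS profile ML agrees with the nlme/ape reference implementation", {
  g <- genComparative(n_tips = 60, lambda_true = 0.6, seed = 63)
  f <- pglsFit(y ~ x1 + x2, g$data, g$tree)
  dat <- g$data
  rownames(dat) <- dat$species
  ref <- nlme::gls(y ~ x1 + x2, dat,
                   correlation = ape::corPagel(0.5, g$tree, form = ~species),
                   method = "ML")
  lam_ref <- stats::coef(ref$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(f@lambda, unname(lam_ref), tolerance = 1e-4)
  expect_equal(f@coefTable$beta, unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f@logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  # lambda fixed at 0 equals regression with diagonal covariance
  f0 <- pglsFit(y ~ x1 + x2, g$data, g$tree, lambda = 0)
  V <- bmCovariance(g$tree)[g$data$species, g$data$species]
  wls <- lm(y ~ x1 + x2, g$data, weights = 1 / diag(V))
  expect_equal(f0@coefTable$beta, unname(coef(wls)), tolerance = 1e-8)
})

test_that("AICc arithmetic and Akaike weights are exact", {
  ll <- -12.3
  expect_equal(aicc(ll, k = 2, n = 10) - (-2 * ll + 2 * 2), 12 / 7)
  expect_error(aicc(ll, k = 5, n = 6), "undefined")
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(w[1], 1 / (1 + exp(-1)), tolerance = 1e-9)
})

test_that("all-subsets ranking matches exhaustive enumeration", {
  g <- genComparative(n_tips = 40, lambda_true = 1,
                      beta_true = c(x1 = 0.8, x2 = 0, x3 = -0.4),
                      seed = 64)
  dd <- dredgePGLS(y ~ x1 + x2 + x3, g$data, g$tree)
  expect_equal(nrow(dd$table), 8L)
  # oracle: refit every subset independently and rank
  subs <- list("1", "x1", "x2", "x3", "x1 + x2", "x1 + x3", "x2 + x3",
               "x1 + x2 + x3")
  or <- vapply(subs, function(s) {
    pglsFit(as.formula(paste("y ~", s)), g$data, g$tree)@aicc
  }, numeric(1))
  expect_equal(sort(dd$table$aicc), sort(or), tolerance = 1e-8)
  expect_equal(dd$table$model[1], subs[[order(or)[1]]])
  expect_equal(sum(dd$table$weight), 1)
  # weights depend only on AICc differences
  expect_equal(dd$table$weight,
               exp(-(dd$table$aicc - min(dd$table$aicc)) / 2) /
                 sum(exp(-(dd$table$aicc - min(dd$table$aicc)) / 2)))
})

test_that("model averaging substitutes zeros in full mode", {
  g <- genComparative(n_tips = 40, lambda_true = 1,
                      beta_true = c(x1 = 0.8, x2 = 0), seed = 65)
  dd <- dredgePGLS(y ~ x1 + x2, g$data, g$tree)
  avg <- modelAverage(dd)
  b_or <- vapply(seq_len(nrow(dd$table)), function(i) {
    ct <- dd$fits[[i]]@coefTable
    j <- match("x1", ct$term)
    if (is.na(j)) 0 else ct$beta[j]
  }, numeric(1))
  expect_equal(avg$beta_avg[avg$term == "x1"],
               sum(dd$table$weight * b_or), tolerance = 1e-10)
  cond <- modelAverage(dd, method = "conditional")
  has <- b_or != 0
  expect_equal(cond$beta_avg[cond$term == "x1"],
               sum((dd$table$weight * b_or)[has]) /
                 sum(dd$table$weight[has]), tolerance = 1e-10)
  expect_true(all(avg$importance >= 0 & avg$importance <= 1))
})

test_that("an injected gross outlier is flagged and removal refits once", {
  g <- genComparative(n_tips = 50, lambda_true = 1, sigma = 0.5, seed = 66)
  d <- g$data
  d$y[7] <- d$y[7] + 10 * 0.5 * sqrt(max(diag(bmCovariance(g$tree))))
  fit <- pglsFit(y ~ x1 + x2, d, g$tree)
  rs <- studentizedResiduals(fit)
  expect_true(7 %in% attr(rs, "flagged"))
  out <- refitWithoutOutliers(y ~ x1 + x2, d, g$tree)
  expect_true(d$species[7] %in% out$removed)
  expect_equal(out$fit@n, fit@n - length(out$removed))
  # flagging is invariant to row order
  perm <- sample(nrow(d))
  fit_p <- pglsFit(y ~ x1 + x2, d[perm, ], g$tree)
  rs_p <- studentizedResiduals(fit_p)
  expect_setequal(names(rs_p)[attr(rs_p, "flagged")],
                  names(rs)[attr(rs, "flagged")])
  # clean data rarely flags anything
  clean <- refitWithoutOutliers(y ~ x1 + x2, g$data, g$tree)
  expect_lte(length(clean$removed), 1L)
})

test_that("residual normality uses whitened residuals", {
  g <- genComparative(n_tips = 50, lambda_true = 1, seed = 67)
  fit <- pglsFit(y ~ x1 + x2, g$data, g$tree)
  p <- residualNormality(fit)
  expect_gt(p, 1e-4)  # correctly specified model
})

test_that("tip grafting restores ultrametricity and preserves distances", {
  tre <- ape::read.tree(text = "((A:6,B:6):4,C:10);")
  coph0 <- ape::cophenetic.phylo(tre)
  out <- graftTips(tre, list(newsp = c("A", "B")))
  # clade stem 4, tree depth 10: attach at the stem midpoint, pendant 8
  ed <- out$edge.length[out$edge[, 2] == which(out$tip.label == "newsp")]
  expect_equal(ed, 8)
  expect_true(ape::is.ultrametric(out, tol = 1e-9))
  coph1 <- ape::cophenetic.phylo(out)
  expect_equal(coph1[rownames(coph0), colnames(coph0)], coph0)
  # grafting then pruning recovers the original metric
  back <- ape::drop.tip(out, "newsp")
  expect_equal(ape::cophenetic.phylo(back)[rownames(coph0), colnames(coph0)],
               coph0)
  expect_error(graftTips(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
                         list(x = c("A", "C"))), "not monophyletic")
  # sister grafting onto a single tip
  one <- graftTips(tre, list(sis = "C"))
  expect_true(ape::is.ultrametric(one, tol = 1e-9))
  expect_true("sis" %in% one$tip.label)
})

test_that("GLS trends reduce to OLS without autocorrelation and refuse one period", {
  set.seed(68)
  d <- expand.grid(species = paste0("s", 1:6), period = 1:5)
  d$group <- rep(c("g1", "g2"), each = 3)[match(d$species,
                                                paste0("s", 1:6))]
  d$y <- 0.5 * d$period + ifelse(d$group == "g2", 0.3 * d$period, 0) +
    rnorm(nrow(d), 0, 0.3)
  tr <- glsTrend(d, "y")
  expect_lt(abs(tr$phi), 0.6)
  ols <- lm(y ~ group * period, d)
  expect_equal(unname(coef(tr$fit)), unname(coef(ols)), tolerance = 0.25)
  expect_true(all(c("group", "period", "group:period") %in%
                    rownames(tr$anova)))
  expect_error(glsTrend(d[d$period == 1, ], "y"), "two periods")
})

test_that("AR(1) trend errors are recovered from simulated series", {
  set.seed(69)
  ok <- 0L
  for (i in 1:20) {
    d <- do.call(rbind, lapply(1:3, function(s) {
      e <- as.numeric(arima.sim(list(ar = 0.6), 20))
      data.frame(species = paste0("s", s), group = "g1", period = 1:20,
                 y = 0.2 * (1:20) + e)
    }))
    phi <- glsTrend(d, "y")$phi
    if (phi >= 0.4 && phi <= 0.8) ok <- ok + 1L
  }
  expect_gte(ok, 16L)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(rankCorrelation(x, x)$rho, 1)
  expect_equal(rankCorrelation(x, -x)$rho, -1)
  set.seed(70)
  for (i in 1:10) {
    a <- sample(20); b <- rnorm(20)
    expect_equal(rankCorrelation(a, b)$rho, cor(rank(a), rank(b)),
                 tolerance = 1e-10)
  }
  expect_error(rankCorrelation(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(rankCorrelation(1:3, 1:3), "n >= 4")
})
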