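test_that("feature expansion has the right size, order and [0,1] scaling", {
  d <- data.frame(a = runif(50), b = runif(50), cc = runif(50))
  e <- expandFeatures(d, c("a", "b", "cc"))
  expect_equal(ncol(e$Z), 9L)  # p + p + choose(p, 2)
  expect_equal(e$featKind, rep(c("linear", "quadratic", "product"), each = 3))
  expect_equal(colnames(e$Z),
               c("a", "b", "cc", "a^2", "b^2", "cc^2", "a*b", "a*cc", "b*cc"))
  expect_true(all(e$Z >= 0 & e$Z <= 1))
  expect_true(all(apply(e$Z, 2, min) == 0) && all(apply(e$Z, 2, max) == 1))
  e1 <- expandFeatures(d["a"], "a")
  expect_equal(ncol(e1$Z), 2L)
  d$k <- 5
  expect_warning(e2 <- expandFeatures(d, c("a", "k")), "constant")
  expect_equal(e2$baseVars, "a")
})

test_that("projection features are clamped into the training range", {
  d <- data.frame(a = 1:10, b = 10:1)
  e <- expandFeatures(d, c("a", "b"))
  new <- data.frame(a = c(-5, 20), b = c(0, 100))
  Z <- expandFeatures(new, c("a", "b"), expansion = e)$Z
  expect_true(all(Z >= 0 & Z <= 1))
  expect_equal(unname(Z[1, "a"]), 0)
  expect_equal(unname(Z[2, "a"]), 1)
})

test_that("replication scheme follows the record-count rules", {
  expect_equal(chooseReplication(29), "bootstrap10")
  expect_equal(chooseReplication(30), "cv4fold")
  expect_equal(chooseReplication(5), "insufficient")
  expect_equal(chooseReplication(8), "bootstrap10")
})

test_that("no-signal data shrinks coefficients and the heavy penalty zeroes them", {
  set.seed(11)
  bg <- data.frame(x = runif(400), w = runif(400))
  pr <- data.frame(x = runif(80), w = runif(80))
  m <- fitPBModel(pr, bg, c("x", "w"))
  expect_true(m@converged)
  # the fitted model has essentially no discriminative power
  met <- computeMetrics(c(tp = 1, fp = 1, fn = 1, tn = 1),
                        predictPB(m, pr), predictPB(m, bg))
  expect_lt(abs(met$auc - 0.5), 0.12)
  p <- predictPB(m, bg, type = "raw")
  expect_lt(max(p) / min(p), 10)  # near-uniform prediction
  m_inf <- fitPBModel(pr, bg, c("x", "w"), beta_reg = 1e6)
  expect_identical(unname(m_inf@beta), rep(0, 5))
})

test_that("a concentrated presence signal yields a positive linear coefficient", {
  set.seed(12)
  bg <- data.frame(x = runif(400), w = runif(400))
  pr <- data.frame(x = rbeta(80, 6, 1.5), w = runif(80))
  m <- fitPBModel(pr, bg, c("x", "w"))
  expect_gt(m@beta[1], 0)  # linear term on x
  expect_gt(mean(predictPB(m, pr)), mean(predictPB(m, bg)))
})

test_that("raw output is a density over the training background", {
  set.seed(13)
  bg <- data.frame(x = runif(300), w = runif(300))
  pr <- data.frame(x = rbeta(50, 4, 2), w = runif(50))
  m <- fitPBModel(pr, bg, c("x", "w"))
  expect_equal(sum(predictPB(m, bg, type = "raw")), 1, tolerance = 1e-6)
  expect_true(all(predictPB(m, bg) >= 0 & predictPB(m, bg) <= 1))
})

test_that("the penalized fit matches an independent generic-optimizer solution", {
  set.seed(14)
  for (i in 1:3) {
    bg <- data.frame(x = runif(150), w = runif(150))
    pr <- data.frame(x = rbeta(50, 5, 1.5), w = runif(50, 0, 1)^(1 + i / 3))
    m <- fitPBModel(pr, bg, c("x", "w"), tol = 1e-8)
    tr <- expandFeatures(rbind(pr, bg), c("x", "w"))
    Zp <- tr$Z[1:50, ]; Zb <- tr$Z[-(1:50), ]
    lam <- m@regLambda; K <- ncol(Zp)
    # split beta = p - q, p,q >= 0: the same objective, smooth and
    # box-constrained, solved by a generic quasi-Newton optimizer
    obj <- function(pq) {
      b <- pq[1:K] - pq[K + 1:K]
      -mean(Zp %*% b) + log(sum(exp(Zb %*% b))) +
        sum(lam * (pq[1:K] + pq[K + 1:K]))
    }
    gr <- function(pq) {
      b <- pq[1:K] - pq[K + 1:K]
      u <- drop(Zb %*% b); w <- exp(u - max(u)); w <- w / sum(w)
      g <- drop(crossprod(Zb, w)) - colMeans(Zp)
      c(g + lam, -g + lam)
    }
    o <- optim(rep(0, 2 * K), obj, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 20000, factr = 10))
    b_oracle <- o$par[1:K] - o$par[K + 1:K]
    expect_lt(max(abs(b_oracle - m@beta)), 1e-3)
  }
})

test_that("replicate sets obey their schemes and are seed-reproducible", {
  set.seed(15)
  bg <- data.frame(x = runif(200), w = runif(200), period = "post1950")
  pr <- data.frame(x = rbeta(40, 4, 2), w = runif(40), period = "post1950")
  cv <- fitReplicates("cv4fold", pr, bg, c("x", "w"), seed = 2)
  expect_length(cv@models, 4L)
  folds <- cv@testIdx
  expect_equal(sort(unlist(folds)), 1:40)
  expect_equal(unname(lengths(folds)), rep(10L, 4))
  cv2 <- fitReplicates("cv4fold", pr, bg, c("x", "w"), seed = 2)
  expect_identical(cv@testIdx, cv2@testIdx)
  bt <- fitReplicates("bootstrap10", pr[1:20, ], bg, c("x", "w"), seed = 3)
  expect_length(bt@models, 10L)
  expect_true(all(vapply(bt@testIdx, function(i) all(i <= 20), logical(1))))
})

test_that("map prediction is consistent with row prediction and propagates nodata", {
  set.seed(16)
  sw <- tinyStacks()
  st <- sw$post1950
  st@layers$temp[4, 4] <- NA
  st@layers$prec[4, 4] <- NA
  cc <- cellCenter(st, c(1, 5, 10), c(2, 6, 9))
  pr <- extractSWD(data.frame(lon = cc[, 1], lat = cc[, 2],
                              period = "post1950"), list(post1950 = st))
  allcc <- cellCenter(st, rep(1:10, 10), rep(1:10, each = 10))
  bg <- extractSWD(data.frame(lon = allcc[, 1], lat = allcc[, 2],
                              period = "post1950"), list(post1950 = st))
  m <- fitPBModel(pr, bg, c("temp", "prec"))
  pred <- predictMap(m, st)
  expect_true(is.na(pred[4, 4]))
  ci <- cellIndex(st, pr$lon, pr$lat)
  expect_equal(pred[ci], predictPB(m, pr))
  # a zero-coefficient model predicts a constant map
  m0 <- m; m0@beta[] <- 0
  p0 <- predictMap(m0, st)
  expect_equal(max(p0, na.rm = TRUE), min(p0, na.rm = TRUE))
})

test_that("the fitted model ranks truth-suitable cells above background", {
  stacks <- genClimate(dims = c(80L, 80L), seed = 31)
  vs <- genVirtualSpecies("v", gaussianNicheCoefs("temp", 17, 1.5),
                          stacks, n_presences = 200, seed = 32)
  rec <- assignPeriod(vs$records)
  sw <- list(pre1950 = stacks$past, post1950 = stacks$current)
  pres <- extractSWD(rec, sw)
  set.seed(33)
  idx <- sample(80 * 80, 2000)
  g <- stacks$current
  cc <- cellCenter(g, (idx - 1) %% 80 + 1, (idx - 1) %/% 80 + 1)
  bg <- extractSWD(data.frame(lon = cc[, 1], lat = cc[, 2],
                              period = "post1950"), sw)
  m <- fitPBModel(pres, bg, c("temp", "prec", "seas", "soil"))
  pred <- predictMap(m, stacks$current)
  tb <- vs$truth >= 0.5
  met <- computeMetrics(c(tp = 1, fp = 1, fn = 1, tn = 1),
                        pred[tb], pred[!tb])
  expect_gt(met$auc, 0.9)
})
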