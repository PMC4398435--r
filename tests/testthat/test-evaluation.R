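test_that("the 10-percentile training presence threshold uses lower interpolation", {
  expect_equal(threshold10ptp(seq(0.1, 1, by = 0.1)), 0.1)
  v <- seq(0.1, 1, by = 0.1)
  tau <- threshold10ptp(v)
  expect_equal(sum(v <= tau), 1L)  # exactly one training presence at the cut
  expect_equal(threshold10ptp(rep(0.42, 7)), 0.42)
  expect_equal(threshold10ptp(0.9), 0.9)
  expect_equal(threshold10ptp(seq(0.01, 1, by = 0.01)), 0.1)
  expect_error(threshold10ptp(numeric()), "no training presence")
})

test_that("confusion counts match a per-point tally", {
  set.seed(21)
  for (i in 1:5) {
    pp <- runif(40) > 0.3
    pb <- runif(70) > 0.6
    cm <- confusionCounts(pp, pb)
    expect_equal(unname(cm["tp"]), sum(pp == TRUE))
    expect_equal(unname(cm["fn"]), sum(pp == FALSE))
    expect_equal(unname(cm["fp"]), sum(pb == TRUE))
    expect_equal(unname(cm["tn"]), sum(pb == FALSE))
  }
  expect_error(confusionCounts(logical(), TRUE), "at least one")
})

test_that("metrics reproduce Cohen's kappa and the TSS identity", {
  met <- computeMetrics(c(tp = 40, fp = 10, fn = 10, tn = 40))
  expect_equal(met$sensitivity, 0.8)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$proportion_correct, 0.8)
  expect_equal(met$kappa, 0.6)  # Po = .8, Pe = .5
  expect_equal(met$tss, 0.6)
  expect_equal(met$omission_rate, 0.2)
  perfect <- computeMetrics(c(tp = 30, fp = 0, fn = 0, tn = 60),
                            score_presence = runif(30, 0.6, 1),
                            score_background = runif(60, 0, 0.5))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$tss, 1)
  expect_equal(perfect$auc, 1)
  degen <- computeMetrics(c(tp = 30, fp = 0, fn = 0, tn = 0))
  expect_true(degen$degenerate)
  expect_equal(degen$kappa, 0)
})

test_that("rank AUC equals the trapezoidal ROC area including ties", {
  set.seed(22)
  for (i in 1:20) {
    sp <- round(runif(30), 2)  # rounding forces ties
    sb <- round(runif(50), 2)
    met <- computeMetrics(c(tp = 1, fp = 1, fn = 1, tn = 1), sp, sb)
    expect_equal(met$auc, rocAreaOracle(sp, sb), tolerance = 1e-9)
  }
})

test_that("the validation gate reproduces the joint expert/kappa truth table", {
  cases <- expand.grid(kappa = c(0.6, 0.39),
                       rating = c("good", "medium", "poor"),
                       stringsAsFactors = FALSE)
  want <- with(cases, ifelse(kappa > 0.4 & rating != "poor",
                             "modellable", "unmodellable"))
  got <- mapply(function(k, r) validationGate(k, r)$decision,
                cases$kappa, cases$rating)
  expect_equal(unname(got), want)
  expect_equal(validationGate(0.4, "good")$decision, "unmodellable")
  expect_warning(out <- validationGate(0.6, NA), "missing expert")
  expect_equal(out$decision, "unresolved")
})

test_that("variant selection follows the expert, then kappa with deterministic ties", {
  k <- c(i = 0.5, ii = 0.7, iii = 0.6, iv = 0.7)
  expect_equal(selectVariant(k, expert_choice = "iii"), "iii")
  expect_equal(selectVariant(k), "ii")  # habitat-restricted beats iv on tie
  expect_equal(selectVariant(c(i = 0.9, iii = 0.9)), "i")
  expect_equal(selectVariant(c(iv = 0.2)), "iv")
  expect_error(selectVariant(c(i = 0.5), expert_choice = "ii"), "not fitted")
})

test_that("replicate evaluation averages across models and supports held-out scoring", {
  set.seed(23)
  bg <- data.frame(x = runif(300), w = runif(300), period = "post1950")
  pr <- data.frame(x = rbeta(40, 6, 1.5), w = runif(40), period = "post1950")
  reps <- fitReplicates("cv4fold", pr, bg, c("x", "w"), seed = 4)
  m_all <- evaluateReplicates(reps, pr, bg)
  m_ho <- evaluateReplicates(reps, pr, bg, points = "heldout")
  expect_equal(m_all$n_replicates, 4L)
  expect_true(m_all$kappa >= -1 && m_all$kappa <= 1)
  expect_equal(m_all$tss, m_all$sensitivity + m_all$specificity - 1)
  expect_equal(m_ho$tss, m_ho$sensitivity + m_ho$specificity - 1)
  expect_gt(m_all$auc, 0.5)
})
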