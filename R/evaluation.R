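## Threshold-dependent model evaluation and the joint expert/Kappa gate.
## Background points are treated as absences when tallying the confusion
## matrix, as is standard for presence-background evaluation; kappa corrects
## the proportion of correct predictions for chance agreement from the
## marginals, and the gate admits a species only when kappa exceeds 0.4 AND
## the species expert rated the mapped range good or medium.

#' Ten-percentile training presence threshold
#'
#' The suitability value below which the lowest 10 percent of training
#' presences fall, computed with the lower-interpolation (type 1) percentile
#' convention on the sorted training presence suitabilities: the threshold
#' is the `ceiling(0.1 n)`-th smallest value. Cells with suitability at or
#' above the threshold are classed presence.
#'
#' @param train_suit numeric vector of training presence suitabilities.
#' @param percentile percentile (default 10).
#' @return numeric threshold.
#' @export
threshold10ptp <- function(train_suit, percentile = 10) {
  if (length(train_suit) == 0L) stop("no training presence values")
  s <- sort(train_suit)
  s[max(1L, ceiling(percentile / 100 * length(s)))]
}

#' Confusion counts from binary predictions
#'
#' Presences supply tp/fn; background points, treated as absences, supply
#' tn/fp.
#'
#' @param pred_presence logical: predicted presence at each test presence.
#' @param pred_background logical: predicted presence at each background
#'   point.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(pred_presence, pred_background) {
  if (length(pred_presence) < 1L || length(pred_background) < 1L)
    stop("need at least one presence and one background evaluation point")
  c(tp = sum(pred_presence), fp = sum(pred_background),
    fn = sum(!pred_presence), tn = sum(!pred_background))
}

#' Threshold-dependent metrics plus rank AUC
#'
#' Computes sensitivity tp/(tp+fn), specificity tn/(tn+fp), omission rate
#' fn/(tp+fn), proportion correct (tp+tn)/N, Cohen's kappa
#' (Po - Pe)/(1 - Pe) with Pe from the marginal products, the True Skill
#' Statistic sensitivity + specificity - 1, and (when continuous scores are
#' supplied) AUC as the Mann-Whitney statistic
#' P(score_presence > score_background) + P(tie)/2.
#'
#' @param counts output of [confusionCounts()].
#' @param score_presence,score_background optional continuous scores for
#'   AUC; AUC is NA when absent.
#' @return named list: auc, omission_rate, sensitivity, specificity,
#'   proportion_correct, kappa, tss, degenerate (TRUE when the chance
#'   agreement Pe is 1 and kappa is reported as 0).
#' @export
computeMetrics <- function(counts, score_presence = NULL,
                           score_background = NULL) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty confusion counts")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  degenerate <- abs(1 - pe) < 1e-12
  kappa <- if (degenerate) 0 else (po - pe) / (1 - pe)
  auc <- NA_real_
  if (!is.null(score_presence) && !is.null(score_background)) {
    r <- rank(c(score_presence, score_background))
    n1 <- length(score_presence); n0 <- length(score_background)
    auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(auc = auc, omission_rate = fn / (tp + fn), sensitivity = sens,
       specificity = spec, proportion_correct = po, kappa = kappa,
       tss = sens + spec - 1, degenerate = degenerate)
}

#' Replicate-averaged evaluation of a fitted species model
#'
#' For each replicate, thresholds the training-presence suitabilities at the
#' 10-percentile training presence rule, classifies the evaluation points
#' against the background, and averages the metrics across replicates.
#' With `points = "all"` (default) every input presence record is scored —
#' the convention of computing accuracy from input species records and
#' background points; with `points = "heldout"` only the replicate's
#' held-out presences are scored (bootstrap replicates with no out-of-bag
#' rows are then skipped). Held-out scoring makes kappa strongly dependent
#' on the test-fold/background imbalance, so the gate statistic uses the
#' full record set.
#'
#' @param reps a [ReplicateSet-class].
#' @param presence,background SWD data.frames used for the fit.
#' @param percentile threshold percentile (default 10).
#' @param points "all" or "heldout".
#' @return named list of averaged metrics plus `threshold` (mean) and
#'   `n_replicates` used.
#' @export
evaluateReplicates <- function(reps, presence, background, percentile = 10,
                               points = c("all", "heldout")) {
  points <- match.arg(points)
  acc <- NULL; nrep <- 0L; thr_all <- numeric()
  for (r in seq_along(reps@models)) {
    m <- reps@models[[r]]
    test_idx <- if (points == "all") seq_len(nrow(presence))
    else reps@testIdx[[r]]
    if (length(test_idx) == 0L) next
    train_scores <- predictPB(m, presence)
    thr <- threshold10ptp(train_scores, percentile)
    sp <- predictPB(m, presence[test_idx, , drop = FALSE])
    sb <- predictPB(m, background)
    met <- computeMetrics(confusionCounts(sp >= thr, sb >= thr), sp, sb)
    met$degenerate <- NULL
    acc <- if (is.null(acc)) met else Map(`+`, acc, met)
    nrep <- nrep + 1L
    thr_all <- c(thr_all, thr)
  }
  if (nrep == 0L) stop("no replicate had held-out presences")
  out <- lapply(acc, `/`, nrep)
  out$threshold <- mean(thr_all)
  out$n_replicates <- nrep
  out
}

#' The joint expert/Kappa validation gate
#'
#' A species is modellable if and only if its kappa exceeds `kappa_cut`
#' (default 0.4) AND its expert rating is good or medium; a kappa at or
#' below the cut, or a rating of poor, makes it unmodellable. A missing
#' rating leaves the species unresolved (excluded, with a warning).
#'
#' @param kappa numeric kappa value.
#' @param rating "good", "medium", "poor", or NA.
#' @param kappa_cut gate threshold (default 0.4).
#' @return list with `decision` ("modellable"/"unmodellable"/"unresolved"),
#'   `kappa`, `rating`.
#' @export
validationGate <- function(kappa, rating, kappa_cut = 0.4) {
  if (is.na(rating)) {
    warning("missing expert rating; species left unresolved")
    return(list(decision = "unresolved", kappa = kappa, rating = NA))
  }
  rating <- match.arg(rating, c("good", "medium", "poor"))
  ok <- (kappa > kappa_cut) && rating %in% c("good", "medium")
  list(decision = if (ok) "modellable" else "unmodellable",
       kappa = kappa, rating = rating)
}

#' Select the model variant carried forward to projection
#'
#' Four variants are assessed per species: i) pre+post-1950 data, climate
#' only; ii) pre+post-1950 data, restricted to occupied land classes;
#' iii) post-1950 data only, climate only; iv) post-1950 data only,
#' habitat-restricted. The species expert's choice wins outright; absent an
#' expert choice the highest kappa wins, ties broken deterministically by
#' preferring habitat restriction (ii/iv over i/iii) and then pre+post input
#' data (ii over iv, i over iii).
#'
#' @param kappas named numeric vector with names among `c("i","ii","iii","iv")`
#'   (variants actually fitted).
#' @param expert_choice the expert's variant, or NA.
#' @return the selected variant label.
#' @export
selectVariant <- function(kappas, expert_choice = NA) {
  stopifnot(length(kappas) >= 1L, all(names(kappas) %in% c("i", "ii", "iii",
                                                           "iv")))
  if (!is.na(expert_choice)) {
    if (!expert_choice %in% names(kappas))
      stop("expert chose variant '", expert_choice, "' which was not fitted")
    return(expert_choice)
  }
  pref <- c(ii = 1L, iv = 2L, i = 3L, iii = 4L)  # tie-break order
  ord <- order(-kappas, pref[names(kappas)])
  names(kappas)[ord[1L]]
}

#' Read an expert ratings CSV
#'
#' Expected header: `species,rating,chosen_variant` with rating in
#' good/medium/poor and chosen_variant in i-iv (empty allowed).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readRatings <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA",
                                                                      ""))
  need <- c("species", "rating", "chosen_variant")
  if (!all(need %in% names(x)))
    stop("ratings CSV must have columns ", paste(need, collapse = ", "))
  bad <- !x$rating %in% c("good", "medium", "poor") & !is.na(x$rating)
  if (any(bad)) stop("invalid rating values: ",
                     paste(unique(x$rating[bad]), collapse = ", "))
  x
}
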