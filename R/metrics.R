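# Evaluation metrics: binary and multi-label AUC, G-mean threshold selection,
# confusion-matrix summaries, and rank-based empirical significance.

#' Binary AUC against same-base negatives
#'
#' Area under the ROC computed over the finite set of observed score
#' thresholds, which equals the Mann-Whitney pairwise probability
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param pos_scores,neg_scores Numeric score vectors (both non-empty).
#' @return AUC in \[0, 1\].
#' @examples
#' auc_b(c(0.9, 0.4), c(0.6, 0.1))  # 0.75
#' @export
auc_b <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("auc_b needs non-empty positive and negative score sets")
  }
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Multi-label AUC against all other labels and unmodifiable bases
#'
#' Same rank estimator as [auc_b()], but the negative pool mixes every other
#' sample: other modifications and unmodifiable nucleotides of all four
#' bases. Because rejecting a non-original base is easy, this AUC is
#' typically substantially higher than the binary one.
#'
#' @param pos_scores Scores of the label's positives.
#' @param all_other_scores Scores of the widened negative pool.
#' @return AUC in \[0, 1\].
#' @export
auc_m <- function(pos_scores, all_other_scores) {
  if (length(all_other_scores) == 0) stop("empty negative pool")
  auc_b(pos_scores, all_other_scores)
}

#' Classification threshold maximizing the G-mean
#'
#' Scans the ROC operating points (the finite set of observed scores) and
#' returns the threshold with the largest sqrt(sensitivity x specificity);
#' ties are broken toward higher specificity. A score is called positive when
#' it is >= the threshold.
#'
#' @param pos_scores,neg_scores Numeric score vectors.
#' @return List with `threshold`, `gmean`, `sn`, `sp`.
#' @export
gmean_threshold <- function(pos_scores, neg_scores) {
  cand <- sort(unique(c(pos_scores, neg_scores, Inf)))
  best <- list(threshold = cand[1], gmean = -1, sn = NA, sp = NA)
  for (thr in cand) {
    sn <- mean(pos_scores >= thr)
    sp <- mean(neg_scores < thr)
    g <- sqrt(sn * sp)
    if (g > best$gmean || (g == best$gmean && sp > best$sp)) {
      best <- list(threshold = thr, gmean = g, sn = sn, sp = sp)
    }
  }
  best
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total and the Matthews
#' correlation coefficient. A zero denominator in the MCC yields 0 with a
#' `degenerate` flag.
#'
#' @param tp,tn,fp,fn Nonnegative confusion counts.
#' @return List with `sn`, `sp`, `acc`, `mcc` and logical `degenerate`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(den)
  list(sn = sn, sp = sp, acc = acc, mcc = mcc, degenerate = degenerate)
}

#' Background score table for significance bounds
#'
#' Scores a set of negative windows with the model and stores, per label, the
#' sorted score sample of negatives on that label's original base. Persisted
#' with the checkpoint so server-style prediction is reproducible.
#'
#' @param model Trained `rm_model`.
#' @param negatives `rm_windows` data.frame of negative windows.
#' @return An `rm_background` object.
#' @export
build_background <- function(model, negatives) {
  stopifnot(nrow(negatives) > 0)
  probs <- predict(model, negatives)
  scores <- list()
  for (j in seq_len(12L)) {
    lab <- rm_label_names()[j]
    rows <- negatives$base == rm_labels()$base[j]
    if (any(rows)) scores[[lab]] <- sort(probs[rows, j])
  }
  structure(list(scores = scores, n = vapply(scores, length, integer(1))),
            class = "rm_background")
}

#' Rank-based empirical p-value upper bound
#'
#' The bound for a score is (number of background scores exceeding it + 1) /
#' (N + 1): if 1% of a large background of unmodified occurrences of the same
#' nucleotide scores higher, the site's p-value is bounded by (about) 0.01.
#' The add-one correction keeps the bound strictly positive for finite
#' backgrounds.
#'
#' @param score Numeric vector of predicted probabilities.
#' @param background `rm_background` from [build_background()], or a numeric
#'   vector of background scores.
#' @param label Modification label selecting the background pool (ignored
#'   when `background` is already a numeric vector).
#' @return P-value upper bounds in (0, 1\].
#' @export
empirical_pvalue_bound <- function(score, background, label = NULL) {
  bg <- if (is.numeric(background)) background else background$scores[[label]]
  if (is.null(bg) || length(bg) == 0) {
    stop("no background scores available", if (!is.null(label))
      paste0(" for label ", label))
  }
  N <- length(bg)
  # bg is sorted for table objects; findInterval counts <= score
  sbg <- if (is.unsorted(bg)) sort(bg) else bg
  n_greater <- N - findInterval(score, sbg)
  (n_greater + 1) / (N + 1)
}

#' Per-label evaluation report
#'
#' Computes, for every label with positives in the evaluation set: binary AUC
#' (positives vs same-base negative windows), multi-label AUC (positives vs
#' every other window), the G-mean-optimal threshold, and Sn/Sp/Acc/MCC at
#' that threshold; mean and median rows summarize across labels.
#'
#' @param model Trained `rm_model`.
#' @param windows `rm_windows` evaluation set (e.g. the test split).
#' @return An `rm_eval` data.frame with one row per label plus mean/median.
#' @export
eval_report <- function(model, windows) {
  probs <- predict(model, windows)
  labels <- rm_window_labels(windows)
  rows <- list()
  for (j in seq_len(12L)) {
    lab <- rm_label_names()[j]
    base_j <- rm_labels()$base[j]
    pos <- labels[, j] == 1L
    neg <- rowSums(labels) == 0L & windows$base == base_j
    if (!any(pos) || !any(neg)) next
    ps <- probs[pos, j]
    ns <- probs[neg, j]
    other <- !pos
    ab <- auc_b(ps, ns)
    am <- auc_m(ps, probs[other, j])
    th <- gmean_threshold(ps, ns)
    cm <- confusion_metrics(tp = sum(ps >= th$threshold),
                            tn = sum(ns < th$threshold),
                            fp = sum(ns >= th$threshold),
                            fn = sum(ps < th$threshold))
    rows[[lab]] <- data.frame(label = lab, n_pos = sum(pos), n_neg = sum(neg),
                              threshold = th$threshold, sn = cm$sn, sp = cm$sp,
                              acc = cm$acc, mcc = cm$mcc, auc_b = ab,
                              auc_m = am, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  if (is.null(rep)) stop("no label in the evaluation set has both positives and matched negatives")
  num <- c("threshold", "sn", "sp", "acc", "mcc", "auc_b", "auc_m")
  mean_row <- data.frame(label = "mean", n_pos = NA, n_neg = NA,
                         t(colMeans(rep[num])), stringsAsFactors = FALSE)
  med_row <- data.frame(label = "median", n_pos = NA, n_neg = NA,
                        t(apply(rep[num], 2, median)), stringsAsFactors = FALSE)
  names(mean_row)[-(1:3)] <- num
  names(med_row)[-(1:3)] <- num
  out <- rbind(rep, mean_row, med_row)
  rownames(out) <- NULL
  class(out) <- c("rm_eval", "data.frame")
  out
}

#' Optional multi-label scheme metrics
#'
#' Standard multi-label summaries over the 12-slot predictions at a fixed
#' probability cutoff: Hamming loss, subset accuracy, micro precision/recall/
#' F1. Labels not applicable to a window's base are excluded.
#'
#' @param probs B x 12 probability matrix.
#' @param labels B x 12 binary matrix.
#' @param bases Character vector of center bases.
#' @param cutoff Probability cutoff (default 0.5).
#' @return Named list of scalar metrics.
#' @export
multilabel_metrics <- function(probs, labels, bases, cutoff = 0.5) {
  mask <- rm_base_mask(bases)
  pred <- (probs >= cutoff) & mask
  truth <- labels == 1L & mask
  hamming <- sum((pred != truth) & mask) / sum(mask)
  subset_acc <- mean(vapply(seq_len(nrow(probs)), function(b) {
    all(pred[b, mask[b, ]] == truth[b, mask[b, ]])
  }, logical(1)))
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth & mask)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(hamming_loss = hamming, subset_accuracy = subset_acc,
       micro_precision = prec, micro_recall = rec, micro_f1 = f1)
}
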