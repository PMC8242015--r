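# brute-force oracle: all positive-negative pairs
auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

test_that("binary AUC equals the Mann-Whitney pairwise probability", {
  expect_equal(auc_b(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_equal(auc_b(c(5, 6, 7), c(1, 2, 3)), 1.0)     # perfect separation
  expect_equal(auc_b(c(1, 2, 3), c(1, 2, 3)), 0.5)     # exchangeable
  expect_error(auc_b(numeric(0), 1), "non-empty")
})

test_that("binary AUC matches all-pairs counting on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    np <- sample(1:50, 1)
    nn <- sample(1:50, 1)
    # coarse grid induces plenty of ties
    pos <- sample(seq(0, 1, by = 0.1), np, replace = TRUE) + rnorm(np, 0, 0.2)
    neg <- sample(seq(0, 1, by = 0.1), nn, replace = TRUE)
    expect_equal(auc_b(pos, neg), auc_pairs(pos, neg), tolerance = 1e-12)
  }
})

test_that("multi-label AUC cannot drop when dominated negatives join the pool", {
  set.seed(11)
  pos <- runif(30, 0.6, 1)
  neg <- runif(30, 0.2, 0.7)
  dominated <- runif(50, 0, 0.15)  # trivially rejected non-original-base cases
  expect_gte(auc_m(pos, c(neg, dominated)), auc_b(pos, neg))
  expect_equal(auc_m(1, runif(20, 0, 0.9)), 1.0)
  set.seed(12)
  expect_equal(auc_m(runif(1e4), runif(1e4)), 0.5, tolerance = 0.02)
})

test_that("the G-mean threshold attains the enumerated optimum", {
  g <- gmean_threshold(c(0.8, 0.7), c(0.3, 0.2))
  expect_equal(g$gmean, 1.0)
  expect_true(g$threshold > 0.3 && g$threshold <= 0.7)
  sep <- gmean_threshold(c(10, 11), c(1, 2))
  expect_equal(sep$gmean, 1.0)
  # enumeration oracle on a random instance
  set.seed(4)
  pos <- runif(25)
  neg <- runif(25, 0, 0.8)
  g2 <- gmean_threshold(pos, neg)
  cand <- sort(unique(c(pos, neg, Inf)))
  best <- max(sapply(cand, function(t) sqrt(mean(pos >= t) * mean(neg < t))))
  expect_equal(g2$gmean, best, tolerance = 1e-12)
  # degenerate: all scores identical -> better of the two trivial calls
  gd <- gmean_threshold(rep(0.5, 3), rep(0.5, 3))
  expect_equal(gd$gmean, 0)
})

test_that("confusion metrics follow their closed forms", {
  m <- confusion_metrics(tp = 10, tn = 10, fp = 10, fn = 10)
  expect_equal(m$sn, 0.5)
  expect_equal(m$sp, 0.5)
  perfect <- confusion_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)
  m2 <- confusion_metrics(tp = 45, tn = 40, fp = 10, fn = 5)
  expect_equal(m2$sn, 45 / 50)
  expect_equal(m2$sp, 40 / 50)
  expect_equal(m2$acc, 85 / 100)
  expect_equal(m2$mcc, (45 * 40 - 10 * 5) / sqrt(55 * 50 * 50 * 45))
  degen <- confusion_metrics(tp = 0, tn = 10, fp = 0, fn = 0)
  expect_equal(degen$mcc, 0)
  expect_true(degen$degenerate)
})

test_that("MCC flips sign when predictions are complemented", {
  for (seed in 1:20) {
    set.seed(seed)
    cm <- as.list(setNames(sample(1:30, 4, replace = TRUE),
                           c("tp", "tn", "fp", "fn")))
    a <- do.call(confusion_metrics, cm)
    b <- confusion_metrics(tp = cm$fn, tn = cm$fp, fp = cm$tn, fn = cm$tp)
    expect_equal(a$mcc, -b$mcc, tolerance = 1e-12)
  }
})

test_that("the empirical p-value bound counts exceeding background scores", {
  expect_equal(empirical_pvalue_bound(0.55, seq(0.1, 1, by = 0.1)), 6 / 11)
  bg <- runif(500)
  expect_equal(empirical_pvalue_bound(2, bg), 1 / 501)  # above everything
  # score exceeded by exactly 1% of a large background
  bg2 <- c(seq(0, 0.89, length.out = 9900), seq(0.91, 1, length.out = 100))
  expect_equal(empirical_pvalue_bound(0.9, bg2), 101 / 10001)
})

test_that("the p-value bound is monotone in score and permutation invariant", {
  set.seed(3)
  bg <- rnorm(200)
  scores <- sort(rnorm(50))
  p <- empirical_pvalue_bound(scores, bg)
  expect_true(all(diff(p) <= 0))
  p2 <- empirical_pvalue_bound(scores, sample(bg))
  expect_equal(p, p2)
  expect_true(all(p > 0 & p <= 1))
  expect_error(empirical_pvalue_bound(0.5, numeric(0)), "no background")
})

test_that("the evaluation report summarizes each label with both AUC flavors", {
  model <- fixture_model()
  rep <- eval_report(model, fixture_split()$test)
  expect_s3_class(rep, "rm_eval")
  expect_setequal(setdiff(rep$label, c("mean", "median")), c("m6A", "m5C"))
  expect_true(all(rep$auc_b >= 0 & rep$auc_b <= 1))
  expect_true(all(rep$mcc >= -1 & rep$mcc <= 1))
  expect_true(all(rep$sn >= 0 & rep$sn <= 1))
  # the mean row averages the label rows
  lab_rows <- rep[!(rep$label %in% c("mean", "median")), ]
  expect_equal(rep$auc_b[rep$label == "mean"], mean(lab_rows$auc_b))
})

test_that("multi-label scheme metrics stay within range", {
  model <- fixture_model()
  test <- fixture_split()$test
  probs <- predict(model, test)
  mm <- multilabel_metrics(probs, rmnet:::rm_window_labels(test), test$base)
  expect_true(mm$hamming_loss >= 0 && mm$hamming_loss <= 1)
  expect_true(mm$subset_accuracy >= 0 && mm$subset_accuracy <= 1)
})
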