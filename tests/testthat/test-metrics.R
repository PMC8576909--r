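test_that("Dice, precision and recall follow their defining ratios", {
  m <- function(idx) { a <- array(0, c(5, 5, 8)); a[idx] <- 1; a }
  T_ <- m(1:100)
  expect_equal(dice_coefficient(T_, T_), 1)
  expect_equal(dice_coefficient(m(101:150), T_), 0)
  expect_equal(dice_coefficient(m(1:50), T_), 2 * 50 / 150)
  expect_error(dice_coefficient(m(integer(0)), m(integer(0))), "empty")

  expect_equal(precision_metric(m(1:50), T_), 1)        # P subset of T
  expect_equal(recall_metric(T_, m(1:50)), 1)           # T subset of P
  P <- m(c(1:40, 101:110))                              # |P|=50, overlap 40
  expect_equal(precision_metric(P, T_), 0.8)
  expect_equal(recall_metric(P, T_), 0.4)
  expect_true(is.na(precision_metric(m(integer(0)), T_)))
  expect_true(is.na(recall_metric(T_, m(integer(0)))))
})

test_that("Dice equals the precision-recall harmonic mean on random masks", {
  set.seed(5)
  checked <- 0
  for (i in 1:100) {
    a <- array(rbinom(48, 1, 0.5), c(4, 4, 3))
    b <- array(rbinom(48, 1, 0.5), c(4, 4, 3))
    p <- precision_metric(a, b); r <- recall_metric(a, b)
    if (is.na(p) || is.na(r) || p + r == 0) next
    expect_equal(dice_coefficient(a, b), 2 * p * r / (p + r))
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("confusion-matrix ratios reproduce the reference test-set row", {
  # test set of 209 malignant / 191 benign with 41 false negatives and 10
  # false positives
  cm <- confusion_matrix(TP = 168, FP = 10, TN = 181, FN = 41)
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 349 / 400)
  expect_equal(met$recall, 168 / 209)
  expect_equal(met$specificity, 181 / 191)
  # printed-precision agreement (display rounding, half away from zero:
  # 87.25 prints as 87.3)
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  expect_equal(round_half_up(100 * met$accuracy, 1), 87.3)
  expect_equal(round_half_up(100 * met$recall, 1), 80.4)
  expect_equal(round_half_up(100 * met$specificity, 1), 94.8)

  perfect <- classification_metrics(confusion_matrix(1, 0, 1, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, recall = 1, specificity = 1))
  worst <- classification_metrics(confusion_matrix(0, 1, 0, 1))
  expect_equal(unlist(worst), c(accuracy = 0, recall = 0, specificity = 0))
  expect_error(confusion_matrix(0, 0, 0, 0), "total")
})

test_that("ROC/AUC equals the pairwise rank probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  # fully interleaved ranks
  expect_equal(roc_auc(c(0.8, 0.7, 0.6, 0.5), c(1, 0, 0, 1))$auc, 0.5)
  expect_error(roc_auc(c(0.2, 0.4), c(1, 1)), "both classes")

  # brute-force pairwise oracle with half credit for ties, n <= 20
  pairwise_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(9)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(s, l)$auc, pairwise_auc(s, l))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(21)
  s <- runif(60)
  l <- rbinom(60, 1, plogis(3 * (s - 0.5)))
  l[1:2] <- c(0, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE)))
  expect_equal(roc_auc(s, l)$auc, as.numeric(ref), tolerance = 1e-12)
})
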