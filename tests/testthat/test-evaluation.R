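# Confusion counts, threshold metrics, rank AUC.

test_that("confusion counts with abnormal as positive", {
  truth <- c(rep("abnormal", 3), rep("normal", 2))
  expect_identical(confusion(truth, truth),
                   c(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  all_norm <- rep("normal", 4)
  expect_identical(confusion(rep("abnormal", 4), all_norm)[["FN"]], 4L)
  expect_error(confusion(c("normal", "weird"), c("normal", "normal")),
               "unknown label")
  # counts always partition n
  set.seed(3)
  for (i in 1:20) {
    tr <- sample(c("normal", "abnormal"), 30, replace = TRUE)
    pr <- sample(c("normal", "abnormal"), 30, replace = TRUE)
    expect_identical(sum(confusion(tr, pr)), 30L)
  }
})

test_that("label swap maps (TP,TN,FP,FN) to (TN,TP,FN,FP)", {
  set.seed(4)
  tr <- sample(c("normal", "abnormal"), 50, replace = TRUE)
  pr <- sample(c("normal", "abnormal"), 50, replace = TRUE)
  swap <- function(x) ifelse(x == "normal", "abnormal", "normal")
  a <- confusion(tr, pr)
  b <- confusion(swap(tr), swap(pr))
  expect_identical(unname(b[c("TN", "TP", "FN", "FP")]),
                   unname(a[c("TP", "TN", "FP", "FN")]))
})

test_that("metrics follow their defining formulas", {
  m <- metrics(c(TP = 10L, TN = 0L, FP = 0L, FN = 0L))
  expect_equal(as.numeric(m), c(1, 1, 1, 1))
  # synthetic fixture reconciled from a published 5000/5000 one-class split
  # (the source text's count phrasing conflicts with its printed precision
  # and recall; these counts are the metric-consistent reading, agreeing
  # with the printed 4-decimal values to their printed precision)
  m2 <- metrics(c(TP = 4743L, TN = 4930L, FP = 70L, FN = 257L))
  expect_equal(m2[["acc"]], 9673 / 10000)
  expect_equal(m2[["pre"]], 4743 / 4813)
  expect_equal(m2[["rec"]], 4743 / 5000)
  expect_lt(abs(m2[["acc"]] - 0.9673), 1e-4)
  expect_lt(abs(m2[["pre"]] - 0.9854), 1e-4)
  expect_lt(abs(m2[["rec"]] - 0.9486), 1e-4)
  expect_error(metrics(c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)), "zero")
})

test_that("zero-denominator metrics are flagged NA, not silently 0", {
  m <- metrics(c(TP = 0L, TN = 5L, FP = 0L, FN = 0L))
  expect_true(is.na(m[["pre"]]))
  expect_true(is.na(m[["rec"]]))
  expect_true(is.na(m[["f1"]]))
  expect_setequal(attr(m, "undefined"), c("pre", "rec", "f1"))
  expect_equal(m[["acc"]], 1)
})

test_that("f1 is the harmonic mean, between precision and recall", {
  set.seed(5)
  for (i in 1:25) {
    counts <- c(TP = sample(1:50, 1), TN = sample(1:50, 1),
                FP = sample(1:50, 1), FN = sample(1:50, 1))
    m <- metrics(counts)
    expect_equal(m[["f1"]],
                 2 * m[["pre"]] * m[["rec"]] / (m[["pre"]] + m[["rec"]]))
    expect_gte(m[["f1"]], min(m[["pre"]], m[["rec"]]) - 1e-12)
    expect_lte(m[["f1"]], max(m[["pre"]], m[["rec"]]) + 1e-12)
  }
})

test_that("AUC endpoints: perfect separation 1, all ties 0.5", {
  labs <- c(rep("normal", 4), rep("abnormal", 4))
  expect_identical(auc_score(c(1:4, 11:14), labs), 1)
  expect_identical(auc_score(rep(2, 8), labs), 0.5)
  expect_identical(auc_score(c(11:14, 1:4), labs), 0)
  expect_error(auc_score(1:4, rep("normal", 4)), "both classes")
})

test_that("AUC matches exhaustive pair counting on small instances", {
  pair_auc <- function(scores, labs) {
    pos <- scores[labs == "abnormal"]
    neg <- scores[labs == "normal"]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  # the 3x3 hand-listed instance
  s <- c(0.1, 0.5, 0.5, 0.4, 0.5, 0.9)
  l <- c("normal", "normal", "normal", "abnormal", "abnormal", "abnormal")
  expect_identical(auc_score(s, l), pair_auc(s, l))
  set.seed(6)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    n_pos <- sample(seq_len(n - 1), 1)
    labs <- sample(c(rep("abnormal", n_pos), rep("normal", n - n_pos)))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(auc_score(scores, labs), pair_auc(scores, labs))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  labs <- sample(c("normal", "abnormal"), 40, replace = TRUE,
                 prob = c(0.5, 0.5))
  labs[1:2] <- c("normal", "abnormal")
  scores <- rnorm(40)
  a <- auc_score(scores, labs)
  expect_equal(auc_score(exp(scores), labs), a)
  expect_equal(auc_score(5 * scores - 3, labs), a)
  expect_equal(auc_score(atan(scores), labs), a)
})

test_that("evaluate_detector assembles a complete report", {
  scores <- c(0.1, 0.2, 0.8, 0.9)
  truth <- c("normal", "normal", "abnormal", "abnormal")
  rep <- evaluate_detector(scores, truth, 0.5)
  expect_s3_class(rep, "eval_report")
  expect_identical(rep$counts, c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(rep$acc, 1)
  expect_equal(rep$auc, 1)
  # single-class input: AUC NA with a note, the rest proceeds
  rep2 <- evaluate_detector(c(0.1, 0.9), c("normal", "normal"), 0.5)
  expect_true(is.na(rep2$auc))
  expect_match(rep2$notes, "both classes")
  expect_equal(rep2$acc, 0.5)
})
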