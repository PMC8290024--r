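# One-decision screening: information-gain stump, confusion metrics,
# ROC/AUC, the repeated split protocol, and paired variable comparison.

test_that("the stump separates well-separated classes at the gap midpoint", {
  rule <- best_threshold(c(1, 2, 8, 9), c("A", "A", "B", "B"), positive = "B")
  expect_equal(rule$cutoff, 5)
  expect_equal(rule$direction, ">")
  expect_equal(rule$train_agreement, 1)
  expect_equal(rule$info_gain, 1)  # 1 bit: perfect split of a 50/50 parent
  expect_error(best_threshold(rep(3, 4), c("A", "A", "B", "B")),
               "no valid cut-off")
  expect_error(best_threshold(1:4, rep("A", 4)), "two classes")
})

test_that("the stump matches exhaustive midpoint enumeration on all labelings", {
  set.seed(31)
  for (n in c(4, 6, 8, 10, 12)) {
    values <- round(rnorm(n), 2)
    if (length(unique(values)) < 2) next
    for (code in seq_len(2^n - 2)) {
      labels <- ifelse(bitwAnd(code, 2^(seq_len(n) - 1)) > 0, "pos", "neg")
      if (length(unique(labels)) < 2) next
      got <- best_threshold(values, labels, positive = "pos")
      want <- brute_best_cut(values, labels, "pos")
      expect_equal(got$cutoff, want$cut)
      expect_equal(got$info_gain, want$gain, tolerance = 1e-12)
      expect_equal(got$train_agreement, want$agree, tolerance = 1e-12)
    }
    # sampled labelings only for the larger sizes would lose exhaustiveness;
    # cap the loop cost instead by limiting n (2^12 labelings is the worst case)
    if (n >= 10) break
  }
})

test_that("interleaved classes still resolve to the enumerated optimum", {
  got <- best_threshold(c(1, 2, 3, 4), c("A", "B", "A", "B"), positive = "B")
  want <- brute_best_cut(c(1, 2, 3, 4), c("A", "B", "A", "B"), "B")
  expect_equal(got$cutoff, want$cut)
  expect_equal(got$info_gain, want$gain)
})

test_that("evaluate_rule reproduces confusion metrics with explicit labels", {
  # 15 treated + 15 untreated, stump catching all treated and 11 untreated
  values <- c(seq(1, 8, length.out = 15),      # treated: low nocturnal activity
              seq(7, 21, length.out = 15))     # untreated: higher, 4 below cut
  labels <- rep(c("treated", "untreated"), each = 15)
  rule <- list(variable = "L5", cutoff = 10.4, direction = "<",
               positive_class = "treated")
  class(rule) <- "threshold_rule"
  rep_ <- evaluate_rule(rule, values, labels)
  expect_equal(c(rep_$tp, rep_$tn, rep_$fp, rep_$fn), c(15, 11, 4, 0))
  expect_equal(rep_$agreement, 26 / 30)
  expect_equal(rep_$ppv, 15 / 19)
  expect_equal(rep_$npv, 1)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 11 / 15)

  # degenerate rule that labels everything positive
  all_pos <- structure(list(variable = NA, cutoff = -Inf, direction = ">",
                            positive_class = "untreated"),
                       class = "threshold_rule")
  r2 <- evaluate_rule(all_pos, values, labels)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)
  expect_equal(r2$agreement, 0.5)  # prevalence of the positive class
})

test_that("confusion metric identities hold over exhaustive small counts", {
  for (tp in 0:6) for (tn in 0:6) for (fp in 0:6) for (fn in 0:6) {
    n <- tp + tn + fp + fn
    if (n == 0) next
    m <- confusion_metrics(tp, tn, fp, fn)
    expect_equal(m$agreement, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(m$ppv, tp / (tp + fp))
    if (tn + fn > 0) expect_equal(m$npv, tn / (tn + fn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
  }
})

test_that("trapezoidal AUC equals the pair-counting U statistic", {
  expect_equal(roc_auc(c(1, 2, 8, 9), c("A", "A", "B", "B"), "B")$auc, 1)
  expect_equal(roc_auc(rep(4, 6), rep(c("A", "B"), 3), "B")$auc, 0.5)
  set.seed(17)
  for (i in 1:20) {
    n <- 50
    score <- sample(round(rnorm(n), 1))  # rounding forces ties
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    got <- roc_auc(score, ifelse(truth, "pos", "neg"), "pos")
    expect_equal(got$auc, brute_auc(score, truth), tolerance = 1e-12)
    # ROC geometry: starts at (0,0), ends at (1,1), monotone
    expect_equal(unlist(got$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(got$roc[nrow(got$roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(got$roc$fpr) >= 0) && all(diff(got$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  score <- c(rnorm(30, 0), rnorm(30, 1))
  labels <- rep(c("ctl", "case"), each = 30)
  got <- roc_auc(score, labels, positive = "case")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, score, levels = c("ctl", "case"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the split protocol is reproducible and its degenerate form refits on all data", {
  set.seed(3)
  values <- c(rnorm(20, 0), rnorm(20, 2))
  labels <- rep(c("lo", "hi"), each = 20)
  a <- split_protocol(values, labels, n_iter = 25, seed = 99, positive = "hi")
  b <- split_protocol(values, labels, n_iter = 25, seed = 99, positive = "hi")
  expect_identical(a$per_iteration, b$per_iteration)
  expect_identical(a$best_rule, b$best_rule)
  expect_equal(a$best_report$agreement,
               max(a$per_iteration$test_agreement))

  d <- split_protocol(values, labels, n_iter = 1, train_frac = 1, seed = 1,
                      positive = "hi")
  full <- best_threshold(values, labels, positive = "hi")
  expect_equal(d$best_rule$cutoff, full$cutoff)
  expect_equal(d$refit_rule$cutoff, full$cutoff)

  expect_error(split_protocol(values[c(1, 21)], labels[c(1, 21)], seed = 1),
               ">= 2 members")
})

test_that("well-separated groups reach high test agreement in most protocol reruns", {
  # class means 3 SDs apart, n = 30 + 30
  hits <- 0
  n_rerun <- 25
  for (k in seq_len(n_rerun)) {
    set.seed(1000 + k)
    values <- c(rnorm(30, 0, 1), rnorm(30, 3, 1))
    labels <- rep(c("ctl", "case"), each = 30)
    res <- split_protocol(values, labels, n_iter = 100, seed = 2000 + k,
                          positive = "case")
    hits <- hits + (res$best_report$agreement >= 0.90)
  }
  expect_gte(hits / n_rerun, 0.95)
})

test_that("paired Wilcoxon comparison of screening variables behaves at its edges", {
  x <- runif(100)
  same <- compare_variables(x, x)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  shifted <- compare_variables(x, x + 0.1)
  expect_false(shifted$degenerate)
  expect_lt(shifted$p_value, 0.001)

  sym <- compare_variables(rep(0, 100), c(rep(0.2, 50), rep(-0.2, 50)))
  expect_gt(sym$p_value, 0.9)

  expect_error(compare_variables(runif(10), runif(12)), "equal length")
})
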