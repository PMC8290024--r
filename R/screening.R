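# One-decision screening: a single-variable threshold rule (a decision
# stump) selected by Shannon information gain, as a C4.5 tree restricted to
# one split would choose it; confusion metrics, ROC/AUC, the repeated
# 66/34 train-test protocol, and paired comparison of candidate variables.

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Fit the best single-threshold rule by information gain
#'
#' Candidate cut-offs are the midpoints between consecutive distinct sorted
#' values. The cut-off maximizing information gain (Shannon entropy
#' reduction, in bits) is returned; ties are broken by higher training
#' agreement, then by the lower cut-off. The side of the cut-off that
#' predicts `positive` is chosen to maximize agreement.
#'
#' @param values numeric predictor, one per subject.
#' @param labels class labels (two levels, both present).
#' @param positive label treated as the positive class; default the last
#'   factor level.
#' @param variable optional predictor name carried in the rule.
#' @return an object of class `threshold_rule`: `variable`, `cutoff`,
#'   `direction` (`">"` means values above the cut-off predict positive),
#'   `positive_class`, `info_gain`, `train_agreement`.
#' @export
best_threshold <- function(values, labels, positive = NULL, variable = NA) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.character(labels)[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes, both present")
  if (is.null(positive)) positive <- classes[2]
  if (!positive %in% classes) stop("positive class not present in labels")
  v <- sort(unique(values))
  if (length(v) < 2) stop("no valid cut-off: fewer than 2 distinct values")
  cuts <- (v[-1] + v[-length(v)]) / 2
  y <- labels == positive
  n <- length(y)
  h0 <- entropy_bits(c(sum(y), n - sum(y)))

  score_cut <- function(cut) {
    left <- values < cut
    nl <- sum(left)
    hl <- entropy_bits(c(sum(y[left]), nl - sum(y[left])))
    hr <- entropy_bits(c(sum(y[!left]), n - nl - sum(y[!left])))
    gain <- h0 - (nl / n * hl + (n - nl) / n * hr)
    agree_gt <- (sum(!left & y) + sum(left & !y)) / n   # ">" predicts positive
    agree_lt <- (sum(left & y) + sum(!left & !y)) / n
    c(gain = gain, agree = max(agree_gt, agree_lt),
      dir_gt = as.numeric(agree_gt >= agree_lt))
  }
  sc <- vapply(cuts, score_cut, numeric(3))
  eps <- 1e-12
  best_gain <- max(sc["gain", ])
  cand <- which(sc["gain", ] >= best_gain - eps)
  cand <- cand[sc["agree", cand] >= max(sc["agree", cand]) - eps]
  i <- cand[1]  # cuts are sorted: earliest candidate = lowest cut-off
  structure(
    list(variable = variable, cutoff = cuts[i],
         direction = if (sc["dir_gt", i] == 1) ">" else "<",
         positive_class = positive, info_gain = unname(sc["gain", i]),
         train_agreement = unname(sc["agree", i])),
    class = "threshold_rule"
  )
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("<threshold_rule> %s %s %.4g -> %s (gain %.3f bits, agreement %.1f%%)\n",
              if (is.na(x$variable)) "value" else x$variable, x$direction,
              x$cutoff, x$positive_class, x$info_gain,
              100 * x$train_agreement))
  invisible(x)
}

predict_rule <- function(rule, values) {
  if (rule$direction == ">") values > rule$cutoff else values < rule$cutoff
}

#' Evaluate a threshold rule on labelled data
#'
#' Confusion counts and the derived fractions, plus the ROC curve and AUC of
#' the underlying variable (oriented so that the rule's positive side scores
#' high). All metrics are reported with explicit class labels: `sensitivity`
#' is recall of `positive_class`, `specificity` recall of the other class.
#'
#' @param rule a [best_threshold()] rule.
#' @param values numeric predictor.
#' @param labels class labels (two levels).
#' @return an object of class `classification_report`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `agreement`, `auc`,
#'   `roc` (data.frame `fpr`, `tpr`), `class_labels`.
#' @export
evaluate_rule <- function(rule, values, labels) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  if (length(values) == 0) stop("empty input")
  pos <- rule$positive_class
  neg <- setdiff(unique(labels), pos)
  if (length(neg) > 1) stop("labels must have two levels")
  pred <- predict_rule(rule, values)
  truth <- labels == pos
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  frac <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  ra <- roc_auc(values, labels, positive = pos, direction = rule$direction)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = frac(tp, fn), specificity = frac(tn, fp),
         ppv = frac(tp, fp), npv = frac(tn, fn),
         agreement = (tp + tn) / (tp + tn + fp + fn),
         auc = ra$auc, roc = ra$roc,
         class_labels = c(positive = pos,
                          negative = if (length(neg)) neg else NA_character_)),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> positive=%s: tp=%d fp=%d tn=%d fn=%d\n  agreement %.1f%%, sens %.1f%%, spec %.1f%%, ppv %.1f%%, npv %.1f%%, AUC %.3f\n",
    x$class_labels["positive"], x$tp, x$fp, x$tn, x$fn, 100 * x$agreement,
    100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv, 100 * x$npv,
    x$auc))
  invisible(x)
}

#' Confusion metrics from raw counts
#'
#' @param tp,tn,fp,fn confusion counts with respect to an explicit positive
#'   class.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `agreement` (fractions).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  frac <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  list(sensitivity = frac(tp, fn), specificity = frac(tn, fp),
       ppv = frac(tp, fp), npv = frac(tn, fn),
       agreement = (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and AUC of a single variable
#'
#' The ROC is swept over every cut-off of the variable (scores oriented so
#' the positive class is predicted on the high side when
#' `direction = ">"`); AUC is the trapezoidal area, which equals the
#' two-sample rank statistic U / (n1 * n2) with ties counted 1/2.
#'
#' @param values numeric predictor.
#' @param labels class labels (two levels, both present).
#' @param positive the positive class label.
#' @param direction `">"` if high values indicate the positive class.
#' @return list with `roc` (data.frame `fpr`, `tpr`, monotone from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(values, labels, positive, direction = ">") {
  labels <- as.character(labels)
  truth <- labels == positive
  if (!any(truth) || all(truth)) stop("both classes must be present")
  score <- if (direction == ">") values else -values
  o <- order(score, decreasing = TRUE)
  s <- score[o]; y <- truth[o]
  # group tied scores so each distinct cut-off contributes one ROC point
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_c <- cumsum(y); fp_c <- cumsum(!y)
  last <- which(c(diff(grp) != 0, TRUE))
  tpr <- c(0, tp_c[last] / sum(truth))
  fpr <- c(0, fp_c[last] / sum(!truth))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Repeated stratified train/test split protocol
#'
#' Re-implements the screening protocol: `n_iter` random splits with
#' `train_frac` of each class used to fit [best_threshold()] and the exact
#' complement used to evaluate it; the reported rule is the best iteration
#' by test agreement (ties: higher test AUC, then lower iteration index).
#' Splits are stratified by class so both partitions always contain both
#' classes; `stratified = FALSE` draws plain random splits and redraws the
#' rare degenerate ones. A refit of the rule on all data is also returned,
#' since a cut-off is sometimes quoted from the full sample rather than the
#' winning train fold.
#'
#' @param values numeric predictor.
#' @param labels class labels (two levels, >= 2 members each).
#' @param n_iter number of random splits (default 100).
#' @param train_frac fraction of each class assigned to training.
#' @param seed integer seed making the whole protocol reproducible.
#' @param positive positive class label (default: last sorted level).
#' @param variable predictor name carried into the rules.
#' @param stratified stratify splits by class (default TRUE).
#' @return an object of class `split_protocol_result`: `best_rule`,
#'   `best_iteration`, `best_report` (test-fold [evaluate_rule()] report),
#'   `refit_rule`, `per_iteration` (data.frame: iteration, cutoff,
#'   direction, test_agreement, test_auc), `selection_criterion`, `seed`.
#' @export
split_protocol <- function(values, labels, n_iter = 100, train_frac = 0.66,
                           seed = 1, positive = NULL, variable = NA,
                           stratified = TRUE) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes")
  if (is.null(positive)) positive <- classes[2]
  idx_by_class <- split(seq_along(labels), labels)
  if (any(lengths(idx_by_class) < 2))
    stop("each class needs >= 2 members to split")
  if (train_frac >= 1) {
    # degenerate protocol: train on everything, nothing left to test
    rule <- best_threshold(values, labels, positive = positive,
                           variable = variable)
    rep_ <- evaluate_rule(rule, values, labels)
    per_iter <- data.frame(iteration = 1L, cutoff = rule$cutoff,
                           direction = rule$direction,
                           test_agreement = NA_real_, test_auc = NA_real_)
    return(structure(
      list(best_rule = rule, best_iteration = 1L, best_report = rep_,
           refit_rule = rule, per_iteration = per_iter,
           selection_criterion = "test_agreement", seed = seed,
           n_iter = 1L, train_frac = 1),
      class = "split_protocol_result"))
  }
  n_train <- lapply(idx_by_class, function(ix)
    min(max(round(length(ix) * train_frac), 1L), length(ix) - 1L))

  set.seed(as.integer(seed))
  rows <- vector("list", n_iter)
  reports <- vector("list", n_iter)
  rules <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    repeat {
      if (stratified) {
        train <- unlist(mapply(function(ix, k) sample(ix, k),
                               idx_by_class, n_train, SIMPLIFY = FALSE))
      } else {
        train <- sample(seq_along(labels),
                        min(max(round(length(labels) * train_frac), 1L),
                            length(labels) - 1L))
      }
      test <- setdiff(seq_along(labels), train)
      ok <- length(unique(labels[train])) == 2 &&
        length(unique(labels[test])) == 2 &&
        length(unique(values[train])) >= 2
      if (ok) break
    }
    rule <- best_threshold(values[train], labels[train], positive = positive,
                           variable = variable)
    rep_ <- evaluate_rule(rule, values[test], labels[test])
    rules[[it]] <- rule
    reports[[it]] <- rep_
    rows[[it]] <- data.frame(iteration = it, cutoff = rule$cutoff,
                             direction = rule$direction,
                             test_agreement = rep_$agreement,
                             test_auc = rep_$auc)
  }
  per_iter <- do.call(rbind, rows)
  o <- order(-per_iter$test_agreement, -per_iter$test_auc,
             per_iter$iteration)
  best <- o[1]
  refit <- best_threshold(values, labels, positive = positive,
                          variable = variable)
  structure(
    list(best_rule = rules[[best]], best_iteration = best,
         best_report = reports[[best]], refit_rule = refit,
         per_iteration = per_iter,
         selection_criterion = "test_agreement", seed = seed,
         n_iter = n_iter, train_frac = train_frac),
    class = "split_protocol_result"
  )
}

#' @export
print.split_protocol_result <- function(x, ...) {
  cat(sprintf(
    "<split_protocol_result> %d x %.0f/%.0f splits (seed %d)\n  best iteration %d: cutoff %.4g (%s), test agreement %.1f%%, test AUC %.3f\n  refit-on-all cutoff %.4g\n",
    x$n_iter, 100 * x$train_frac, 100 * (1 - x$train_frac), x$seed,
    x$best_iteration, x$best_rule$cutoff, x$best_rule$direction,
    100 * x$best_report$agreement, x$best_report$auc, x$refit_rule$cutoff))
  invisible(x)
}

#' Compare two screening variables across protocol iterations
#'
#' Two-sided Wilcoxon signed-rank test on the per-iteration metric
#' differences of two [split_protocol()] runs performed with the same seed
#' (so iterations are paired by the identical random splits). Zero
#' differences are dropped; when every difference is zero the comparison is
#' degenerate and p = 1 is reported with a flag.
#'
#' @param a,b `split_protocol_result` objects, or the per-iteration metric
#'   vectors themselves.
#' @param metric per-iteration column to compare (default
#'   `"test_agreement"`).
#' @return list with `p_value`, `statistic`, `n_pairs` (non-zero
#'   differences), `n_zero`, `degenerate`, `metric`.
#' @export
compare_variables <- function(a, b, metric = "test_agreement") {
  get_vec <- function(x) {
    if (inherits(x, "split_protocol_result")) x$per_iteration[[metric]]
    else as.numeric(x)
  }
  va <- get_vec(a); vb <- get_vec(b)
  if (length(va) != length(vb))
    stop("per-iteration sequences must have equal length (same protocol)")
  d <- vb - va
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(p_value = 1, statistic = NA_real_, n_pairs = 0,
                n_zero = length(d), degenerate = TRUE, metric = metric))
  wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0,
                                            alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_pairs = length(nz), n_zero = sum(d == 0), degenerate = FALSE,
       metric = metric)
}
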