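# Conformal and classical performance metrics.

#' Class-conditional validity of prediction sets
#'
#' Among compounds whose true label is `class_c`, the fraction of
#' prediction sets containing that class. A `both` outcome is always
#' correct (it contains every class) and an `empty` outcome always
#' erroneous. Returns `NA` (undefined), never 0, when no compound of the
#' class is present.
#'
#' @param outcomes Outcome factor from [prediction_set()].
#' @param true_labels 0/1 vector aligned with `outcomes`.
#' @param class_c 0 (inactive) or 1 (active).
#' @return Fraction in [0, 1], or `NA` if undefined.
#' @export
cp_validity <- function(outcomes, true_labels, class_c) {
  stopifnot(length(outcomes) == length(true_labels))
  sel <- true_labels == class_c
  if (!any(sel)) return(NA_real_)
  contains <- outcomes %in%
    c(if (class_c == 1L) "single_active" else "single_inactive", "both")
  mean(contains[sel])
}

#' Class-conditional efficiency of prediction sets
#'
#' Among compounds whose true label is `class_c`, the fraction with a
#' single-label outcome (either label, correct or not). `NA` when no
#' compound of the class is present. `denominator = "predicted"` computes
#' the alternative reading where compounds are grouped by predicted single
#' label instead of true label.
#'
#' @inheritParams cp_validity
#' @param denominator `"true"` (default) or `"predicted"` class grouping.
#' @return Fraction in [0, 1], or `NA` if undefined.
#' @export
cp_efficiency <- function(outcomes, true_labels, class_c,
                          denominator = c("true", "predicted")) {
  denominator <- match.arg(denominator)
  single <- outcomes %in% c("single_active", "single_inactive")
  if (denominator == "true") {
    stopifnot(length(outcomes) == length(true_labels))
    sel <- true_labels == class_c
    if (!any(sel)) return(NA_real_)
    return(mean(single[sel]))
  }
  lab <- if (class_c == 1L) "single_active" else "single_inactive"
  if (!any(single)) return(NA_real_)
  sum(outcomes == lab) / length(outcomes)
}

#' Classification metrics on single-label predictions
#'
#' Restricts to compounds with a single-label outcome, tabulates the 2x2
#' confusion table (active prediction vs true label) and returns accuracy,
#' sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), balanced
#' accuracy BA = (SE+SP)/2 and Matthews correlation (0 when a marginal is
#' zero). All values are `NA` when there is no single-label prediction.
#'
#' @inheritParams cp_validity
#' @return Named list: `n_single`, `tp`, `fp`, `tn`, `fn`, `acc`, `se`,
#'   `sp`, `ba`, `mcc`.
#' @export
single_label_metrics <- function(outcomes, true_labels) {
  stopifnot(length(outcomes) == length(true_labels))
  sel <- outcomes %in% c("single_active", "single_inactive")
  if (!any(sel))
    return(list(n_single = 0L, tp = NA_integer_, fp = NA_integer_,
                tn = NA_integer_, fn = NA_integer_, acc = NA_real_,
                se = NA_real_, sp = NA_real_, ba = NA_real_, mcc = NA_real_))
  pred <- outcomes[sel] == "single_active"
  truth <- true_labels[sel] == 1L
  tp <- sum(pred & truth);  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  se <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(n_single = sum(sel), tp = tp, fp = fp, tn = tn, fn = fn,
       acc = (tp + tn) / sum(sel), se = se, sp = sp,
       ba = if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2,
       mcc = mcc)
}

#' ROC-AUC from conformal p-value differences
#'
#' Ranks compounds by `p_active - p_inactive` and computes the area under
#' the ROC curve by the Mann-Whitney rank formulation; tied scores receive
#' 0.5 credit. `NA` when only one class is present.
#'
#' @param p_active,p_inactive Numeric p-value vectors.
#' @param true_labels 0/1 vector.
#' @return AUC in [0, 1], or `NA` if undefined.
#' @export
roc_auc_from_pvalue_diff <- function(p_active, p_inactive, true_labels) {
  score <- p_active - p_inactive
  n1 <- sum(true_labels == 1L); n0 <- sum(true_labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)  # average ranks implement the 0.5 tie convention
  (sum(r[true_labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metrics report at one significance level
#'
#' Bundles class-wise validity and efficiency, outcome counts, single-label
#' classification metrics and the p-value-difference ROC-AUC.
#'
#' @param pvals Data frame with `p_active`, `p_inactive`.
#' @param true_labels 0/1 vector.
#' @param significance Significance level in (0, 1).
#' @return A one-row data frame of metrics (undefined metrics are `NA`).
#' @export
metrics_report <- function(pvals, true_labels, significance) {
  outc <- prediction_set(pvals$p_active, pvals$p_inactive, significance)
  counts <- table(outc)
  sl <- single_label_metrics(outc, true_labels)
  data.frame(
    significance = significance,
    n_evaluated = length(outc),
    n_single_active = as.integer(counts[["single_active"]]),
    n_single_inactive = as.integer(counts[["single_inactive"]]),
    n_both = as.integer(counts[["both"]]),
    n_empty = as.integer(counts[["empty"]]),
    validity_active = cp_validity(outc, true_labels, 1L),
    validity_inactive = cp_validity(outc, true_labels, 0L),
    efficiency_active = cp_efficiency(outc, true_labels, 1L),
    efficiency_inactive = cp_efficiency(outc, true_labels, 0L),
    acc = sl$acc, ba = sl$ba, se = sl$se, sp = sl$sp, mcc = sl$mcc,
    n_single = sl$n_single,
    roc_auc = roc_auc_from_pvalue_diff(pvals$p_active, pvals$p_inactive,
                                       true_labels))
}
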