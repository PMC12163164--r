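# Mondrian inductive conformal prediction over a random-forest base
# classifier.
#
# The base model is fitted on the proper training set only. Nonconformity
# of an example for a hypothesized class is 1 minus the forest's predicted
# probability of that class. Calibration scores are grouped by the true
# class of the calibration examples (the Mondrian taxonomy), so p-values
# and the resulting error guarantee are class-conditional.

#' Nonconformity score from a class probability
#'
#' `1 - p`, the default inductive-conformal nonconformity measure for
#' probabilistic classifiers: monotone decreasing in the predicted
#' probability of the hypothesized class, bounded in [0, 1].
#'
#' @param prob Probability (or vector of probabilities) in [0, 1].
#' @return Nonconformity scores in [0, 1].
#' @export
nonconformity <- function(prob) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  1 - prob
}

#' Conformal p-value against a calibration score list
#'
#' `p = (#\{s in cal : s >= t\} + 1) / (n_cal + 1)` for a test
#' nonconformity `t`: the (deterministic, non-smoothed) fraction of
#' calibration examples at least as nonconforming as the test example,
#' with ties counting toward the numerator. Always lies in
#' `[1/(n_cal+1), 1]`; an empty calibration list gives 1.
#'
#' With `smooth = TRUE`, ties are split uniformly at random
#' (`(#\{s > t\} + u * (#\{s = t\} + 1)) / (n_cal + 1)`), which is the
#' classical randomized p-value; the default is deterministic for
#' reproducibility.
#'
#' @param cal_scores Numeric vector of calibration nonconformity scores.
#' @param test_score Numeric vector of test nonconformity scores.
#' @param smooth Randomize tie handling (default FALSE).
#' @return Numeric vector of p-values, one per test score.
#' @export
#' @examples
#' p_value(c(0.9, 0.5, 0.2), 0.6)  # 0.5
p_value <- function(cal_scores, test_score, smooth = FALSE) {
  n <- length(cal_scores)
  vapply(test_score, function(t) {
    ge <- sum(cal_scores >= t)
    if (!smooth) {
      (ge + 1) / (n + 1)
    } else {
      gt <- sum(cal_scores > t)
      eq <- ge - gt
      (gt + stats::runif(1) * (eq + 1)) / (n + 1)
    }
  }, numeric(1))
}

#' Fit a Mondrian inductive conformal predictor
#'
#' Fits a probability random forest (\pkg{ranger}) on the proper training
#' set and computes class-wise calibration nonconformity scores on the
#' calibration set: for each calibration example, `1 -` the predicted
#' probability of its true class, stored separately per class.
#'
#' @param x_train,y_train Proper training features (matrix) and 0/1 labels.
#' @param x_cal,y_cal Calibration features and 0/1 labels; both classes
#'   must be present (otherwise an error instructs re-splitting).
#' @param num_trees Trees in the forest (default 100, the common default
#'   for this application).
#' @param mtry Variables per split (default: ranger's `sqrt(p)`).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param spec Optional [featurizer_spec()] recorded for prediction-time
#'   consistency checks.
#' @param token_dict Optional token dictionary persisted with the model.
#' @return An object of class `mondrian_icp`: the fitted base model,
#'   `cal_scores` (list with components `inactive` and `active`), the
#'   nonconformity function name, `spec`, and `seed`.
#' @export
fit_icp <- function(x_train, y_train, x_cal, y_cal,
                    num_trees = 100L, mtry = NULL, seed,
                    spec = NULL, token_dict = NULL) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  y_train <- as.integer(y_train); y_cal <- as.integer(y_cal)
  if (length(unique(y_train)) < 2L)
    stop("both classes must be present in the training set", call. = FALSE)
  if (length(unique(y_cal)) < 2L)
    stop("calibration set contains a single class; re-split with a ",
         "different seed or stratified calibration sampling", call. = FALSE)
  x_train <- as.matrix(x_train); x_cal <- as.matrix(x_cal)
  colnames(x_train) <- paste0("f", seq_len(ncol(x_train)))
  base <- ranger::ranger(
    x = x_train, y = factor(y_train, levels = c(0L, 1L)),
    probability = TRUE, num.trees = num_trees,
    mtry = mtry, seed = seed, num.threads = 1L)
  colnames(x_cal) <- colnames(x_train)
  pr <- stats::predict(base, data = x_cal, num.threads = 1L)$predictions
  prob_true <- ifelse(y_cal == 1L, pr[, "1"], pr[, "0"])
  scores <- nonconformity(prob_true)
  model <- structure(
    list(base = base,
         cal_scores = list(inactive = scores[y_cal == 0L],
                           active = scores[y_cal == 1L]),
         nonconformity = "1 - p(class)",
         num_trees = num_trees,
         n_features = ncol(x_train),
         spec = spec, token_dict = token_dict, seed = seed),
    class = "mondrian_icp")
  model
}

#' Class-conditional p-values for new examples
#'
#' For each row of `x`, the base forest's class probabilities are turned
#' into nonconformity scores for both hypothesized classes, and each score
#' is calibrated against that class's calibration list, giving the pair
#' `(p_inactive, p_active)`.
#'
#' @param model A fitted `mondrian_icp`.
#' @param x Feature matrix featurized with the model's spec.
#' @param smooth Randomized tie handling in the p-values (default FALSE).
#' @return Data frame with columns `p_inactive`, `p_active`.
#' @export
predict_pvalues <- function(model, x, smooth = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(x), model$n_features), call. = FALSE)
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  pr <- stats::predict(model$base, data = x, num.threads = 1L)$predictions
  data.frame(
    p_inactive = p_value(model$cal_scores$inactive, nonconformity(pr[, "0"]),
                         smooth = smooth),
    p_active   = p_value(model$cal_scores$active, nonconformity(pr[, "1"]),
                         smooth = smooth))
}

.outcome_levels <- c("single_active", "single_inactive", "both", "empty")

#' Map p-value pairs to four-outcome prediction sets
#'
#' A class enters the prediction set iff its p-value is strictly greater
#' than the significance level. The four outcomes are `single_active`,
#' `single_inactive`, `both` and `empty`; the factor levels are ordered by
#' the consensus tie-break priority (active > inactive > both > empty).
#'
#' @param p_active,p_inactive Numeric p-value vectors.
#' @param significance Significance level in (0, 1).
#' @return Factor of outcomes with levels
#'   `single_active, single_inactive, both, empty`.
#' @export
#' @examples
#' prediction_set(0.5, 0.1, 0.2)  # single_active
prediction_set <- function(p_active, p_inactive, significance) {
  stopifnot(significance > 0, significance < 1)
  act <- p_active > significance
  ina <- p_inactive > significance
  out <- ifelse(act & ina, "both",
         ifelse(act, "single_active",
         ifelse(ina, "single_inactive", "empty")))
  factor(out, levels = .outcome_levels)
}

#' Predict method for Mondrian conformal predictors
#'
#' @param object A fitted `mondrian_icp`.
#' @param x Feature matrix.
#' @param significance Significance level(s); when supplied, prediction
#'   sets are returned alongside the p-values.
#' @param type `"p.value"` (default) or `"set"` (requires a single
#'   `significance`).
#' @param ... Unused.
#' @return For `type = "p.value"`, a data frame of p-value pairs (plus one
#'   outcome column per significance level if given); for `type = "set"`,
#'   the outcome factor.
#' @export
predict.mondrian_icp <- function(object, x, significance = NULL,
                                 type = c("p.value", "set"), ...) {
  type <- match.arg(type)
  pv <- predict_pvalues(object, x)
  if (type == "set") {
    if (is.null(significance) || length(significance) != 1L)
      stop("type = 'set' requires a single significance level", call. = FALSE)
    return(prediction_set(pv$p_active, pv$p_inactive, significance))
  }
  if (!is.null(significance)) {
    for (eps in significance) {
      pv[[sprintf("set_%g", eps)]] <-
        prediction_set(pv$p_active, pv$p_inactive, eps)
    }
  }
  pv
}

#' @export
print.mondrian_icp <- function(x, ...) {
  cat("Mondrian inductive conformal predictor\n")
  cat(sprintf("  base: probability forest, %d trees, %d features\n",
              x$num_trees, x$n_features))
  cat(sprintf("  nonconformity: %s\n", x$nonconformity))
  cat(sprintf("  calibration: %d inactive, %d active\n",
              length(x$cal_scores$inactive), length(x$cal_scores$active)))
  if (!is.null(x$spec)) cat(sprintf("  featurizer: %s\n", x$spec$name))
  invisible(x)
}

#' @export
summary.mondrian_icp <- function(object, ...) {
  print(object)
  cat("  calibration score quartiles:\n")
  for (cl in c("inactive", "active")) {
    q <- stats::quantile(object$cal_scores[[cl]], c(0.25, 0.5, 0.75))
    cat(sprintf("    %-8s %.3f / %.3f / %.3f\n", cl, q[1], q[2], q[3]))
  }
  invisible(object)
}
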