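# Cross-validated experiment grid: featurizers x folds x significance
# levels, plus consensus models.

#' Run the cross-validated conformal prediction experiment
#'
#' For each featurizer: featurizes the valid records once, then for each
#' fold fits a Mondrian conformal predictor on the fold's proper training
#' set (calibrating on the fold's calibration set) and predicts p-values
#' for the fold's test set. Test predictions are pooled over folds — every
#' record is predicted exactly once — and the full metrics report is
#' computed at each significance level, for each single model and for the
#' requested consensus models. Fully reproducible given `seed`.
#'
#' @param records Standardized dataset (needs `smiles_std`, `label`; rows
#'   with `NA` canonical SMILES are excluded with a message).
#' @param specs Character vector of featurizer names (see
#'   [featurizer_names()]), or list of [featurizer_spec()] objects.
#' @param significance Significance levels (default 0.1..0.3).
#' @param consensus Character vector among `"pvals"`, `"cls"`; consensus
#'   models are added when at least two specs are fitted (default both).
#' @param k Folds (default 10).
#' @param cal_frac Calibration fraction (default 0.2).
#' @param seed Integer seed (required).
#' @param num_trees Trees per forest (default 100).
#' @param shuffle Shuffle before folding (default TRUE).
#' @return An object of class `cp_experiment`: `pvalues` (one pooled
#'   p-value table per model), `outcomes` (per significance), `metrics`
#'   (long data frame), `predictions` (per-compound table), `labels`,
#'   `folds`, `seed`.
#' @export
run_cv_experiment <- function(records, specs, significance = c(0.1, 0.15, 0.2, 0.25, 0.3),
                              consensus = c("pvals", "cls"), k = 10L,
                              cal_frac = 0.2, seed, num_trees = 100L,
                              shuffle = TRUE) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(all(significance > 0), all(significance < 1))
  if (is.character(specs)) specs <- lapply(specs, featurizer_spec)
  spec_names <- vapply(specs, function(s) s$name, character(1))
  keep <- which(!is.na(records$smiles_std))
  if (length(keep) < nrow(records))
    message(sprintf("excluding %d invalid records", nrow(records) - length(keep)))
  data <- records[keep, , drop = FALSE]
  y <- as.integer(data$label)
  if (length(unique(y)) < 2L) stop("need both classes", call. = FALSE)
  n <- nrow(data)
  folds <- make_folds(n, k = k, cal_frac = cal_frac, seed = seed,
                      shuffle = shuffle)
  old <- .hold_rng(seed)
  fold_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                                  length(specs) * k),
                       nrow = length(specs))
  .restore_rng(old)
  pvalues <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    feats <- featurize_dataset(data, spec)
    if (nrow(feats$failed) > 0L)
      message(sprintf("%s: %d records failed featurization",
                      spec$name, nrow(feats$failed)))
    # map record row -> feature matrix row (NA if featurization failed)
    frow <- rep(NA_integer_, n)
    frow[feats$row_index] <- seq_along(feats$row_index)
    pv <- data.frame(p_inactive = rep(NA_real_, n),
                     p_active = rep(NA_real_, n))
    for (fi in seq_len(k)) {
      f <- folds[[fi]]
      tr <- stats::na.omit(frow[f$train_idx])
      ca <- stats::na.omit(frow[f$cal_idx])
      te_rec <- f$test_idx[!is.na(frow[f$test_idx])]
      te <- frow[te_rec]
      model <- fit_icp(feats$x[tr, , drop = FALSE], y[f$train_idx][!is.na(frow[f$train_idx])],
                       feats$x[ca, , drop = FALSE], y[f$cal_idx][!is.na(frow[f$cal_idx])],
                       num_trees = num_trees, seed = fold_seeds[si, fi],
                       spec = spec, token_dict = feats$token_dict)
      pv[te_rec, ] <- predict_pvalues(model, feats$x[te, , drop = FALSE])
    }
    pvalues[[spec$name]] <- pv
  }
  # consensus models over the fitted specs
  if (length(specs) >= 2L && length(consensus) > 0L) {
    if ("pvals" %in% consensus) {
      med <- consensus_pvals(pvalues[spec_names], significance[1L])
      pvalues[["consensus_pvals"]] <- med[, c("p_inactive", "p_active")]
    }
  }
  outcomes <- list(); metrics <- list(); preds <- list()
  for (nm in names(pvalues)) {
    pv <- pvalues[[nm]]
    ok <- !is.na(pv$p_active)
    for (eps in significance) {
      outc <- prediction_set(pv$p_active[ok], pv$p_inactive[ok], eps)
      outcomes[[nm]][[sprintf("%g", eps)]] <- outc
      m <- metrics_report(pv[ok, ], y[ok], eps)
      m <- cbind(data.frame(model = nm), m)
      metrics[[length(metrics) + 1L]] <- m
    }
    preds[[nm]] <- data.frame(id = data$id, model = nm, label = y,
                              p_inactive = pv$p_inactive,
                              p_active = pv$p_active)
  }
  if (length(specs) >= 2L && "cls" %in% consensus) {
    for (eps in significance) {
      key <- sprintf("%g", eps)
      per_model <- lapply(spec_names, function(nm) {
        pv <- pvalues[[nm]]
        prediction_set(pv$p_active, pv$p_inactive, eps)  # NAs propagate
      })
      cc <- consensus_cls(per_model)
      ok <- !is.na(cc)
      outcomes[["consensus_cls"]][[key]] <- cc[ok]
      sl <- single_label_metrics(cc[ok], y[ok])
      counts <- table(cc[ok])
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = "consensus_cls", significance = eps,
        n_evaluated = sum(ok),
        n_single_active = as.integer(counts[["single_active"]]),
        n_single_inactive = as.integer(counts[["single_inactive"]]),
        n_both = as.integer(counts[["both"]]),
        n_empty = as.integer(counts[["empty"]]),
        validity_active = cp_validity(cc[ok], y[ok], 1L),
        validity_inactive = cp_validity(cc[ok], y[ok], 0L),
        efficiency_active = cp_efficiency(cc[ok], y[ok], 1L),
        efficiency_inactive = cp_efficiency(cc[ok], y[ok], 0L),
        acc = sl$acc, ba = sl$ba, se = sl$se, sp = sl$sp, mcc = sl$mcc,
        n_single = sl$n_single, roc_auc = NA_real_)
    }
  }
  structure(list(
    pvalues = pvalues,
    outcomes = outcomes,
    metrics = do.call(rbind, metrics),
    predictions = do.call(rbind, preds),
    labels = y,
    ids = data$id,
    folds = folds,
    spec_names = spec_names,
    significance = significance,
    seed = seed),
    class = "cp_experiment")
}

#' @export
print.cp_experiment <- function(x, ...) {
  cat(sprintf("Cross-validated conformal prediction experiment (seed %d)\n",
              x$seed))
  cat(sprintf("  %d compounds, %d folds, models: %s\n",
              length(x$labels), length(x$folds),
              paste(unique(x$metrics$model), collapse = ", ")))
  cat(sprintf("  significance levels: %s\n",
              paste(x$significance, collapse = ", ")))
  invisible(x)
}

#' @export
summary.cp_experiment <- function(object, significance = 0.2, ...) {
  m <- object$metrics
  m <- m[abs(m$significance - significance) < 1e-9, ]
  cat(sprintf("Metrics at significance %g:\n", significance))
  show <- m[, c("model", "validity_active", "validity_inactive",
                "efficiency_active", "efficiency_inactive", "ba", "mcc")]
  print(format(show, digits = 3), row.names = FALSE)
  invisible(m)
}

#' Validity/efficiency curves of a fitted experiment
#'
#' Plots class-wise validity (solid) and efficiency (dashed) against the
#' significance level for one model, with the 1 - significance diagonal.
#'
#' @param x A `cp_experiment`.
#' @param model Model name (default: first).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cp_experiment <- function(x, model = NULL, ...) {
  if (is.null(model)) model <- x$metrics$model[1L]
  m <- x$metrics[x$metrics$model == model, ]
  m <- m[order(m$significance), ]
  graphics::matplot(m$significance,
                    m[, c("validity_active", "validity_inactive",
                          "efficiency_active", "efficiency_inactive")],
                    type = "b", lty = c(1, 1, 2, 2), pch = c(1, 2, 1, 2),
                    col = c("firebrick", "navy", "firebrick", "navy"),
                    xlab = "significance level",
                    ylab = "fraction", main = model, ylim = c(0, 1), ...)
  graphics::abline(a = 1, b = -1, col = "grey60")
  graphics::legend("bottomleft", bty = "n",
                   legend = c("validity (active)", "validity (inactive)",
                              "efficiency (active)", "efficiency (inactive)"),
                   lty = c(1, 1, 2, 2), pch = c(1, 2, 1, 2),
                   col = c("firebrick", "navy", "firebrick", "navy"))
  invisible(x)
}
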