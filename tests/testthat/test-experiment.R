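# A small shared experiment keeps these contract checks fast.
small_data <- generate_dataset(synthetic_config(n_compounds = 250L,
                                                label_noise = 0, seed = 12L))
small_exp <- run_cv_experiment(small_data,
                               c("ngram_4_hashed_64", "ngram_6_hashed_64"),
                               significance = c(0.1, 0.2, 0.3),
                               k = 2L, seed = 12L)

test_that("the cross-validated experiment populates every reported field", {
  expect_s3_class(small_exp, "cp_experiment")
  m <- small_exp$metrics
  expect_true(all(c("ngram_4_hashed_64", "ngram_6_hashed_64",
                    "consensus_pvals", "consensus_cls") %in% m$model))
  expect_identical(nrow(m), 4L * 3L)
  num_cols <- c("validity_active", "validity_inactive",
                "efficiency_active", "efficiency_inactive")
  expect_true(all(m[, num_cols] >= 0 & m[, num_cols] <= 1, na.rm = TRUE))
  # every compound predicted exactly once over the pooled folds
  expect_false(anyNA(small_exp$pvalues[["ngram_4_hashed_64"]]$p_active))
  # outcome counts conserve the evaluated total
  expect_true(all(m$n_single_active + m$n_single_inactive + m$n_both +
                    m$n_empty == m$n_evaluated))
})

test_that("experiments are bit-reproducible under the same seed", {
  again <- run_cv_experiment(small_data,
                             c("ngram_4_hashed_64", "ngram_6_hashed_64"),
                             significance = c(0.1, 0.2, 0.3),
                             k = 2L, seed = 12L)
  expect_identical(small_exp$predictions, again$predictions)
  expect_identical(small_exp$metrics, again$metrics)
  other <- run_cv_experiment(small_data, "ngram_4_hashed_64",
                             significance = 0.2, k = 2L, seed = 13L)
  expect_false(identical(
    small_exp$pvalues[["ngram_4_hashed_64"]],
    other$pvalues[["ngram_4_hashed_64"]]))
})

test_that("report metrics satisfy their defining identities", {
  m <- small_exp$metrics
  ok <- !is.na(m$ba)
  expect_equal(m$ba[ok], (m$se[ok] + m$sp[ok]) / 2, tolerance = 1e-12)
  # accuracy recomputed independently from pooled outcomes
  for (nm in c("ngram_4_hashed_64", "consensus_cls")) {
    o <- small_exp$outcomes[[nm]][["0.2"]]
    y <- small_exp$labels
    sel <- o %in% c("single_active", "single_inactive")
    acc_ind <- mean((o[sel] == "single_active") == (y[sel] == 1L))
    row <- m[m$model == nm & abs(m$significance - 0.2) < 1e-9, ]
    expect_equal(row$acc, acc_ind, tolerance = 1e-12)
  }
})

test_that("print, summary and plot methods run quietly", {
  expect_output(print(small_exp), "Cross-validated")
  expect_output(summary(small_exp, 0.2), "Metrics at significance")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(small_exp, model = "ngram_4_hashed_64")
  grDevices::dev.off()
  expect_true(file.exists(tf)); unlink(tf)
})
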