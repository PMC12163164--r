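test_that("validity counts both as correct and empty as erroneous", {
  o <- outc("single_active", "both", "single_inactive", "empty")
  y <- c(1L, 1L, 1L, 1L)
  expect_identical(cp_validity(o, y, 1L), 0.5)
  expect_identical(cp_validity(rep(outc("both"), 4L), y, 1L), 1)
  expect_identical(cp_validity(rep(outc("empty"), 4L), y, 1L), 0)
  expect_true(is.na(cp_validity(o, y, 0L)))  # undefined, not zero
})

test_that("efficiency is the single-label fraction regardless of correctness", {
  o <- outc("single_active", "both", "single_inactive", "single_active")
  y <- rep(1L, 4L)
  expect_identical(cp_efficiency(o, y, 1L), 0.75)
  expect_identical(cp_efficiency(rep(outc("both"), 3L), rep(1L, 3L), 1L), 0)
  expect_identical(cp_efficiency(rep(outc("single_inactive"), 3L), rep(1L, 3L), 1L), 1)
  # brute-force recount: efficiency * n equals the singleton count
  set.seed(17)
  o2 <- outc(sample(c("single_active", "single_inactive", "both", "empty"),
                    50L, replace = TRUE))
  y2 <- rbinom(50L, 1L, 0.4)
  for (cl in 0:1) {
    eff <- cp_efficiency(o2, y2, cl)
    n_cl <- sum(y2 == cl)
    expect_equal(round(eff * n_cl),
                 sum(o2[y2 == cl] %in% c("single_active", "single_inactive")))
  }
})

test_that("single-label metrics reproduce 2x2 arithmetic", {
  o <- outc(rep("single_active", 13L), rep("single_inactive", 7L))
  y <- c(rep(1L, 8L), rep(0L, 5L), rep(1L, 2L), rep(0L, 5L))
  m <- single_label_metrics(o, y)
  expect_identical(m$tp, 8L); expect_identical(m$fn, 2L)
  expect_identical(m$tn, 5L); expect_identical(m$fp, 5L)
  expect_identical(m$se, 0.8); expect_identical(m$sp, 0.5)
  expect_identical(m$ba, 0.65); expect_identical(m$acc, 0.65)
  # perfect predictions
  mp <- single_label_metrics(outc(rep("single_active", 3L), rep("single_inactive", 3L)),
                             c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_identical(mp$mcc, 1)
  # balanced label-independent table -> MCC 0
  mb <- single_label_metrics(outc(rep(c("single_active", "single_inactive"), each = 2L)),
                             c(1L, 0L, 1L, 0L))
  expect_identical(mb$mcc, 0)
  # no singletons -> undefined markers
  mn <- single_label_metrics(outc("both", "empty"), c(1L, 0L))
  expect_true(is.na(mn$ba) && is.na(mn$acc))
})

test_that("p-value difference AUC follows the Mann-Whitney tie conventions", {
  # perfectly ordered
  expect_identical(roc_auc_from_pvalue_diff(c(0.9, 0.8, 0.2, 0.1),
                                            c(0.1, 0.2, 0.9, 0.8),
                                            c(1L, 1L, 0L, 0L)), 1)
  # all tied -> 0.5
  expect_identical(roc_auc_from_pvalue_diff(rep(0.5, 6L), rep(0.5, 6L),
                                            rep(c(1L, 0L), 3L)), 0.5)
  expect_true(is.na(roc_auc_from_pvalue_diff(runif(4), runif(4), rep(1L, 4L))))
  # shuffled labels -> approximately 0.5
  set.seed(19)
  pa <- runif(2000); pi_ <- runif(2000); y <- rbinom(2000, 1L, 0.5)
  expect_lt(abs(roc_auc_from_pvalue_diff(pa, pi_, y) - 0.5), 0.05)
  # agrees with an independent ROC implementation
  set.seed(20)
  pa <- runif(200); pi_ <- runif(200)
  y <- rbinom(200, 1L, 0.5)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, pa - pi_, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_auc_from_pvalue_diff(pa, pi_, y), auc_ref,
               tolerance = 1e-12)
})

test_that("the metrics report is internally consistent", {
  set.seed(23)
  pv <- data.frame(p_active = runif(100), p_inactive = runif(100))
  y <- rbinom(100L, 1L, 0.3)
  rep_ <- metrics_report(pv, y, 0.2)
  expect_identical(rep_$n_single_active + rep_$n_single_inactive +
                     rep_$n_both + rep_$n_empty, rep_$n_evaluated)
  expect_identical(rep_$ba, (rep_$se + rep_$sp) / 2)
  expect_true(rep_$mcc >= -1 && rep_$mcc <= 1)
})
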