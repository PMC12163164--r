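test_that("nonconformity is 1 - probability with range checking", {
  expect_identical(nonconformity(1), 0)
  expect_identical(nonconformity(0), 1)
  expect_identical(nonconformity(0.75), 0.25)
  expect_error(nonconformity(1.2), "\\[0, 1\\]")
})

test_that("p-values follow the count-and-divide rule with ties counted", {
  expect_identical(p_value(c(0.9, 0.5, 0.2), 0.6), 0.5)
  expect_identical(p_value(numeric(0), 0.3), 1)
  expect_identical(p_value(c(0.1, 0.2, 0.3), 1.0), 0.25)
  # tie counts toward the numerator
  expect_identical(p_value(c(0.5, 0.2), 0.5), 2 / 3)
})

test_that("p-values agree exactly with brute-force counting on random fixtures", {
  set.seed(77)
  for (i in 1:1000) {
    cal <- round(runif(sample(1:20, 1L)), 2)
    t <- round(runif(1), 2)
    brute <- 0L
    for (s in cal) if (s >= t) brute <- brute + 1L
    expect_identical(p_value(cal, t), (brute + 1) / (length(cal) + 1))
  }
  # bounds: p in [1/(n+1), 1]
  set.seed(78)
  for (i in 1:50) {
    cal <- runif(10)
    p <- p_value(cal, runif(1))
    expect_gte(p, 1 / 11); expect_lte(p, 1)
  }
})

test_that("fitting performs class-wise calibration bookkeeping", {
  toy <- toy_classification(100L, seed = 3L)
  idx_cal <- 81:100
  # force a known class split in the calibration set
  toy$y[idx_cal] <- rep(c(1L, 0L), c(12L, 8L))
  m <- fit_icp(toy$x[1:80, ], toy$y[1:80], toy$x[idx_cal, ], toy$y[idx_cal],
               seed = 9L)
  expect_s3_class(m, "mondrian_icp")
  expect_length(m$cal_scores$active, 12L)
  expect_length(m$cal_scores$inactive, 8L)
  expect_true(all(unlist(m$cal_scores) >= 0 & unlist(m$cal_scores) <= 1))
  # identical seeds give identical calibration scores
  m2 <- fit_icp(toy$x[1:80, ], toy$y[1:80], toy$x[idx_cal, ], toy$y[idx_cal],
                seed = 9L)
  expect_identical(m$cal_scores, m2$cal_scores)
  # single-class calibration set is a fitting error
  expect_error(
    fit_icp(toy$x[1:80, ], toy$y[1:80], toy$x[1:5, ], rep(1L, 5L), seed = 1L),
    "single class")
})

test_that("a separable problem yields conforming calibration scores", {
  toy <- toy_classification(200L, seed = 5L, separation = 6)
  m <- fit_icp(toy$x[1:150, ], toy$y[1:150], toy$x[151:200, ], toy$y[151:200],
               seed = 2L)
  expect_lt(median(m$cal_scores$active), 0.5)
  expect_lt(median(m$cal_scores$inactive), 0.5)
})

test_that("prediction-time p-values are deterministic and oracle-consistent", {
  toy <- toy_classification(120L, seed = 8L)
  m <- fit_icp(toy$x[1:80, ], toy$y[1:80], toy$x[81:100, ], toy$y[81:100],
               seed = 4L)
  xt <- toy$x[101:120, ]
  pv1 <- predict_pvalues(m, xt)
  pv2 <- predict_pvalues(m, xt)
  expect_identical(pv1, pv2)
  expect_true(all(pv1$p_active > 0 & pv1$p_active <= 1))
  # hand-check one row against the count rule on a 5-score fixture
  m$cal_scores$active <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  m$cal_scores$inactive <- c(0.8, 0.6, 0.4, 0.2, 0.05)
  pr <- predict(m$base, data = {z <- xt[1, , drop = FALSE]
                                colnames(z) <- paste0("f", 1:ncol(z)); z},
                num.threads = 1L)$predictions
  pv <- predict_pvalues(m, xt[1, , drop = FALSE])
  expect_identical(pv$p_active,
                   (sum(m$cal_scores$active >= (1 - pr[, "1"])) + 1) / 6)
  expect_identical(pv$p_inactive,
                   (sum(m$cal_scores$inactive >= (1 - pr[, "0"])) + 1) / 6)
  # dimension mismatch is an error
  expect_error(predict_pvalues(m, xt[, 1:5]), "dimension")
})

test_that("p-value pairs map to the four outcomes by strict comparison", {
  expect_identical(as.character(prediction_set(0.5, 0.1, 0.2)), "single_active")
  expect_identical(as.character(prediction_set(0.5, 0.5, 0.2)), "both")
  expect_identical(as.character(prediction_set(0.05, 0.15, 0.2)), "empty")
  expect_identical(as.character(prediction_set(0.1, 0.5, 0.2)), "single_inactive")
  # boundary: p == significance excludes the class
  expect_identical(as.character(prediction_set(0.2, 0.1, 0.2)), "empty")
})

test_that("prediction sets are nested across significance levels", {
  toy <- toy_classification(150L, seed = 13L)
  m <- fit_icp(toy$x[1:90, ], toy$y[1:90], toy$x[91:120, ], toy$y[91:120],
               seed = 6L)
  pv <- predict_pvalues(m, toy$x[121:150, ])
  eps <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  for (i in seq_len(length(eps) - 1L)) {
    s1 <- prediction_set(pv$p_active, pv$p_inactive, eps[i])
    s2 <- prediction_set(pv$p_active, pv$p_inactive, eps[i + 1L])
    has_a1 <- s1 %in% c("single_active", "both")
    has_a2 <- s2 %in% c("single_active", "both")
    has_i1 <- s1 %in% c("single_inactive", "both")
    has_i2 <- s2 %in% c("single_inactive", "both")
    expect_true(all(has_a1 | !has_a2))  # larger eps never adds a class
    expect_true(all(has_i1 | !has_i2))
  }
})
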