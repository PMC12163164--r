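pv_df <- function(pa, pi) data.frame(p_active = pa, p_inactive = pi)

test_that("median p-value consensus follows the even/odd conventions", {
  models <- list(pv_df(0.1, 0.9), pv_df(0.3, 0.5), pv_df(0.5, 0.1))
  cp <- consensus_pvals(models, 0.2)
  expect_identical(cp$p_active, 0.3)
  models4 <- c(models, list(pv_df(1.0, 0.2)))
  cp4 <- consensus_pvals(models4, 0.2)
  expect_identical(cp4$p_active, 0.4)  # mean of the central pair
  # all models identical -> consensus equals any single model
  same <- replicate(5, pv_df(c(0.4, 0.05), c(0.1, 0.5)), simplify = FALSE)
  cs <- consensus_pvals(same, 0.2)
  expect_identical(cs$p_active, c(0.4, 0.05))
  expect_identical(as.character(cs$outcome),
                   as.character(prediction_set(c(0.4, 0.05), c(0.1, 0.5), 0.2)))
  expect_error(consensus_pvals(list(pv_df(0.1, 0.2), pv_df(c(0.1, 0.2), c(0.3, 0.4))), 0.2),
               "same compounds")
})

test_that("majority vote resolves ties by the fixed class priority", {
  # three-way single/single/both tie -> active class
  expect_identical(
    as.character(consensus_cls(list(outc("single_active"),
                                    outc("single_inactive"), outc("both")))),
    "single_active")
  # clear majority
  expect_identical(
    as.character(consensus_cls(list(outc("single_inactive"),
                                    outc("single_inactive"),
                                    outc("single_active")))),
    "single_inactive")
  # both/empty tie -> both
  expect_identical(
    as.character(consensus_cls(list(outc("both"), outc("both"),
                                    outc("empty"), outc("empty")))),
    "both")
  expect_error(consensus_cls(list(outc("both"), outc(c("both", "empty")))),
               "same compounds")
})

test_that("consensus is permutation-invariant and idempotent", {
  set.seed(55)
  models <- replicate(5, pv_df(runif(20), runif(20)), simplify = FALSE)
  base_p <- consensus_pvals(models, 0.2)
  outs <- lapply(models, function(m)
    prediction_set(m$p_active, m$p_inactive, 0.2))
  base_c <- consensus_cls(outs)
  for (i in 1:10) {
    perm <- sample(5L)
    expect_identical(consensus_pvals(models[perm], 0.2), base_p)
    expect_identical(consensus_cls(outs[perm]), base_c)
  }
  # k copies of one model equal that model
  one <- models[[1L]]
  rep_p <- consensus_pvals(replicate(4, one, simplify = FALSE), 0.2)
  expect_identical(rep_p$p_active, one$p_active)
  expect_identical(consensus_cls(replicate(4, outs[[1L]], simplify = FALSE)),
                   outs[[1L]])
})

test_that("missing votes are excluded per compound, not per model", {
  m1 <- pv_df(c(0.9, NA), c(0.1, NA))   # model fails on compound 2
  m2 <- pv_df(c(0.8, 0.6), c(0.2, 0.1))
  m3 <- pv_df(c(0.7, 0.4), c(0.3, 0.05))
  cp <- consensus_pvals(list(m1, m2, m3), 0.2)
  expect_identical(cp$p_active[2L], 0.5)  # median of the two reporting models
  o1 <- prediction_set(m1$p_active, m1$p_inactive, 0.2)
  o2 <- prediction_set(m2$p_active, m2$p_inactive, 0.2)
  o3 <- prediction_set(m3$p_active, m3$p_inactive, 0.2)
  cc <- consensus_cls(list(o1, o2, o3))
  expect_false(anyNA(cc))
})

test_that("consensus sets resolve and missing members raise configuration errors", {
  expect_identical(length(consensus_set("set2")), 7L)
  expect_true("ngramsPE" %in% consensus_set("set2"))
  expect_true("Core-Substituent_fps" %in% consensus_set("set1"))
  expect_error(hazcp:::.check_members(consensus_set("set2"),
                                      c("ngram_4_hashed_64")),
               "requires fitted models")
  expect_error(hazcp:::.check_members("ngramsPE", "ngramsPE"),
               "at least two")
})

test_that("median consensus preserves nesting across significance levels", {
  set.seed(66)
  models <- replicate(4, pv_df(runif(30), runif(30)), simplify = FALSE)
  eps <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  sets <- lapply(eps, function(e) consensus_pvals(models, e)$outcome)
  for (i in seq_len(length(eps) - 1L)) {
    a1 <- sets[[i]] %in% c("single_active", "both")
    a2 <- sets[[i + 1L]] %in% c("single_active", "both")
    i1 <- sets[[i]] %in% c("single_inactive", "both")
    i2 <- sets[[i + 1L]] %in% c("single_inactive", "both")
    expect_true(all(a1 | !a2))
    expect_true(all(i1 | !i2))
  }
})
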