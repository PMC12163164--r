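test_that("generated datasets hit the target composition and standardize cleanly", {
  cfg <- synthetic_config(n_compounds = 1000L, active_fraction = 0.1,
                          label_noise = 0, seed = 3L)
  d <- generate_dataset(cfg)
  expect_identical(nrow(d), 1000L)
  expect_true(all(d$valid))
  # binomial bounds around the target active fraction
  se3 <- 3 * sqrt(0.1 * 0.9 / 1000)
  expect_gt(mean(d$motif), 0.1 - se3)
  expect_lt(mean(d$motif), 0.1 + se3)
  # noise 0: label is exactly motif presence, so a motif lookup is perfect
  expect_identical(d$label, as.integer(d$motif))
  # determinism
  expect_identical(generate_dataset(cfg, standardize = FALSE),
                   generate_dataset(cfg, standardize = FALSE))
  expect_false(identical(
    generate_dataset(synthetic_config(n_compounds = 100L, seed = 1L),
                     standardize = FALSE),
    generate_dataset(synthetic_config(n_compounds = 100L, seed = 2L),
                     standardize = FALSE)))
})

test_that("salt fragments appear at the configured rate and survive the pipeline", {
  d <- generate_dataset(synthetic_config(n_compounds = 600L,
                                         salt_fraction = 0.25, seed = 9L))
  frac_salt <- mean(grepl(".", d$smiles_raw, fixed = TRUE))
  expect_gt(frac_salt, 0.25 - 3 * sqrt(0.25 * 0.75 / 600))
  expect_lt(frac_salt, 0.25 + 3 * sqrt(0.25 * 0.75 / 600))
  expect_true(all(d$valid))
  # N-gram featurization handles every salt-containing record
  salted <- d[grepl(".", d$smiles_raw, fixed = TRUE), ]
  ft <- featurize_dataset(salted, "ngram_4_hashed_64")
  expect_identical(nrow(ft$x), nrow(salted))
})

test_that("label noise degrades the motif-label association monotonically", {
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    s <- 0
    for (i in 1:2) for (j in 1:2)
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    s
  }
  mis <- vapply(c(0, 0.1, 0.3), function(nz) {
    d <- generate_dataset(synthetic_config(n_compounds = 1500L,
                                           label_noise = nz, seed = 31L),
                          standardize = FALSE)
    mi(d$motif, d$label)
  }, numeric(1))
  expect_true(all(diff(mis) < 0))
})

test_that("imbalance profiles mirror the documented class ratios", {
  pr <- imbalance_profiles(n = 500L, seed = 2L)
  expect_equal(pr[["H30x-like"]]$active_fraction, 448 / 13556,
               tolerance = 1e-12)
  expect_equal(pr[["H41x-like"]]$active_fraction, 4847 / 9887,
               tolerance = 1e-12)
  expect_identical(length(pr), 10L)
  # every profile generates without error at n=500
  for (nm in names(pr)) {
    d <- generate_dataset(pr[[nm]], standardize = FALSE)
    expect_identical(nrow(d), 500L)
  }
})
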