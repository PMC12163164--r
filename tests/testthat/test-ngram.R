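test_that("dictionary codes are unique 3-digit integers covering canonical SMILES", {
  d <- smiles_dictionary()
  expect_false(any(duplicated(d)))
  expect_false(any(duplicated(names(d))))
  expect_true(all(d >= 101L & d <= 177L))
  expect_identical(unname(d[c("a", "z", "A", "Z", "0", "9", "|")]),
                   c(101L, 126L, 127L, 152L, 164L, 173L, 177L))
  # every character the canonical writer emits on a diverse molecule bank
  bank <- synthetic_smiles_bank(100L)
  chars <- unique(unlist(strsplit(bank, "")))
  expect_true(all(chars %in% names(d)))
})

test_that("window codes concatenate dictionary digits exactly", {
  expect_identical(encode_window("abcd"), "101102103104")
  expect_identical(encode_window("bcda"), "102103104101")
  expect_identical(encode_window("cdag"), "103104101107")
  # 6-grams exceed double precision and must still be exact
  expect_identical(encode_window("abcdag"), "101102103104101107")
  expect_error(encode_window("ab~d"), "not in the N-gram dictionary")
})

test_that("sliding-window hashed counts match the worked example", {
  v <- encode_ngram_counts("abcdag", 4L, 1024L)
  expect_identical(which(v > 0L) - 1L, c(576L, 613L, 755L))
  expect_identical(sum(v), 3L)
  # repeated window increments its position
  v2 <- encode_ngram_counts("abcdabcd", 4L, 1024L)
  expect_identical(v2[576L + 1L], 2L)
  oracle <- py_window_positions(c("abcd", "bcda", "cdab", "dabc"), 1024L)
  expect_identical(sort(which(v2 > 0L) - 1L), sort(unique(oracle)))
  # string shorter than n gives the zero vector
  expect_identical(encode_ngram_counts("abc", 4L, 1024L), integer(1024L))
  expect_error(encode_ngram_counts("ab?d", 4L, 64L), "'\\?' at position 3")
})

test_that("count conservation: sum of counts equals number of windows", {
  set.seed(11)
  for (s in random_dict_strings(200L, 1L, 30L)) {
    for (n in c(4L, 6L)) {
      v <- encode_ngram_counts(s, n, 64L)
      expect_identical(sum(v), max(0L, nchar(s) - n + 1L))
    }
  }
})

test_that("hashed positions agree with a big-integer modulo oracle", {
  set.seed(21)
  for (n in c(4L, 6L)) {
    wins <- random_dict_strings(50L, n, n)
    for (m in c(64L, 256L, 1024L)) {
      oracle <- py_window_positions(wins, m)
      mine <- vapply(wins, function(w) which(encode_ngram_counts(w, n, m) > 0L) - 1L,
                     integer(1))
      expect_identical(unname(mine), oracle)
    }
  }
})

test_that("appending one character adds exactly one window", {
  set.seed(31)
  for (s in random_dict_strings(30L, 4L, 25L)) {
    v1 <- encode_ngram_counts(s, 4L, 256L)
    v2 <- encode_ngram_counts(paste0(s, "x"), 4L, 256L)
    diff <- v2 - v1
    expect_identical(sum(diff), 1L)
    expect_true(all(diff >= 0L))
  }
})
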