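# Shared fixtures and independent oracles for the test suite.

# Independent arbitrary-precision oracle for window hashing: Python big
# integers concatenate the 3-digit codes and reduce modulo hash_len.
# Returns one integer position per window string.
py_window_positions <- function(windows, hash_len) {
  dict <- smiles_dictionary()
  payload <- jsonlite::toJSON(list(windows = windows, m = hash_len,
                                   dict = as.list(dict)),
                              auto_unbox = TRUE)
  tf <- tempfile(fileext = ".json"); writeLines(payload, tf)
  script <- paste(
    "import json,sys",
    sprintf("d=json.load(open('%s'))", tf),
    "dd=d['dict']",
    "for w in d['windows']:",
    "    code=int(''.join('%03d'%dd[c] for c in w))",
    "    print(code%d['m'])",
    sep = "\n")
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  out <- system2("python", sf, stdout = TRUE)
  unlink(c(tf, sf))
  as.integer(out)
}

# Random strings over the dictionary alphabet (used by N-gram property
# tests; not required to be chemically meaningful).
random_dict_strings <- function(n, min_len = 1L, max_len = 40L) {
  alphabet <- names(smiles_dictionary())
  vapply(seq_len(n), function(i) {
    L <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
    paste0(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Small bank of diverse, valid, standardized SMILES built from the
# synthetic grammar (cached per session).
synthetic_smiles_bank <- local({
  cache <- NULL
  function(n = 100L, seed = 424L) {
    if (is.null(cache) || length(cache) < n) {
      d <- generate_dataset(synthetic_config(n_compounds = max(n, 100L),
                                             salt_fraction = 0.15,
                                             seed = seed))
      cache <<- d$smiles_std[d$valid]
    }
    cache[seq_len(n)]
  }
})

# Quick separable feature matrix + labels for ICP unit tests: class 1
# concentrates mass on the first features.
toy_classification <- function(n, p = 20L, seed = 1L, separation = 2) {
  set.seed(seed)
  y <- rbinom(n, 1L, 0.4)
  x <- matrix(rpois(n * p, 1), n, p)
  x[, 1L] <- x[, 1L] + y * separation
  x[, 2L] <- x[, 2L] + (1L - y) * separation
  list(x = x, y = y)
}

# Outcome factor helper
outc <- function(...) factor(c(...), levels = c("single_active",
                                                "single_inactive",
                                                "both", "empty"))
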