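# Featurizer specifications and dataset-level featurization.

#' Construct a featurizer specification
#'
#' A featurizer spec names one of the registered descriptor families and
#' fixes its parameters. The registered configurations are:
#' `ngram_4_hashed_64/256/1024`, `ngram_6_hashed_64/256/1024` (character
#' N-grams of canonical SMILES, counts), `ngramsPE` (pair-encoded token
#' N-grams, n=4, 1024), `deepsmiles` and `selfies` (transformed strings,
#' character N-grams, n=4, 1024), `morgan2`/`morgan4` (circular counts,
#' 1024), `SMILES_extnd_connect_fps_2`/`_4` (binary circular, 1024) and
#' `Core-Substituent_fps` (binary, length 1000; adapter contract only — an
#' external provider function must be registered, see `adapter`).
#'
#' @param name Registered configuration name (see above).
#' @param adapter Optional function `function(smiles) -> numeric vector`
#'   implementing an external fingerprint provider (required for the
#'   `core_substituent` family).
#' @return An object of class `featurizer_spec` with fields `name`,
#'   `family`, `n`, `hash_len`, `radius`, `value_kind`.
#' @export
#' @examples
#' featurizer_spec("ngram_4_hashed_1024")
featurizer_spec <- function(name, adapter = NULL) {
  reg <- .featurizer_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown featurizer '%s'; registered: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  spec <- reg[[name]]
  spec$name <- name
  spec$adapter <- adapter
  if (spec$family == "core_substituent" && is.null(adapter))
    stop("'Core-Substituent_fps' is an adapter contract: supply an external ",
         "provider via `adapter=`", call. = FALSE)
  class(spec) <- "featurizer_spec"
  spec
}

.featurizer_registry <- function() {
  ng <- function(n, h) list(family = "ngram", n = n, hash_len = h,
                            radius = NA_integer_, value_kind = "counts")
  list(
    ngram_4_hashed_64    = ng(4L, 64L),
    ngram_4_hashed_256   = ng(4L, 256L),
    ngram_4_hashed_1024  = ng(4L, 1024L),
    ngram_6_hashed_64    = ng(6L, 64L),
    ngram_6_hashed_256   = ng(6L, 256L),
    ngram_6_hashed_1024  = ng(6L, 1024L),
    ngramsPE   = list(family = "ngram_pe", n = 4L, hash_len = 1024L,
                      radius = NA_integer_, value_kind = "counts"),
    deepsmiles = list(family = "deepsmiles_ngram", n = 4L, hash_len = 1024L,
                      radius = NA_integer_, value_kind = "counts"),
    selfies    = list(family = "selfies_ngram", n = 4L, hash_len = 1024L,
                      radius = NA_integer_, value_kind = "counts"),
    morgan2    = list(family = "morgan", n = NA_integer_, hash_len = 1024L,
                      radius = 2L, value_kind = "counts"),
    morgan4    = list(family = "morgan", n = NA_integer_, hash_len = 1024L,
                      radius = 4L, value_kind = "counts"),
    SMILES_extnd_connect_fps_2 =
      list(family = "secfp", n = NA_integer_, hash_len = 1024L,
           radius = 2L, value_kind = "binary"),
    SMILES_extnd_connect_fps_4 =
      list(family = "secfp", n = NA_integer_, hash_len = 1024L,
           radius = 4L, value_kind = "binary"),
    `Core-Substituent_fps` =
      list(family = "core_substituent", n = NA_integer_, hash_len = 1000L,
           radius = NA_integer_, value_kind = "binary")
  )
}

#' Names of all registered featurizer configurations
#' @param implemented_only Drop adapter-only families (default TRUE).
#' @return Character vector of configuration names.
#' @export
featurizer_names <- function(implemented_only = TRUE) {
  nm <- names(.featurizer_registry())
  if (implemented_only) nm <- setdiff(nm, "Core-Substituent_fps")
  nm
}

#' @export
print.featurizer_spec <- function(x, ...) {
  cat(sprintf("Featurizer '%s' (family %s): hash_len=%d%s%s, %s\n",
              x$name, x$family, x$hash_len,
              if (!is.na(x$n)) sprintf(", n=%d", x$n) else "",
              if (!is.na(x$radius)) sprintf(", radius=%d", x$radius) else "",
              x$value_kind))
  invisible(x)
}

# Featurize one standardized SMILES under a spec. `token_dict` carries the
# persisted pair-encoding token dictionary where applicable.
.featurize_one <- function(smiles, spec, token_dict = NULL) {
  switch(spec$family,
    ngram = encode_ngram_counts(smiles, spec$n, spec$hash_len),
    ngram_pe = {
      toks <- tokenize_pe(smiles)
      encode_token_ngrams(toks, spec$n, spec$hash_len, dict = token_dict)
    },
    deepsmiles_ngram =
      encode_ngram_counts(transform_deepsmiles(smiles), spec$n, spec$hash_len),
    selfies_ngram =
      encode_ngram_counts(transform_selfies(smiles), spec$n, spec$hash_len),
    morgan = morgan_counts(smiles, spec$radius, spec$hash_len),
    secfp = secfp_binary(smiles, spec$radius, spec$hash_len),
    core_substituent = {
      v <- spec$adapter(smiles)
      if (length(v) != spec$hash_len || !all(v %in% c(0, 1)))
        stop("adapter output violates the binary length-1000 contract",
             call. = FALSE)
      as.integer(v)
    },
    stop(sprintf("unknown featurizer family '%s'", spec$family), call. = FALSE)
  )
}

#' Featurize a standardized dataset
#'
#' Applies one featurizer to every valid record and returns the feature
#' matrix. For the pair-encoded family the token dictionary is built over
#' the whole dataset in first-seen order and returned for persistence, so
#' new molecules can be featurized consistently. Records whose
#' featurization fails are reported in `failed` (with messages), never
#' silently dropped.
#'
#' @param records Data frame with at least `smiles_std` (and optionally
#'   `id`); typically the output of [standardize_dataset()].
#' @param spec A [featurizer_spec()] or a registered configuration name.
#' @param token_dict Optional persisted token dictionary (pair-encoded
#'   family); built from the data when NULL.
#' @return List with `x` (matrix n_ok x hash_len), `row_index` (row numbers
#'   of `records` corresponding to the matrix rows), `failed` (data.frame:
#'   row, message), `spec`, and `token_dict` (or NULL).
#' @export
featurize_dataset <- function(records, spec, token_dict = NULL) {
  if (is.character(spec)) spec <- featurizer_spec(spec)
  smiles <- records$smiles_std
  if (is.null(smiles)) stop("records must carry a 'smiles_std' column",
                            call. = FALSE)
  ok_rows <- which(!is.na(smiles))
  if (spec$family == "ngram_pe" && is.null(token_dict)) {
    all_tokens <- unlist(lapply(smiles[ok_rows], tokenize_pe))
    token_dict <- token_dictionary(all_tokens)
  }
  rows <- vector("list", length(ok_rows))
  failed <- list()
  keep <- logical(length(ok_rows))
  for (k in seq_along(ok_rows)) {
    i <- ok_rows[k]
    v <- tryCatch(.featurize_one(smiles[i], spec, token_dict),
                  error = function(e) e)
    if (inherits(v, "error")) {
      failed[[length(failed) + 1L]] <-
        data.frame(row = i, message = conditionMessage(v))
    } else {
      rows[[k]] <- v; keep[k] <- TRUE
    }
  }
  if (!any(keep))
    stop("featurization failed for every record", call. = FALSE)
  x <- do.call(rbind, rows[keep])
  rownames(x) <- if (!is.null(records$id)) as.character(records$id[ok_rows[keep]])
  list(x = x, row_index = ok_rows[keep],
       failed = if (length(failed)) do.call(rbind, failed)
                else data.frame(row = integer(0), message = character(0)),
       spec = spec, token_dict = token_dict)
}
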