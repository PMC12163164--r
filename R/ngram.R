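#' Character dictionary for SMILES N-gram encoding
#'
#' Returns the fixed character-to-code dictionary used by the N-gram
#' featurizers: `'a'`..`'z'` map to 101..126, `'A'`..`'Z'` to 127..152,
#' then `' '` 153, `'\\'` 154, `'/'` 155, `'.'` 156, `'['` 157, `']'` 158,
#' `'('` 159, `')'` 160, `'='` 161, `'#'` 162, `'@'` 163, `'0'`..`'9'`
#' 164..173, `'+'` 174, `'-'` 175, `'%'` 176 and `'|'` 177. Every code is a
#' distinct 3-digit integer, so concatenating window codes is injective.
#' The dictionary covers every character the canonical SMILES writer can
#' emit (including ring-closure indices above 9, which use `'%'`).
#'
#' @return A named integer vector mapping single characters to 3-digit codes.
#' @export
#' @examples
#' d <- smiles_dictionary()
#' d[c("a", "b", "C", "[", "%")]
smiles_dictionary <- function() {
  chars <- c(letters, LETTERS, " ", "\\", "/", ".", "[", "]", "(", ")",
             "=", "#", "@", as.character(0:9), "+", "-", "%", "|")
  codes <- 101L + seq_along(chars) - 1L
  names(codes) <- chars
  codes
}

# Look up dictionary codes for each character of a string; errors name the
# first unknown character and its 1-based position.
.char_codes <- function(s, dict = smiles_dictionary()) {
  if (nchar(s) == 0L) return(integer(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  codes <- dict[chars]
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop(sprintf("character '%s' at position %d is not in the N-gram dictionary",
                 chars[i], i), call. = FALSE)
  }
  unname(codes)
}

#' Decimal concatenation code of one N-gram window
#'
#' Concatenates the 3-digit dictionary codes of the window's characters,
#' left to right, into one decimal integer. The result is exact for any
#' window length: it is returned as a decimal digit string because a
#' 6-gram code (18 digits) exceeds double precision.
#'
#' @param chars A single string: the window (all characters must be in the
#'   dictionary).
#' @param dict Code dictionary, by default [smiles_dictionary()].
#' @return The concatenated code as a character scalar of decimal digits.
#' @export
#' @examples
#' encode_window("abcd")  # "101102103104"
#' encode_window("bcda")  # "102103104101"
encode_window <- function(chars, dict = smiles_dictionary()) {
  codes <- .char_codes(chars, dict)
  paste0(codes, collapse = "")
}

# Reduce the decimal concatenation of `codes` (each `width` digits) modulo
# `m` without forming the big integer: Horner's rule in base 10^width.
# Intermediate values stay below m * 10^width, safe in doubles for the
# supported hash lengths.
.window_mod <- function(codes, m, width = 3L) {
  base <- 10^width
  r <- 0
  for (c in codes) r <- (r * base + c) %% m
  r
}

#' Hashed N-gram count vector of a string
#'
#' Slides a window of `n` characters one position at a time over `s`. Each
#' window's characters are mapped to their 3-digit dictionary codes, the
#' codes are concatenated into one decimal integer, and the integer modulo
#' `hash_len` gives the vector position (0-based) whose count is
#' incremented. A string shorter than `n` yields the all-zero vector.
#'
#' The modulo of the (possibly 18-digit) concatenation is computed exactly
#' by modular Horner evaluation, so no precision is lost for 6-grams.
#'
#' @param s Input string (SMILES or any transform of it).
#' @param n Window length, typically 4 or 6.
#' @param hash_len Vector length: 64, 256 or 1024.
#' @param dict Code dictionary, by default [smiles_dictionary()].
#' @return Integer vector of length `hash_len`; `sum(result)` equals
#'   `max(0, nchar(s) - n + 1)`.
#' @export
#' @examples
#' v <- encode_ngram_counts("abcdag", 4, 1024)
#' which(v > 0) - 1L  # 0-based positions 576, 613, 755
encode_ngram_counts <- function(s, n = 4L, hash_len = 1024L,
                                dict = smiles_dictionary()) {
  stopifnot(length(s) == 1L, n >= 1L, hash_len >= 2L)
  codes <- .char_codes(s, dict)
  L <- length(codes)
  out <- integer(hash_len)
  if (L < n) return(out)
  # Horner over all windows at once: column j holds code j of every window.
  nwin <- L - n + 1L
  r <- numeric(nwin)
  for (j in seq_len(n)) r <- (r * 1000 + codes[j:(j + nwin - 1L)]) %% hash_len
  tabulate(as.integer(r) + 1L, nbins = hash_len)
}

#' Assign fixed-width codes to a token vocabulary
#'
#' Builds the token dictionary used by [encode_token_ngrams()]: each unique
#' token, in first-seen order, receives a zero-padded fixed-width integer
#' code. Fixed width keeps the decimal concatenation of token codes
#' injective, mirroring the 3-digit character dictionary.
#'
#' @param tokens Character vector of tokens (duplicates allowed).
#' @param width Code width in digits (default 4).
#' @param start First code (default 1001, so codes never have leading zeros).
#' @return Named integer vector mapping tokens to codes, with attribute
#'   `"width"`.
#' @export
token_dictionary <- function(tokens, width = 4L, start = 1001L) {
  vocab <- unique(tokens)
  if (length(vocab) > 10^width - start)
    stop(sprintf("token vocabulary (%d) overflows the %d-digit code width",
                 length(vocab), width), call. = FALSE)
  codes <- start + seq_along(vocab) - 1L
  names(codes) <- vocab
  attr(codes, "width") <- as.integer(width)
  codes
}

#' Hashed N-gram counts over a token sequence
#'
#' Token-level analogue of [encode_ngram_counts()]: windows of `n`
#' consecutive token codes are concatenated decimally (at the dictionary's
#' fixed width) and reduced modulo `hash_len` with counts. With
#' single-character tokens and `dict = smiles_dictionary()` this reproduces
#' the character-level encoder exactly.
#'
#' @param tokens Character vector of tokens (empty vector gives zeros).
#' @param n Window length in tokens (default 4).
#' @param hash_len Vector length (default 1024).
#' @param dict Token dictionary from [token_dictionary()]; defaults to one
#'   built from `tokens` themselves (use a persisted dictionary to featurize
#'   consistently across molecules).
#' @return Integer vector of length `hash_len`.
#' @export
encode_token_ngrams <- function(tokens, n = 4L, hash_len = 1024L,
                                dict = token_dictionary(tokens)) {
  stopifnot(n >= 1L, hash_len >= 2L)
  out <- integer(hash_len)
  L <- length(tokens)
  if (L < n) return(out)
  codes <- dict[tokens]
  if (anyNA(codes)) {
    i <- which(is.na(codes))[1L]
    stop(sprintf("token '%s' at position %d is not in the token dictionary",
                 tokens[i], i), call. = FALSE)
  }
  width <- attr(dict, "width")
  if (is.null(width)) width <- max(nchar(as.character(dict)))
  base <- 10^width
  nwin <- L - n + 1L
  r <- numeric(nwin)
  cds <- unname(codes)
  for (j in seq_len(n)) r <- (r * base + cds[j:(j + nwin - 1L)]) %% hash_len
  tabulate(as.integer(r) + 1L, nbins = hash_len)
}
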