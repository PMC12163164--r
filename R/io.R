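# Dataset reading, structure standardization and cross-validation splits.

#' Read a labelled SMILES dataset from CSV
#'
#' Reads a UTF-8 CSV with a header row and returns one record per row, in
#' file order. Labels are mapped to 0/1: the values in `active_values`
#' (case-insensitive) and `"1"` become 1, those in `inactive_values` and
#' `"0"` become 0; anything else is a row-level error naming the offending
#' rows.
#'
#' @param path CSV file path.
#' @param id_col,smiles_col,label_col Column names (defaults `id`,
#'   `smiles`, `label`).
#' @param active_values,inactive_values Accepted label synonyms.
#' @param sep Field delimiter (default `","`).
#' @return Data frame with columns `id`, `smiles_raw`, `label`.
#' @export
read_dataset <- function(path, id_col = "id", smiles_col = "smiles",
                         label_col = "label",
                         active_values = c("1", "active"),
                         inactive_values = c("0", "inactive"),
                         sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  for (col in c(id_col, smiles_col, label_col)) {
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
  }
  if (nrow(df) == 0L)
    return(data.frame(id = character(0), smiles_raw = character(0),
                      label = integer(0)))
  raw <- tolower(trimws(df[[label_col]]))
  lab <- ifelse(raw %in% tolower(active_values), 1L,
                ifelse(raw %in% tolower(inactive_values), 0L, NA_integer_))
  if (anyNA(lab)) {
    bad <- which(is.na(lab))
    stop(sprintf("unparseable label%s in row%s %s (values: %s)",
                 if (length(bad) > 1L) "s" else "",
                 if (length(bad) > 1L) "s" else "",
                 paste(bad, collapse = ", "),
                 paste(unique(df[[label_col]][bad]), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(id = df[[id_col]], smiles_raw = df[[smiles_col]], label = lab)
}

#' Standardize SMILES strings to canonical form
#'
#' Canonicalizes each SMILES with the Open Babel canonical writer
#' (via \pkg{ChemmineOB}). Unparseable structures return `NA` (the
#' invalid marker) rather than raising; salts and multi-fragment
#' `.`-SMILES are kept intact. Standardization is idempotent: applying it
#' to its own output returns the same string.
#'
#' Conversion is batched for speed; because an invalid structure aborts an
#' Open Babel batch, the batch is resumed after each failure and the
#' failing entry marked invalid.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
#' @examples
#' \donttest{
#' standardize_smiles(c("OCC", "CCO", "C1CC"))  # "CCO", "CCO", NA
#' }
standardize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  while (length(todo) > 0L) {
    titles <- paste0("m", todo)
    input <- paste0(smiles[todo], " ", titles, "\n", collapse = "")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", input),
      error = function(e) "")
    lines <- strsplit(res, "\n", fixed = TRUE)[[1L]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      can <- trimws(parts[1L])
      ttl <- if (length(parts) > 1L) trimws(parts[2L]) else ""
      idx <- suppressWarnings(as.integer(sub("^m", "", ttl)))
      if (!is.na(idx) && nzchar(can)) {
        out[idx] <- can
        got <- c(got, idx)
      }
    }
    remaining <- setdiff(todo, got)
    if (length(remaining) == length(todo)) {
      # nothing converted: first pending entry is invalid; skip it
      remaining <- remaining[-1L]
    } else if (length(remaining) > 0L) {
      # batch aborted at the first failure among the pending entries
      remaining <- remaining[-1L]
    }
    todo <- remaining
  }
  out
}

#' Standardize a dataset of molecule records
#'
#' Adds `smiles_std` (canonical SMILES or `NA`) and `valid` columns to the
#' output of [read_dataset()]. Invalid structures are kept in the table,
#' flagged, and reported via a message; downstream functions use only
#' valid rows.
#'
#' @param records Data frame with `smiles_raw` (and typically `id`,
#'   `label`).
#' @param dedup Drop later duplicates of the same canonical SMILES
#'   (default FALSE: no deduplication).
#' @return The input with `smiles_std` and `valid` columns appended.
#' @export
standardize_dataset <- function(records, dedup = FALSE) {
  records$smiles_std <- standardize_smiles(records$smiles_raw)
  records$valid <- !is.na(records$smiles_std)
  n_bad <- sum(!records$valid)
  if (n_bad > 0L)
    message(sprintf("%d of %d structures failed standardization and are flagged invalid",
                    n_bad, nrow(records)))
  if (dedup) {
    dup <- duplicated(records$smiles_std) & records$valid
    if (any(dup)) {
      message(sprintf("dropping %d duplicate canonical structures", sum(dup)))
      records <- records[!dup, , drop = FALSE]
      rownames(records) <- NULL
    }
  }
  records
}

#' Cross-validation folds with per-fold calibration sets
#'
#' Builds `k` test folds covering all records exactly once. Within each
#' fold's complement (the training pool), a random `cal_frac` fraction is
#' set aside as the conformal calibration set and the rest is the proper
#' training set. Indices are shuffled before folding by default; with
#' `shuffle = FALSE` folds are contiguous blocks in input order.
#'
#' @param n_records Number of records.
#' @param k Number of folds (default 10).
#' @param cal_frac Calibration fraction of each training pool (default 0.2).
#' @param seed Integer seed; splits are reproducible given the seed.
#' @param shuffle Shuffle before folding (default TRUE).
#' @param stratify Optional 0/1 label vector; when supplied, calibration
#'   sets are drawn per class (off by default: pass NULL).
#' @return List of `k` objects of class `fold_split`, each with
#'   `fold_index` (0-based), `train_idx`, `cal_idx`, `test_idx`.
#' @export
#' @examples
#' f <- make_folds(100, k = 10, cal_frac = 0.2, seed = 1)
#' lengths(f[[1]][c("train_idx", "cal_idx", "test_idx")])  # 72, 18, 10
make_folds <- function(n_records, k = 10L, cal_frac = 0.2, seed,
                       shuffle = TRUE, stratify = NULL) {
  if (n_records < k) stop("n_records must be at least k", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (cal_frac <= 0 || cal_frac >= 1) stop("cal_frac must be in (0,1)",
                                           call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  old <- .hold_rng(seed)
  on.exit(.restore_rng(old))
  perm <- if (shuffle) sample.int(n_records) else seq_len(n_records)
  # contiguous blocks of the permutation, sizes differing by at most one
  sizes <- rep(n_records %/% k, k)
  extra <- n_records %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  folds <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- sort(perm[starts[i]:ends[i]])
    pool <- sort(setdiff(seq_len(n_records), test_idx))
    n_cal <- round(cal_frac * length(pool))
    cal_idx <- if (is.null(stratify)) {
      sort(sample(pool, n_cal))
    } else {
      y <- stratify[pool]
      n1 <- round(n_cal * mean(y == 1))
      c1 <- sample(pool[y == 1], min(n1, sum(y == 1)))
      c0 <- sample(pool[y == 0], min(n_cal - length(c1), sum(y == 0)))
      sort(c(c0, c1))
    }
    folds[[i]] <- structure(
      list(fold_index = i - 1L,
           train_idx = setdiff(pool, cal_idx),
           cal_idx = cal_idx,
           test_idx = test_idx),
      class = "fold_split")
  }
  folds
}

#' Fold assignments as a long table
#'
#' @param folds Output of [make_folds()].
#' @param ids Optional record identifiers (defaults to indices).
#' @return Data frame with columns `id`, `fold`, `role` (train/cal/test).
#' @export
fold_table <- function(folds, ids = NULL) {
  rows <- lapply(folds, function(f) {
    idx <- c(f$train_idx, f$cal_idx, f$test_idx)
    data.frame(id = if (is.null(ids)) idx else ids[idx],
               fold = f$fold_index,
               role = rep(c("train", "cal", "test"),
                          c(length(f$train_idx), length(f$cal_idx),
                            length(f$test_idx))))
  })
  do.call(rbind, rows)
}

# Seed the RNG for a reproducible block, saving the caller's state.
.hold_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
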