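# Consensus predictors over per-descriptor conformal models.

#' Descriptor sets for consensus modelling
#'
#' `all` is every registered configuration; `set1` combines fingerprints
#' and transforms (`Core-Substituent_fps`, `deepsmiles`, `morgan2`,
#' `ngramsPE`, `SMILES_extnd_connect_fps_2`, `selfies`,
#' `ngram_4_hashed_1024`); `set2` is the pure N-gram set
#' (`ngram_4_hashed_64/256/1024`, `ngram_6_hashed_64/256/1024`,
#' `ngramsPE`), the recommended default because the N-gram encoders handle
#' every character that occurs in SMILES strings, salts and metals
#' included.
#'
#' @param set One of `"all"`, `"set1"`, `"set2"`.
#' @return Character vector of configuration names.
#' @export
consensus_set <- function(set = c("set2", "set1", "all")) {
  set <- match.arg(set)
  switch(set,
    all = names(.featurizer_registry()),
    set1 = c("Core-Substituent_fps", "deepsmiles", "morgan2", "ngramsPE",
             "SMILES_extnd_connect_fps_2", "selfies", "ngram_4_hashed_1024"),
    set2 = c("ngram_4_hashed_64", "ngram_4_hashed_256", "ngram_4_hashed_1024",
             "ngram_6_hashed_64", "ngram_6_hashed_256", "ngram_6_hashed_1024",
             "ngramsPE"))
}

# Validate that the models named by a consensus set are all present.
.check_members <- function(members, available) {
  missing <- setdiff(members, available)
  if (length(missing) > 0L)
    stop(sprintf("consensus set requires fitted models for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (length(members) < 2L)
    stop("a consensus needs at least two models", call. = FALSE)
  invisible(TRUE)
}

#' Median-p-value consensus
#'
#' For each compound and each class, takes the median of the class
#' p-values across models (even counts use the mean of the two central
#' values; a model's missing value — e.g. a featurization failure on that
#' compound — is excluded from that compound's median). The prediction set
#' is then derived from the median pair at the given significance level.
#'
#' @param pvals_list List of p-value tables (each with `p_active`,
#'   `p_inactive`, all for the same compounds in the same order).
#' @param significance Significance level in (0, 1).
#' @return Data frame with `p_active`, `p_inactive` (medians) and
#'   `outcome`.
#' @export
consensus_pvals <- function(pvals_list, significance) {
  stopifnot(length(pvals_list) >= 1L)
  ns <- vapply(pvals_list, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all models must report p-values for the same compounds", call. = FALSE)
  pa <- vapply(pvals_list, function(d) d$p_active, numeric(ns[1L]))
  pi_ <- vapply(pvals_list, function(d) d$p_inactive, numeric(ns[1L]))
  if (ns[1L] == 1L) { pa <- matrix(pa, 1L); pi_ <- matrix(pi_, 1L) }
  med_a <- apply(pa, 1L, stats::median, na.rm = TRUE)
  med_i <- apply(pi_, 1L, stats::median, na.rm = TRUE)
  data.frame(p_active = med_a, p_inactive = med_i,
             outcome = prediction_set(med_a, med_i, significance))
}

#' Majority-vote consensus
#'
#' For each compound, the outcome with the most votes across models wins;
#' ties are broken by the fixed priority active single > inactive single >
#' both > empty. Missing votes (NA) are excluded for that compound only.
#'
#' @param outcomes_list List of outcome factors (as produced by
#'   [prediction_set()] at a common significance level), same compounds in
#'   the same order.
#' @return Factor of consensus outcomes.
#' @export
#' @examples
#' a <- factor("single_active",   levels = hazcp:::.outcome_levels)
#' b <- factor("single_inactive", levels = hazcp:::.outcome_levels)
#' d <- factor("both",            levels = hazcp:::.outcome_levels)
#' consensus_cls(list(a, b, d))  # three-way tie resolves to single_active
consensus_cls <- function(outcomes_list) {
  stopifnot(length(outcomes_list) >= 1L)
  ns <- lengths(outcomes_list)
  if (length(unique(ns)) != 1L)
    stop("all models must report outcomes for the same compounds", call. = FALSE)
  n <- ns[1L]
  votes <- vapply(outcomes_list,
                  function(o) as.integer(factor(as.character(o),
                                                levels = .outcome_levels)),
                  integer(n))
  if (n == 1L) votes <- matrix(votes, 1L)
  idx <- apply(votes, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_integer_)
    tab <- tabulate(v, nbins = 4L)
    which.max(tab)  # first maximum = priority order of the levels
  })
  factor(.outcome_levels[idx], levels = .outcome_levels)
}
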