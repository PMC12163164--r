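# Synthetic labelled SMILES datasets with planted toxicophore motifs.
#
# Molecules are assembled from a fragment grammar: a scaffold template
# with one substitution slot receives either a toxicophore motif fragment
# (actives) or a benign substituent (inactives), optional extra benign
# decoration, and, for a configurable fraction, an appended counter-ion or
# solvate fragment. The binary label is "contains >= 1 motif", XOR-flipped
# with probability `label_noise` to emulate conflicting annotations.
# Because labels are a function of structure, featurizers genuinely carry
# signal and both CP efficiency and base-classifier accuracy are
# meaningfully exercised.

.default_motifs <- c(
  nitro = "[N+](=O)[O-]",
  trichloromethyl = "C(Cl)(Cl)Cl",
  nitroso = "N=O",
  thiocyanate = "SC#N"
)

.benign_subs <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "CO", "CCO",
                  "C(C)C", "F", "Cl", "CCN")

.scaffolds <- c(
  "c1ccc(%s)cc1",        # benzene
  "c1ccnc(%s)c1",        # pyridine
  "C1CCC(%s)CC1",        # cyclohexane
  "CC(%s)CO",            # branched chain
  "OCC(%s)CC",           # alcohol chain
  "CC(C)(%s)CO"          # quaternary-ish chain
)

.salt_frags <- c(".[Na+].[Cl-]", ".Cl", ".O", ".[K+].[Br-]")

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the generator's standard study conditions: 2000
#' compounds, 30% actives, 5% label noise (emulating discarded/conflicting
#' annotations), 10% salt/solvate fragments, and four planted toxicophore
#' motifs (nitro, trichloromethyl, nitroso, thiocyanate) on six scaffold
#' templates.
#'
#' @param n_compounds Number of molecules.
#' @param active_fraction Target fraction of motif-carrying molecules,
#'   in (0, 1).
#' @param motifs Named character vector of motif fragments (inserted as
#'   substituents); must be nonempty.
#' @param label_noise Probability of flipping a label, in [0, 0.5).
#' @param salt_fraction Fraction of molecules with an appended
#'   counter-ion/solvate fragment, in [0, 1].
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_compounds = 2000L, active_fraction = 0.3,
                             motifs = .default_motifs, label_noise = 0.05,
                             salt_fraction = 0.1, seed = 1L) {
  stopifnot(n_compounds >= 1L,
            active_fraction > 0, active_fraction < 1,
            length(motifs) >= 1L,
            label_noise >= 0, label_noise < 0.5,
            salt_fraction >= 0, salt_fraction <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 active_fraction = active_fraction, motifs = motifs,
                 label_noise = label_noise, salt_fraction = salt_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labelled synthetic SMILES dataset
#'
#' Every generated SMILES standardizes successfully; the achieved active
#' fraction is binomial around the target. Ground-truth columns `motif`
#' (presence) and `motif_name` are included so the labelling mechanism is
#' fully observable.
#'
#' @param config A [synthetic_config()].
#' @param standardize Also run [standardize_dataset()] on the result
#'   (default TRUE).
#' @return Data frame with columns `id`, `smiles_raw`, `label`, `motif`,
#'   `motif_name` (and `smiles_std`, `valid` when standardized).
#' @export
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_config(n_compounds = 50, seed = 7))
#' table(d$label)
#' }
generate_dataset <- function(config = synthetic_config(),
                             standardize = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .hold_rng(config$seed)
  on.exit(.restore_rng(old))
  n <- config$n_compounds
  has_motif <- stats::rbinom(n, 1L, config$active_fraction) == 1L
  scaf <- sample(.scaffolds, n, replace = TRUE)
  motif_idx <- sample(length(config$motifs), n, replace = TRUE)
  benign <- sample(.benign_subs, n, replace = TRUE)
  extra <- sample(c("", "C", "CC", "O"), n, replace = TRUE)
  salts <- ifelse(stats::runif(n) < config$salt_fraction,
                  sample(.salt_frags, n, replace = TRUE), "")
  sub <- ifelse(has_motif, unname(config$motifs[motif_idx]), benign)
  # extra benign decoration is prepended to the substituent where it stays
  # syntactically valid (simple chain prefix)
  core <- sprintf(scaf, paste0(extra, sub))
  smiles <- paste0(core, salts)
  flip <- stats::runif(n) < config$label_noise
  label <- as.integer(xor(has_motif, flip))
  out <- data.frame(
    id = sprintf("syn%05d", seq_len(n)),
    smiles_raw = smiles,
    label = label,
    motif = has_motif,
    motif_name = ifelse(has_motif, names(config$motifs)[motif_idx],
                        NA_character_))
  if (standardize) out <- standardize_dataset(out)
  out
}

#' Named generator profiles mirroring realistic class imbalance
#'
#' Returns configurations whose active fractions reproduce the imbalance
#' ratios of the ten hazard-statement groups commonly modelled for
#' REACH-registered substances, from strongly imbalanced acute oral
#' toxicity (about 3% actives) to nearly balanced chronic aquatic toxicity
#' (about 49% actives), scaled to `n` compounds.
#'
#' @param n Compounds per profile (default 2000).
#' @param seed Seed recorded in each profile.
#' @return Named list of [synthetic_config()] objects.
#' @export
imbalance_profiles <- function(n = 2000L, seed = 1L) {
  counts <- list(
    "H30x-like"   = c(448, 13108),
    "H31x0123-like" = c(1067, 5942),
    "H31x57-like" = c(4931, 5342),
    "H33x0123-like" = c(393, 8433),
    "H33x45-like" = c(1708, 1994),
    "H34x-like"   = c(393, 8433),
    "H35x-like"   = c(510, 2769),
    "H36x01-like" = c(903, 4905),
    "H40x-like"   = c(1754, 7615),
    "H41x-like"   = c(4847, 5040))
  lapply(counts, function(ct)
    synthetic_config(n_compounds = n,
                     active_fraction = ct[1] / sum(ct),
                     seed = seed))
}
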