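---
title: "Conformal prediction of hazard classes from SMILES N-grams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal prediction of hazard classes from SMILES N-grams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory hazard communication under the EU CLP regulation (the EU
adoption of GHS) assigns hazard statements — H-statement codes such as
H301, "toxic if swallowed" — to substances. For novel compounds with
little experimental data, in-silico models can triage likely hazard
classes, but a bare class label is of limited regulatory value: what is
needed is a prediction together with a calibrated statement of how often
such predictions are wrong, separately for the hazardous and the
non-hazardous class. hazcp implements that combination: string-based
molecular featurization, a random-forest classifier, and a Mondrian
inductive conformal prediction (ICP) layer that converts classifier
output into set-valued predictions with class-conditional error control.

## The model

### Mondrian inductive conformal prediction

Let a binary training set be split into a *proper training set* and a
*calibration set*. A probability forest is fitted on the proper training
set only. For any example and hypothesized class $c$, the nonconformity
score is

$$\alpha_c(x) = 1 - \hat p_c(x),$$

the complement of the forest's predicted probability for $c$ — the common
default for probabilistic base classifiers: monotone, bounded in $[0,1]$.
Each calibration example contributes the score of its *true* class to
that class's calibration list (the Mondrian taxonomy: one list per
class). For a test example, the p-value for class $c$ is

$$p_c = \frac{\#\{\,s \in S_c : s \ge \alpha_c(x)\,\} + 1}{|S_c| + 1},$$

with ties counted in the numerator. Class $c$ enters the prediction set
iff $p_c > \varepsilon$ for the user-chosen significance level
$\varepsilon$. Four outcomes are possible: `single_active`,
`single_inactive`, `both`, `empty`. Under exchangeability, the Mondrian
construction guarantees per class: the probability that the true class
is excluded is at most (approximately) $\varepsilon$. `both` is always a
correct prediction, `empty` always an error.

Two evaluation notions follow. **Validity** (per class): the fraction of
compounds of that class whose prediction set contains it. **Efficiency**
(per class): the fraction of compounds of that class receiving a
single-label (informative) prediction, correct or not.

Numerical choices worth knowing:

* p-values are deterministic (non-smoothed) by default; a smoothed
  variant with seeded random tie-splitting is available
  (`p_value(..., smooth = TRUE)`). Determinism makes runs bit-for-bit
  reproducible; smoothing makes the validity guarantee exact rather than
  conservative.
* Set inclusion uses the strict comparison $p_c > \varepsilon$, the form
  under which the validity proofs are stated. At $p_c = \varepsilon$ the
  class is excluded.
* The base forest uses 100 trees (a standard default for this kind of
  tabular count data), single-threaded, with an explicit seed, so fits
  are deterministic.
* `fit_icp()` refuses single-class calibration sets rather than
  producing degenerate (empty) calibration lists.

### Consensus models

Per-descriptor conformal models are combined two ways:

* `consensus_pvals`: per compound and class, the median p-value across
  models (even counts: mean of the central pair). The median pair is
  then thresholded like any p-value pair. Medians of monotone families
  are monotone, so nesting of prediction sets across $\varepsilon$ is
  preserved; the formal class-wise guarantee, however, is *not* carried
  through the median, so consensus validity is an empirical property,
  checked rather than assumed.
* `consensus_cls`: per compound, majority vote over the models' outcomes
  at one significance level, with ties broken by the fixed priority
  active > inactive > both > empty — deliberately biased toward flagging
  hazard in doubt.

A model that fails on a particular compound (for instance a fingerprint
that cannot process an organometallic fragment) loses its vote for that
compound only; this keeps consensus defined on salt- and
metal-containing structures, which the N-gram families always handle.

## Featurization

### Dictionary N-gram hashing

Every character a canonical SMILES writer can emit is mapped to a fixed
3-digit code (`'a'`→101 … `'|'`→177; see `smiles_dictionary()`). A
window of $n$ characters (n = 4 or 6) slides one position at a time;
the window's codes are concatenated into one decimal integer and reduced
modulo the hash length (64, 256 or 1024); the resulting position's count
is incremented. For `"abcdag"` the windows `abcd`, `bcda`, `cdag` give
101102103104, 102103104101, 103104101107 and (mod 1024) positions 576,
613, 755.

Because a 6-gram concatenation has 18 digits, the modulo is evaluated by
Horner's rule in base $10^3$ — exact in double precision since
intermediates never exceed `hash_len * 1000`. `encode_window()` returns
the full code as a digit string, which is exact at any window length.
Strings shorter than $n$ yield the zero vector: no complete window
exists, and dropping such records would silently change dataset sizes.

### Transforms and token N-grams

Three variants re-encode the SMILES string before K-merization:

* **DeepSMILES** (`transform_deepsmiles()`): ring-closure digit pairs
  become a single ring-size symbol at the closing atom and branches lose
  their opening parentheses (each `)` pops one atom). Implemented
  in-package with an exact decoder used for round-trip verification
  against the Open Babel canonicalizer.
* **SELFIES-style** (`transform_selfies()`): bracketed per-atom tokens
  with `Branch`/`Ring` length-prefix symbols spelled in the standard
  16-symbol index alphabet. Two pragmatic choices keep the encoding
  total and exactly invertible on standardized SMILES: aromatic atoms
  stay lowercase (no kekulization), and bracket-atom bodies (charge,
  explicit H, stereo tags) are carried verbatim. Downstream the string
  is only a character sequence for K-merization, so these choices affect
  no guarantee; `selfies_decode()` plus encoding is a fixed point, which
  the tests verify.
* **Pair-encoded tokens** (`tokenize_pe()`): a deterministic, built-in
  ordered pair-merge vocabulary (BPE-style) fuses frequent adjacent
  SMILES tokens; bracket atoms, `Cl`/`Br` and `%nn` closures are atomic.
  Token N-grams then mirror the character scheme with one change: each
  unique token receives a fixed-width (4-digit, zero-padded) code
  assigned in first-seen order over the dataset and persisted with the
  model — fixed width is what keeps decimal concatenation injective.
  With single-character tokens and the character dictionary, the token
  encoder reproduces the character encoder exactly (a test asserts
  this equivalence).

### Circular fingerprints

`morgan_counts()` is an ECFP-style iterative neighbourhood-hashing count
fingerprint over the package's own SMILES graph parser: radius-0 atom
invariants hash element, charge, degree, implicit-H count, aromaticity
and (optionally) the chiral tag; each iteration rehashes an atom's
invariant with its sorted (bond order, neighbour invariant) pairs. An
environment that has stopped growing (already covers its connected
component) contributes nothing further, so small molecules saturate:
the radius-4 vector of ethane equals its radius-2 vector.
`secfp_binary()` folds the same environment identifiers (without
chirality) into a 0/1 vector. These are determinism-contracted
descriptors, not bit-compatible with any other toolkit's fingerprints.
The core-substituent family is an adapter contract only: supply a
provider function, or use the pure N-gram consensus set (`set2`, the
recommended default) which has no such dependency.

## Standardization and splitting

SMILES are canonicalized with the Open Babel canonical writer
(ChemmineOB). Unparseable structures map to `NA` — an invalid marker,
not an exception — and are flagged, counted and excluded downstream.
Salts and multi-fragment SMILES are kept intact; handling *all* SMILES
symbols, metals and counter-ions included, is precisely the N-gram
families' advantage. Standardization is idempotent, and no deduplication
is performed by default (`standardize_dataset(dedup = TRUE)` merges
canonical duplicates).

Cross-validation uses `k = 10` folds over a seeded shuffle
(`shuffle = FALSE` restores plain contiguous folds); within each fold's
training pool a random 20% becomes the calibration set (unstratified by
default, a stratified option exists for severely imbalanced data). Test
sets partition the data, so pooling test predictions over folds predicts
every compound exactly once.

## The synthetic data generator

Real regulatory datasets of this kind cannot be redistributed, so the
package ships a generator whose output has the statistical features the
pipeline must survive, without pretending to be real chemistry:

* **Motif-driven labels.** Molecules are assembled from six scaffold
  templates and substituent pools; actives receive one of four planted
  toxicophore motifs (nitro, trichloromethyl, nitroso, thiocyanate).
  The label is motif presence XOR a noise flip. Labels being a function
  of structure is what makes featurizer signal, base-model accuracy and
  CP efficiency meaningful; purely random labels would only exercise
  validity.
* **Defaults** (the generator's standard conditions): 2000 compounds,
  30% actives, 5% label noise (emulating conflicting-annotation
  removal in real dossiers), 10% salt/solvate fragments. Profiles
  mirroring realistic class-imbalance ratios — from ~3% actives (acute
  oral toxicity-like) to ~49% (chronic aquatic toxicity-like) — are
  available via `imbalance_profiles()`.
* **What it does not emulate:** realistic medicinal chemistry, the
  chemical-space diversity of registry data, activity cliffs, or
  inter-endpoint label correlation. Passing tests on this generator
  shows the machinery is correct and calibrated under exchangeability;
  it does not certify performance on real regulatory data.

## Evaluation harness

`run_cv_experiment()` runs the folds-by-featurizers grid, pools test
p-values, and reports per significance level: class-wise validity and
efficiency, outcome counts, and — on the single-label subset — accuracy,
sensitivity, specificity, balanced accuracy and MCC, plus a ROC-AUC that
ranks compounds by $p_{active} - p_{inactive}$ (Mann–Whitney form, ties
credited 0.5). Undefined metrics (empty denominators) are `NA`, never 0,
so nothing silently averages over them. Efficiency and validity
denominators are the compounds whose *true* label is the class — the
class-conditional reading consistent with the Mondrian guarantee; the
per-predicted-class variant is available via
`cp_efficiency(denominator = "predicted")`.

The test suite exercises the full pipeline at n = 2000 compounds,
10 folds and seven N-gram featurizers (the `set2` consensus set) — sizes
chosen so the class-wise binomial error bars at $\varepsilon = 0.2$ are
a few percent, tight enough to detect calibration failures.

## Known limitations

* **Efficiency need not increase with the significance level.**
  Efficiency is $1 - \Pr(\text{both}) - \Pr(\text{empty})$. Raising
  $\varepsilon$ shrinks the `both` region but grows the `empty` region
  (the guarantee itself makes $\Pr(p_{true} \le \varepsilon) \approx
  \varepsilon$). On hard tasks, where `both` dominates at small
  $\varepsilon$, efficiency rises with $\varepsilon$; on well-separated
  data — including this package's default synthetic benchmark, where
  `both` is nearly exhausted already at $\varepsilon = 0.1$ — efficiency
  *decreases* roughly linearly in $\varepsilon$. The harness reports the
  full profile rather than assuming either regime.
* The class-wise error guarantee assumes exchangeability; covariate
  shift between training and deployment chemical space voids it.
* Median-p-value consensus loses the formal guarantee (checked
  empirically, above).
* The circular fingerprints are self-consistent descriptors; do not mix
  them with vectors produced by other software.
* Binary classification only; one model per hazard-statement group.

## A minimal session

```{r, eval = FALSE}
library(hazcp)

dat <- generate_dataset(synthetic_config(n_compounds = 500, seed = 7))
ex <- run_cv_experiment(dat, consensus_set("set2"),
                        significance = c(0.1, 0.15, 0.2, 0.25, 0.3),
                        k = 10, seed = 7)
summary(ex, significance = 0.2)
plot(ex, model = "ngram_4_hashed_1024")
```
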