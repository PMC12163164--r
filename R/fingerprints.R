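# ECFP-style circular fingerprints over the package's SMILES graph parser.

# Deterministic 31-bit polynomial string hash (base 31 over raw bytes).
.str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

# Per-atom environment invariants for radii 0..radius. The radius-0
# invariant hashes element, charge, heavy degree, hydrogen count, aromatic
# flag and (if `chirality`) the chiral tag; each iteration rehashes the
# atom's previous invariant together with the sorted (bond order, neighbour
# invariant) pairs. An environment that stopped growing (it already covers
# its whole connected component) is frozen and marked not-new, so it adds
# no further counts. Returns list(inv = n_atoms x (radius+1) matrix,
# new = logical matrix flagging still-growing environments).
.circular_invariants <- function(mol, radius, chirality = TRUE) {
  n <- nrow(mol$atoms)
  hyd <- .hydrogen_counts(mol)
  nbrs <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[r, ]
      nbrs[[b$a1]] <- rbind(nbrs[[b$a1]], c(b$a2, b$order))
      nbrs[[b$a2]] <- rbind(nbrs[[b$a2]], c(b$a1, b$order))
    }
  }
  inv <- matrix(0, n, radius + 1L)
  grew <- matrix(FALSE, n, radius + 1L)  # environment still expanding?
  grew[, 1L] <- TRUE
  reach <- lapply(seq_len(n), function(i) i)  # atoms within current radius
  for (i in seq_len(n)) {
    a <- mol$atoms[i, ]
    deg <- if (is.null(nbrs[[i]])) 0L else nrow(nbrs[[i]])
    key <- paste(a$element, a$charge, deg, hyd[i], as.integer(a$aromatic),
                 if (chirality) a$chiral else "", sep = "|")
    inv[i, 1L] <- .str_hash(key)
  }
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      new_reach <- reach
      for (i in seq_len(n)) {
        if (is.null(nbrs[[i]])) { inv[i, r + 1L] <- inv[i, r]; next }
        new_reach[[i]] <- sort(unique(c(reach[[i]],
                                        unlist(reach[nbrs[[i]][, 1L]]))))
        if (length(new_reach[[i]]) == length(reach[[i]])) {
          # environment saturated: freeze invariant, contribute nothing new
          inv[i, r + 1L] <- inv[i, r]
          next
        }
        parts <- apply(nbrs[[i]], 1L, function(x)
          sprintf("%.0f:%.0f", x[2L] * 10, inv[x[1L], r]))
        key <- paste(inv[i, r], paste(sort(parts), collapse = ","), sep = ";")
        inv[i, r + 1L] <- .str_hash(key)
        grew[i, r + 1L] <- TRUE
      }
      reach <- new_reach
    }
  }
  list(inv = inv, new = grew)
}

#' Morgan-style circular fingerprint with counts
#'
#' Hashed count vector of circular atom environments, in the ECFP family:
#' every atom contributes one environment identifier per radius 0..`radius`
#' (iterative neighbourhood hashing with chirality included in the atom
#' invariant), and each identifier increments its position modulo
#' `hash_len`. Deterministic for a given input; enantiomers written with
#' `@`/`@@` tags yield different vectors.
#'
#' @param smiles A valid SMILES string.
#' @param radius Environment radius, 2 or 4.
#' @param hash_len Folded vector length (default 1024).
#' @param chirality Include chiral tags in atom invariants (default TRUE).
#' @return Integer count vector of length `hash_len`.
#' @export
morgan_counts <- function(smiles, radius = 2L, hash_len = 1024L,
                          chirality = TRUE) {
  mol <- tryCatch(parse_smiles(smiles),
                  error = function(e) stop(sprintf(
                    "cannot featurize '%s': %s", smiles, conditionMessage(e)),
                    call. = FALSE))
  if (nrow(mol$atoms) == 0L) return(integer(hash_len))
  ci <- .circular_invariants(mol, radius, chirality)
  ids <- ci$inv[ci$new]   # one identifier per still-growing environment
  pos <- as.integer(ids %% hash_len)
  tabulate(pos + 1L, nbins = hash_len)
}

#' Binary circular-substructure fingerprint
#'
#' SECFP-style binary fingerprint: circular atom environments (radii
#' 0..`radius`, identified by the same neighbourhood signatures as
#' [morgan_counts()] but without chirality, mirroring substructure-string
#' hashing) are folded onto `hash_len` positions; a position is 1 if any
#' environment maps to it. Deterministic per input; values are always
#' 0 or 1.
#'
#' @inheritParams morgan_counts
#' @return Integer 0/1 vector of length `hash_len`.
#' @export
secfp_binary <- function(smiles, radius = 2L, hash_len = 1024L) {
  v <- morgan_counts(smiles, radius = radius, hash_len = hash_len,
                     chirality = FALSE)
  as.integer(v > 0L)
}
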