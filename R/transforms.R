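# String transforms of SMILES used as alternative N-gram substrates.

#' Rewrite a SMILES string in DeepSMILES form
#'
#' Applies both DeepSMILES rewritings: ring-closure digit pairs are replaced
#' by a single ring-size symbol at the closing atom (sizes above 9 use
#' `%nn`), and branches lose their opening parentheses — each closing `)`
#' pops one atom off the current path, so a branch of k atoms ends in k
#' `)` characters. The output alphabet is a subset of the SMILES N-gram
#' dictionary, so DeepSMILES strings feed the same K-merization.
#'
#' @param smiles A valid SMILES string.
#' @return The DeepSMILES string.
#' @seealso [deepsmiles_decode()] for the inverse.
#' @export
#' @examples
#' transform_deepsmiles("CCO")     # unchanged: no rings or branches
#' transform_deepsmiles("C1CC1")   # "CCC3"
#' transform_deepsmiles("CC(C)O")  # "CCC)O"
transform_deepsmiles <- function(smiles) {
  toks <- smiles_tokens(smiles)
  types <- attr(toks, "type")
  out <- character(0)
  path <- integer(0)          # atom ids on the current DFS path
  marks <- integer(0)         # path depth at each open '('
  pend <- ""                  # bond symbol awaiting its atom / ring closure
  atom_id <- 0L
  ring_open <- list()
  for (k in seq_along(toks)) {
    tok <- toks[k]; ty <- types[k]
    if (ty == "atom") {
      out <- c(out, pend, tok); pend <- ""
      atom_id <- atom_id + 1L
      path <- c(path, atom_id)
    } else if (ty == "bond") {
      pend <- tok
    } else if (ty == "open") {
      marks <- c(marks, length(path))
    } else if (ty == "close") {
      m <- marks[length(marks)]; marks <- marks[-length(marks)]
      out <- c(out, strrep(")", length(path) - m))
      path <- path[seq_len(m)]
    } else if (ty == "ring") {
      lab <- if (startsWith(tok, "%")) substring(tok, 2L) else tok
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- list(atom = path[length(path)], bond = pend)
      } else {
        op <- ring_open[[lab]]; ring_open[[lab]] <- NULL
        pos <- match(op$atom, path)
        if (is.na(pos))
          stop("ring closure partner left the DFS path; SMILES form not supported",
               call. = FALSE)
        size <- length(path) - pos + 1L
        sym <- if (pend != "") pend else op$bond
        out <- c(out, sym,
                 if (size > 9L) sprintf("%%%02d", size) else as.character(size))
      }
      pend <- ""
    } else if (ty == "dot") {
      out <- c(out, ".")
      path <- integer(0); marks <- integer(0); atom_id <- 0L
    }
  }
  paste0(out, collapse = "")
}

#' Decode a DeepSMILES string back to SMILES
#'
#' Inverse of [transform_deepsmiles()]: each `)` pops one atom off the
#' path, a ring-size symbol bonds the current atom to the atom size-1
#' steps up the path. Returns a valid (not necessarily canonical) SMILES.
#'
#' @param ds A DeepSMILES string.
#' @return A SMILES string for the same molecule.
#' @export
deepsmiles_decode <- function(ds) {
  toks <- smiles_tokens(ds)
  types <- attr(toks, "type")
  atoms <- list(); bonds <- list()
  path <- integer(0); pend <- ""; frag <- 1L
  for (k in seq_along(toks)) {
    tok <- toks[k]; ty <- types[k]
    if (ty == "atom") {
      a <- .parse_atom_token(tok); a$fragment <- frag
      atoms[[length(atoms) + 1L]] <- a
      idx <- length(atoms)
      if (length(path) > 0L)
        bonds[[length(bonds) + 1L]] <- .mk_bond(path[length(path)], idx, pend, atoms)
      pend <- ""
      path <- c(path, idx)
    } else if (ty == "bond") {
      pend <- tok
    } else if (ty == "close") {
      if (length(path) == 0L) stop("unbalanced ')' in DeepSMILES", call. = FALSE)
      path <- path[-length(path)]
    } else if (ty == "ring") {
      size <- as.integer(if (startsWith(tok, "%")) substring(tok, 2L) else tok)
      cur <- path[length(path)]
      tgt_pos <- length(path) - size + 1L
      if (tgt_pos < 1L) stop("ring size exceeds path depth", call. = FALSE)
      b <- .mk_bond(path[tgt_pos], cur, pend, atoms)
      b$ring <- TRUE
      bonds[[length(bonds) + 1L]] <- b
      pend <- ""
    } else if (ty == "open") {
      stop("'(' cannot occur in DeepSMILES", call. = FALSE)
    } else if (ty == "dot") {
      path <- integer(0); frag <- frag + 1L
    }
  }
  write_smiles(.as_mol(atoms, bonds))
}

.as_mol <- function(atoms, bonds) {
  atoms_df <- do.call(rbind, lapply(atoms, function(a)
    data.frame(text = a$text, element = a$element, aromatic = a$aromatic,
               charge = a$charge, hcount = a$hcount, chiral = a$chiral,
               fragment = a$fragment, stringsAsFactors = FALSE)))
  bonds_df <- if (length(bonds) > 0L) {
    do.call(rbind, lapply(bonds, function(b)
      data.frame(a1 = b$a1, a2 = b$a2, order = b$order,
                 aromatic = b$aromatic, ring = isTRUE(b$ring))))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0),
               aromatic = logical(0), ring = logical(0))
  }
  list(atoms = atoms_df, bonds = bonds_df)
}

# ---- SELFIES-style encoding -------------------------------------------------

# 16-symbol index alphabet (values 0..15) used to spell Branch lengths and
# Ring distances, big-endian base 16.
.selfies_idx <- c("[C]", "[Ring1]", "[Ring2]",
                  "[Branch1]", "[=Branch1]", "[#Branch1]",
                  "[Branch2]", "[=Branch2]", "[#Branch2]",
                  "[Branch3]", "[=Branch3]", "[#Branch3]",
                  "[O]", "[N]", "[=N]", "[=C]")

.selfies_index_symbols <- function(v, L) {
  digs <- integer(L)
  for (k in L:1) { digs[k] <- v %% 16L; v <- v %/% 16L }
  .selfies_idx[digs + 1L]
}

.selfies_index_value <- function(syms) {
  v <- 0L
  for (s in syms) {
    d <- match(s, .selfies_idx)
    if (is.na(d)) stop(sprintf("'%s' is not an index symbol", s), call. = FALSE)
    v <- v * 16L + (d - 1L)
  }
  v
}

.bond_prefix <- function(order, arom_pair) {
  if (order == 2) "=" else if (order == 3) "#"
  else if (order == 1 && arom_pair) "-" else ""
}

#' Encode a SMILES string as a SELFIES-style token string
#'
#' Produces a bracketed token string in the SELFIES grammar: one token per
#' atom (bond order prefixed inside the token, e.g. `[=O]`), branches as
#' `[BranchL]` plus length index symbols followed by the branch tokens, and
#' rings as `[RingL]` plus distance index symbols at the closing atom.
#' Aromatic atoms are kept as lowercase tokens rather than kekulized, and
#' bracket-atom bodies (charges, explicit H, stereo) are carried verbatim;
#' both choices make the encoding total on standardized SMILES and exactly
#' invertible by [selfies_decode()]. Fragments are joined with `.`.
#'
#' Every output character belongs to the N-gram dictionary, so the string
#' feeds the same K-merization as raw SMILES.
#'
#' @param smiles A valid SMILES string.
#' @return A SELFIES-style token string.
#' @export
#' @examples
#' transform_selfies("CCO")  # "[C][C][O]"
transform_selfies <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  if (length(frags) == 0L) return("")
  paste0(vapply(frags, .selfies_encode_fragment, character(1)),
         collapse = ".")
}

.selfies_encode_fragment <- function(smiles) {
  mol <- parse_smiles(smiles)
  n <- nrow(mol$atoms)
  if (n == 0L) return("")
  tree_kids <- vector("list", n)   # child atoms in emission order
  kid_bond <- vector("list", n)
  rings_at <- vector("list", n)    # ring bonds closing at this atom
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[r, ]
      if (b$ring) {
        rings_at[[b$a2]] <- c(rings_at[[b$a2]], list(b))
      } else {
        tree_kids[[b$a1]] <- c(tree_kids[[b$a1]], b$a2)
        kid_bond[[b$a1]] <- c(kid_bond[[b$a1]], list(b))
      }
    }
  }
  atom_token <- function(i, prefix) {
    txt <- mol$atoms$text[i]
    body <- if (startsWith(txt, "[")) substr(txt, 2L, nchar(txt) - 1L) else txt
    paste0("[", prefix, body, "]")
  }
  arom <- mol$atoms$aromatic
  encode_atom <- function(i, prefix) {
    syms <- atom_token(i, prefix)
    for (b in rings_at[[i]]) {
      q <- i - b$a1                 # atoms back in emission order
      v <- q - 1L
      L <- if (v < 16L) 1L else if (v < 256L) 2L else 3L
      pre <- .bond_prefix(b$order, arom[b$a1] && arom[b$a2])
      syms <- c(syms, paste0("[", pre, "Ring", L, "]"),
                .selfies_index_symbols(v, L))
    }
    kids <- tree_kids[[i]]
    if (length(kids) > 0L) {
      for (kk in seq_along(kids)) {
        b <- kid_bond[[i]][[kk]]
        j <- kids[kk]
        pre <- .bond_prefix(b$order, arom[i] && arom[j])
        sub <- encode_atom(j, pre)
        if (kk < length(kids)) {
          v <- length(sub) - 1L
          L <- if (v < 16L) 1L else if (v < 256L) 2L else 3L
          syms <- c(syms, paste0("[Branch", L, "]"),
                    .selfies_index_symbols(v, L), sub)
        } else {
          syms <- c(syms, sub)
        }
      }
    }
    syms
  }
  paste0(encode_atom(1L, ""), collapse = "")
}

#' Decode a SELFIES-style token string back to SMILES
#'
#' Inverse of [transform_selfies()]. Returns a valid (not necessarily
#' canonical) SMILES string.
#'
#' @param sf A SELFIES-style token string.
#' @return A SMILES string.
#' @export
selfies_decode <- function(sf) {
  frags <- strsplit(sf, ".", fixed = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) return("")
  paste0(vapply(frags, .selfies_decode_fragment, character(1)),
         collapse = ".")
}

.selfies_tokens <- function(sf) {
  m <- gregexpr("\\[[^][]*\\]", sf)[[1L]]
  if (m[1L] == -1L) {
    if (nzchar(sf)) stop("malformed SELFIES-style string", call. = FALSE)
    return(character(0))
  }
  regmatches(sf, gregexpr("\\[[^][]*\\]", sf))[[1L]]
}

.selfies_decode_fragment <- function(sf) {
  toks <- .selfies_tokens(sf)
  atoms <- list(); bonds <- list()
  mk_atom <- function(body) {
    plain <- body %in% .organic
    txt <- if (plain) body else paste0("[", body, "]")
    a <- .parse_atom_token(txt); a$fragment <- 1L
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  add_bond <- function(i, j, prefix) {
    sym <- if (prefix == "-") {
      "-"
    } else prefix
    b <- if (prefix == "-") {
      list(a1 = min(i, j), a2 = max(i, j), order = 1, aromatic = FALSE,
           ring = FALSE)
    } else .mk_bond(i, j, prefix, atoms)
    bonds[[length(bonds) + 1L]] <<- b
    length(bonds)
  }
  # consume `count` symbols starting at p, attached to atom `prev`;
  # returns position after the consumed region
  walk <- function(p, stop_after, prev) {
    consumed <- 0L
    while (p <= length(toks) && (is.na(stop_after) || consumed < stop_after)) {
      tok <- toks[p]
      body <- substr(tok, 2L, nchar(tok) - 1L)
      m <- regexec("^([=#-]?)(Branch|Ring)([1-3])$", body)
      g <- regmatches(body, m)[[1L]]
      if (length(g) > 0L) {
        pre <- g[2L]; kind <- g[3L]; L <- as.integer(g[4L])
        idx <- toks[(p + 1L):(p + L)]
        v <- .selfies_index_value(idx)
        p <- p + 1L + L; consumed <- consumed + 1L + L
        if (kind == "Ring") {
          q <- v + 1L
          tgt <- prev - q
          if (is.na(prev) || tgt < 1L)
            stop("ring distance exceeds decoded atoms", call. = FALSE)
          b <- add_bond(tgt, prev, pre)
          bonds[[b]]$ring <<- TRUE
        } else {
          blen <- v + 1L
          p <- walk(p, blen, prev)
          consumed <- consumed + blen
        }
      } else {
        pre <- ""
        if (substr(body, 1L, 1L) %in% c("=", "#", "-")) {
          pre <- substr(body, 1L, 1L); body <- substring(body, 2L)
        }
        idx <- mk_atom(body)
        if (!is.na(prev)) add_bond(prev, idx, pre)
        prev <- idx
        p <- p + 1L; consumed <- consumed + 1L
      }
    }
    p
  }
  walk(1L, NA_integer_, NA_integer_)
  write_smiles(.as_mol(atoms, bonds))
}

# ---- Pair-encoding tokenizer ------------------------------------------------

# Built-in merge vocabulary for the pair-encoding tokenizer: frequent
# adjacent token pairs in canonical SMILES, applied greedily in this order.
.pe_merges <- list(
  c("c", "c"), c("cc", "cc"), c("C", "C"), c("c", "1"), c("c", "2"),
  c("C", "("), c("(", "C"), c("=", "O"), c("(", "=O"), c("C", "1"),
  c("O", "C"), c("N", "C"), c("C", "O"), c("C", "N"), c("(", "Cl"),
  c("(", "F"), c("C(", "=O)"), c("=O", ")"), c("cc", "1"), c("cc", "2"),
  c("C", ")"), c("O", ")"), c("N", ")"), c("C1", "CC"), c("CC", "CC")
)

#' Tokenize a SMILES string with built-in pair-encoding merges
#'
#' Splits a SMILES string into multi-character tokens: bracket atoms,
#' two-letter elements and `%nn` ring closures are atomic, and a fixed,
#' ordered pair-merge vocabulary then greedily fuses frequent adjacent
#' token pairs (byte-pair-encoding style). The tokenization is
#' deterministic and lossless: concatenating the tokens reproduces the
#' input exactly. Characters outside the merge vocabulary fall back to
#' single-character tokens.
#'
#' @param smiles A SMILES string (empty string gives an empty token list).
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize_pe("[Na+]")        # one token
#' tokenize_pe("CC(=O)Oc1ccccc1")
tokenize_pe <- function(smiles) {
  if (nchar(smiles) == 0L) return(character(0))
  toks <- as.character(smiles_tokens(smiles))
  for (mg in .pe_merges) {
    if (length(toks) < 2L) break
    repeat {
      hit <- which(toks[-length(toks)] == mg[1L] & toks[-1L] == mg[2L])
      if (length(hit) == 0L) break
      i <- hit[1L]
      toks <- c(toks[seq_len(i - 1L)], paste0(mg[1L], mg[2L]),
                if (i + 2L <= length(toks)) toks[(i + 2L):length(toks)])
    }
  }
  toks
}
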