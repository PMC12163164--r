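# Lightweight SMILES lexer / graph parser / writer.
#
# Supports the subset emitted by the Open Babel canonical writer: organic
# subset atoms (B C N O P S F Cl Br I and aromatic b c n o p s), bracket
# atoms with isotope/chirality/H-count/charge, bonds - = # : / \, branches,
# ring closures (digits and %nn), and '.'-separated fragments. Used by the
# string transforms and the circular fingerprints; not a full OpenSMILES
# implementation (no reaction, wildcard or quadruple-bond syntax).

.two_letter <- c("Cl", "Br")
.organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
              "b", "c", "n", "o", "p", "s")
.bond_chars <- c("-", "=", "#", ":", "/", "\\")

#' Split a SMILES string into lexical tokens
#'
#' Tokens are bracket atoms (`[...]` kept whole), two-letter organic atoms
#' (`Cl`, `Br`), single-letter atoms, bond symbols, branch parentheses,
#' ring-closure labels (single digits or `%nn`), and `.` separators.
#' Concatenating the tokens reproduces the input exactly.
#'
#' @param s A SMILES string.
#' @return Character vector of tokens with a `"type"` attribute: one of
#'   `atom`, `bond`, `open`, `close`, `ring`, `dot`.
#' @export
smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  toks <- character(0); types <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES", call. = FALSE)
      toks <- c(toks, paste0(chars[i:j], collapse = "")); types <- c(types, "atom")
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure", call. = FALSE)
      toks <- c(toks, paste0(chars[i:(i + 2L)], collapse = "")); types <- c(types, "ring")
      i <- i + 3L
    } else if (ch %in% c("0","1","2","3","4","5","6","7","8","9")) {
      toks <- c(toks, ch); types <- c(types, "ring")
      i <- i + 1L
    } else if (ch == "(") {
      toks <- c(toks, ch); types <- c(types, "open"); i <- i + 1L
    } else if (ch == ")") {
      toks <- c(toks, ch); types <- c(types, "close"); i <- i + 1L
    } else if (ch == ".") {
      toks <- c(toks, ch); types <- c(types, "dot"); i <- i + 1L
    } else if (ch %in% .bond_chars) {
      toks <- c(toks, ch); types <- c(types, "bond"); i <- i + 1L
    } else {
      pair <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (pair %in% .two_letter) {
        toks <- c(toks, pair); types <- c(types, "atom"); i <- i + 2L
      } else if (ch %in% .organic) {
        toks <- c(toks, ch); types <- c(types, "atom"); i <- i + 1L
      } else {
        stop(sprintf("unexpected character '%s' at position %d in SMILES", ch, i),
             call. = FALSE)
      }
    }
  }
  attr(toks, "type") <- types
  toks
}

# Decompose one atom token into fields. Bracket atoms are parsed for
# element, aromaticity, chirality, explicit H count and charge.
.parse_atom_token <- function(tok) {
  if (!startsWith(tok, "[")) {
    el <- tok
    aromatic <- el %in% c("b", "c", "n", "o", "p", "s")
    return(list(text = tok, element = if (aromatic) toupper(el) else el,
                aromatic = aromatic, charge = 0L, hcount = NA_integer_,
                chiral = ""))
  }
  body <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regexec("^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
               body)
  g <- regmatches(body, m)[[1L]]
  if (length(g) == 0L)
    stop(sprintf("cannot parse bracket atom '%s'", tok), call. = FALSE)
  el <- g[3L]
  aromatic <- el == tolower(el) && nchar(el) >= 1L &&
    substr(el, 1L, 1L) %in% letters
  hfield <- g[5L]
  hcount <- if (hfield == "") 0L
            else if (hfield == "H") 1L
            else as.integer(substring(hfield, 2L))
  cfield <- g[6L]
  charge <- if (cfield == "") 0L
            else if (cfield %in% c("+", "-")) ifelse(cfield == "+", 1L, -1L)
            else if (grepl("^[+]+$", cfield)) nchar(cfield)
            else if (grepl("^[-]+$", cfield)) -nchar(cfield)
            else as.integer(paste0(substr(cfield, 1L, 1L),
                                   substring(cfield, 2L))) *
                 (if (substr(cfield, 1L, 1L) == "-") 1L else 1L)
  if (grepl("^[+-][0-9]+$", cfield)) {
    mag <- as.integer(substring(cfield, 2L))
    charge <- if (substr(cfield, 1L, 1L) == "-") -mag else mag
  }
  list(text = tok, element = if (aromatic) toupper(el) else el,
       aromatic = aromatic, charge = charge, hcount = hcount,
       chiral = if (is.na(g[4L]) || g[4L] == "") "" else g[4L])
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds atom and bond tables by a stack-based walk of the SMILES syntax.
#' Ring-closure bonds are recorded with `ring = TRUE` at the closing atom.
#' Bond order is 1, 2 or 3; a bond between two aromatic atoms written
#' without a symbol (or with `:`) is flagged aromatic with order 1.5.
#'
#' @param s A valid SMILES string.
#' @return A list with `atoms` (data.frame: text, element, aromatic, charge,
#'   hcount, chiral, fragment) and `bonds` (data.frame: a1, a2, order,
#'   aromatic, ring; `a1` precedes `a2` in atom order).
#' @export
parse_smiles <- function(s) {
  toks <- smiles_tokens(s)
  types <- attr(toks, "type")
  atoms <- list(); bonds <- list()
  prev <- NA_integer_            # current attachment atom
  stack <- integer(0)            # saved attachment atoms for '('
  pend_bond <- ""                # bond symbol awaiting next atom/ring
  ring_open <- list()            # label -> list(atom, bond)
  frag <- 1L
  for (k in seq_along(toks)) {
    tok <- toks[k]; ty <- types[k]
    if (ty == "atom") {
      a <- .parse_atom_token(tok)
      a$fragment <- frag
      atoms[[length(atoms) + 1L]] <- a
      idx <- length(atoms)
      if (!is.na(prev)) {
        bonds[[length(bonds) + 1L]] <-
          .mk_bond(prev, idx, pend_bond, atoms)
      }
      prev <- idx; pend_bond <- ""
    } else if (ty == "bond") {
      pend_bond <- tok
    } else if (ty == "open") {
      stack <- c(stack, prev)
    } else if (ty == "close") {
      if (length(stack) == 0L) stop("unmatched ')' in SMILES", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
    } else if (ty == "ring") {
      lab <- if (startsWith(tok, "%")) substring(tok, 2L) else tok
      if (!is.null(ring_open[[lab]])) {
        op <- ring_open[[lab]]
        sym <- if (pend_bond != "") pend_bond else op$bond
        b <- .mk_bond(op$atom, prev, sym, atoms)
        b$ring <- TRUE
        bonds[[length(bonds) + 1L]] <- b
        ring_open[[lab]] <- NULL
      } else {
        ring_open[[lab]] <- list(atom = prev, bond = pend_bond)
      }
      pend_bond <- ""
    } else if (ty == "dot") {
      prev <- NA_integer_; frag <- frag + 1L
    }
  }
  if (length(ring_open) > 0L)
    stop("unmatched ring closure in SMILES", call. = FALSE)
  if (length(stack) > 0L)
    stop("unmatched '(' in SMILES", call. = FALSE)
  atoms_df <- do.call(rbind, lapply(atoms, function(a)
    data.frame(text = a$text, element = a$element, aromatic = a$aromatic,
               charge = a$charge, hcount = a$hcount, chiral = a$chiral,
               fragment = a$fragment, stringsAsFactors = FALSE)))
  if (is.null(atoms_df))
    atoms_df <- data.frame(text = character(0), element = character(0),
                           aromatic = logical(0), charge = integer(0),
                           hcount = integer(0), chiral = character(0),
                           fragment = integer(0))
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

.mk_bond <- function(i, j, sym, atoms) {
  a1 <- min(i, j); a2 <- max(i, j)
  arom_pair <- atoms[[i]]$aromatic && atoms[[j]]$aromatic
  if (sym %in% c("", "-", "/", "\\")) {
    if (sym == "" && arom_pair)
      list(a1 = a1, a2 = a2, order = 1.5, aromatic = TRUE, ring = FALSE)
    else
      list(a1 = a1, a2 = a2, order = 1, aromatic = FALSE, ring = FALSE)
  } else if (sym == "=") {
    list(a1 = a1, a2 = a2, order = 2, aromatic = FALSE, ring = FALSE)
  } else if (sym == "#") {
    list(a1 = a1, a2 = a2, order = 3, aromatic = FALSE, ring = FALSE)
  } else if (sym == ":") {
    list(a1 = a1, a2 = a2, order = 1.5, aromatic = TRUE, ring = FALSE)
  } else {
    stop(sprintf("unsupported bond symbol '%s'", sym), call. = FALSE)
  }
}

# Standard valences for implicit hydrogen counting on organic-subset atoms.
.std_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                  F = 1, Cl = 1, Br = 1, I = 1)

# Implicit/explicit hydrogen count per atom. Bracket atoms carry their
# explicit count; organic-subset atoms get max(0, valence - ceil(bond sum)),
# with aromatic bonds contributing 1.5.
.hydrogen_counts <- function(mol) {
  n <- nrow(mol$atoms)
  h <- integer(n)
  bsum <- numeric(n)
  if (nrow(mol$bonds) > 0L) {
    for (r in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[r, ]
      bsum[b$a1] <- bsum[b$a1] + b$order
      bsum[b$a2] <- bsum[b$a2] + b$order
    }
  }
  for (i in seq_len(n)) {
    if (!is.na(mol$atoms$hcount[i])) {
      h[i] <- mol$atoms$hcount[i]
    } else {
      v <- .std_valence[mol$atoms$element[i]]
      h[i] <- if (is.na(v)) 0L else max(0L, as.integer(v - ceiling(bsum[i])))
    }
  }
  h
}

# Write a molecular graph back to SMILES. A first DFS classifies bonds into
# spanning-tree and ring bonds; ring bonds get closure labels attached to
# both end atoms, then a second DFS over the tree emits atoms, branches and
# the closure labels. Output is valid SMILES, not necessarily canonical.
write_smiles <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L) return("")
  nb <- nrow(mol$bonds)
  adj <- vector("list", n)
  if (nb > 0L) {
    for (r in seq_len(nb)) {
      adj[[mol$bonds$a1[r]]] <- c(adj[[mol$bonds$a1[r]]], r)
      adj[[mol$bonds$a2[r]]] <- c(adj[[mol$bonds$a2[r]]], r)
    }
  }
  bond_sym <- function(r) {
    o <- mol$bonds$order[r]
    if (o == 2) return("=")
    if (o == 3) return("#")
    i <- mol$bonds$a1[r]; j <- mol$bonds$a2[r]
    if (o == 1 && mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) return("-")
    ""   # plain single bond or aromatic bond
  }
  # pass 1: classify bonds via DFS from each fragment root
  is_tree <- rep(FALSE, max(1L, nb))
  seen <- rep(FALSE, n)
  order_children <- vector("list", n)  # tree bond rows, in DFS order
  roots <- integer(0)
  for (root in seq_len(n)) {
    if (seen[root]) next
    roots <- c(roots, root)
    stk <- list(list(atom = root, from = NA_integer_))
    seen[root] <- TRUE
    # recursive DFS to keep child order depth-first (matches emission)
    dfs <- function(i, from_bond) {
      for (r in adj[[i]]) {
        if (!is.na(from_bond) && r == from_bond) next
        j <- if (mol$bonds$a1[r] == i) mol$bonds$a2[r] else mol$bonds$a1[r]
        if (!seen[j]) {
          seen[j] <<- TRUE
          is_tree[r] <<- TRUE
          order_children[[i]] <<- c(order_children[[i]], r)
          dfs(j, r)
        }
      }
    }
    dfs(root, NA_integer_)
  }
  # ring bonds: every non-tree bond; assign labels and attach to both atoms
  ring_at <- vector("list", n)
  lab <- 0L
  if (nb > 0L) {
    for (r in which(!is_tree)) {
      lab <- lab + 1L
      sym <- bond_sym(r)
      tokl <- if (lab > 9L) sprintf("%%%02d", lab) else as.character(lab)
      tok <- paste0(sym, tokl)
      ring_at[[mol$bonds$a1[r]]] <- c(ring_at[[mol$bonds$a1[r]]], tok)
      ring_at[[mol$bonds$a2[r]]] <- c(ring_at[[mol$bonds$a2[r]]], tok)
    }
  }
  emit <- function(i) {
    out <- paste0(mol$atoms$text[i],
                  paste0(unlist(ring_at[[i]]), collapse = ""))
    kids <- character(0)
    for (r in order_children[[i]]) {
      j <- if (mol$bonds$a1[r] == i) mol$bonds$a2[r] else mol$bonds$a1[r]
      kids <- c(kids, paste0(bond_sym(r), emit(j)))
    }
    if (length(kids) > 1L)
      out <- paste0(out,
                    paste0("(", kids[-length(kids)], ")", collapse = ""),
                    kids[length(kids)])
    else if (length(kids) == 1L)
      out <- paste0(out, kids)
    out
  }
  paste0(vapply(roots, emit, character(1)), collapse = ".")
}
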