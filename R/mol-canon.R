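# Canonical atom ordering and SMILES output for fragment identity.
#
# Identity of a fragment is its canonical SMILES as produced here: iterative
# neighbourhood refinement (Morgan-style) followed by backtracking over
# residual symmetry classes, choosing the labelling with the lexicographically
# smallest adjacency code. Hydrogen counts are deliberately excluded from
# fragment identity: a fragment is an attachment-free substructure query, so
# two extractions differing only in how many hydrogens the parent supplied
# are the same pattern.

BOND_CHAR <- c("1" = "", "2" = "=", "3" = "#", "4" = ":", "9" = "~", "0" = "")

ELEMENT_CODE_TABLE <- c("*", "B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# flat integer encoding handed to the compiled kernels; unconstrained query
# properties become negative sentinels
encode_graph <- function(g, use_h) {
  elem <- match(g$elem, ELEMENT_CODE_TABLE) - 1L
  arom <- ifelse(is.na(g$arom), -1L, as.integer(g$arom))
  charge <- ifelse(is.na(g$charge), -999L, g$charge)
  h <- if (use_h) ifelse(is.na(g$hcount), -1L, g$hcount)
  else rep(-1L, n_atoms(g))
  list(elem = as.integer(elem), arom = as.integer(arom),
       charge = as.integer(charge), hcount = as.integer(h),
       bond = g$bond)
}

# an unwritten charge and a zero charge are the same thing for canonical
# identity (a fragment SMILES only decorates non-neutral atoms), even though
# they differ for matching (unwritten = unconstrained in a query)
encode_for_canon <- function(g, use_h) {
  e <- encode_graph(g, use_h)
  e$charge[e$charge == -999L] <- 0L
  e
}

# canonical ranks via compiled refinement + backtracking; hydrogen counts
# participate in identity only for full molecules (use_h = TRUE)
canon_ranks <- function(g, use_h = FALSE) {
  e <- encode_for_canon(g, use_h)
  .canon_ranks_cpp(e$elem, e$arom, e$charge, e$hcount, e$bond)
}

# cheap canonical identity key (no SMILES writing); equal keys identify
# identical fragments, so the string form is only materialized once per
# unique fragment
canon_key <- function(g, use_h = FALSE) {
  e <- encode_for_canon(g, use_h)
  .canon_key_cpp(e$elem, e$arom, e$charge, e$hcount, e$bond)
}

smiles_atom_text <- function(g, i, include_h) {
  el <- g$elem[i]
  if (el == "*") return("*")
  sym <- if (isTRUE(g$arom[i])) tolower(el) else el
  chg <- g$charge[i]
  h <- if (include_h) g$hcount[i] else NA_integer_
  needs_bracket <- (!is.na(chg) && chg != 0L) || !(el %in% ORGANIC_SUBSET) ||
    (include_h && !is.na(h) && h != default_implicit_h(g, i))
  if (!needs_bracket) return(sym)
  htxt <- if (!is.na(h) && h > 0L) {
    if (h == 1L) "H" else paste0("H", h)
  } else ""
  ctxt <- if (is.na(chg) || chg == 0L) ""
  else if (chg == 1L) "+"
  else if (chg == -1L) "-"
  else sprintf("%+d", chg)
  paste0("[", sym, htxt, ctxt, "]")
}

# H count a SMILES reader would infer for atom i written without brackets
default_implicit_h <- function(g, i) {
  orders <- g$bord[[i]]
  bsum <- sum(ifelse(orders == 4L, 1L, orders))
  if (isTRUE(g$arom[i]) && g$elem[i] %in% AROMATIC_VALENCE_BUMP)
    bsum <- bsum + 1L
  vals <- DEFAULT_VALENCE[[g$elem[i]]]
  if (is.null(vals)) return(0L)
  v <- vals[vals >= bsum]
  if (length(v) == 0L) 0L else min(v) - bsum
}

#' Write a molgraph as a SMILES string following canonical ranks
#'
#' @param g molgraph (connected)
#' @param include_h write explicit hydrogen counts where they deviate from
#'   the implicit default (needed for molecules destined for other toolkits);
#'   fragments are written without hydrogen specifications.
#' @return SMILES string
#' @keywords internal
write_smiles <- function(g, ranks = canon_ranks(g), include_h = FALSE) {
  n <- n_atoms(g)
  if (n == 1L) return(smiles_atom_text(g, 1L, include_h))
  root <- which.min(ranks)

  # assign ring-closure bonds: non-tree edges under a DFS in rank order
  visited <- logical(n)
  tree_child <- vector("list", n)    # ordered children
  closure_at <- vector("list", n)    # list of c(other, order, digit)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  digit_next <- 0L
  open_closures <- new.env(parent = emptyenv())

  build_tree <- function(i) {
    for (k in order(ranks[g$adj[[i]]])) {
      j <- g$adj[[i]][k]
      if (!visited[j]) {
        visited[j] <<- TRUE
        tree_child[[i]] <<- c(tree_child[[i]], j)
        assign(ekey(i, j), TRUE, envir = edge_used)
        build_tree(j)
      }
    }
  }
  visited[root] <- TRUE
  build_tree(root)

  # remaining edges are ring closures; assign digits deterministically by
  # walking atoms in output (tree) order
  out_order <- integer(0)
  walk <- function(i) {
    out_order <<- c(out_order, i)
    for (j in tree_child[[i]]) walk(j)
  }
  walk(root)
  pos_in_out <- integer(n); pos_in_out[out_order] <- seq_len(n)
  closures <- which(!vapply(seq_len(nrow(g$bond)), function(k) {
    exists(ekey(g$bond[k, 1L], g$bond[k, 2L]), envir = edge_used)
  }, logical(1)))
  if (length(closures) > 0L) {
    first_pos <- pmin(pos_in_out[g$bond[closures, 1L]],
                      pos_in_out[g$bond[closures, 2L]])
    second_pos <- pmax(pos_in_out[g$bond[closures, 1L]],
                       pos_in_out[g$bond[closures, 2L]])
    ord <- order(first_pos, second_pos)
    for (d in seq_along(ord)) {
      k <- closures[ord[d]]
      a <- g$bond[k, 1L]; b <- g$bond[k, 2L]; o <- g$bond[k, 3L]
      digit <- if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
      first <- if (pos_in_out[a] < pos_in_out[b]) a else b
      second <- if (first == a) b else a
      closure_at[[first]] <- c(closure_at[[first]], list(c(second, o, digit, "open")))
      closure_at[[second]] <- c(closure_at[[second]], list(c(first, o, digit, "close")))
    }
  }

  bond_text <- function(a, b, o) {
    if (o == 4L && isTRUE(g$arom[a]) && isTRUE(g$arom[b])) return("")
    if (o == 1L && isTRUE(g$arom[a]) && isTRUE(g$arom[b])) return("-")
    BOND_CHAR[[as.character(o)]]
  }

  emit <- function(i) {
    txt <- smiles_atom_text(g, i, include_h)
    for (cl in closure_at[[i]]) {
      o <- as.integer(cl[2L])
      other <- as.integer(cl[1L])
      btxt <- if (cl[4L] == "open") bond_text(i, other, o) else ""
      txt <- paste0(txt, btxt, cl[3L])
    }
    ch <- tree_child[[i]]
    if (length(ch) > 0L) {
      parts <- vapply(ch, function(j) paste0(bond_text(i, j, g$bond_order_between(i, j)), emit(j)), character(1))
      if (length(parts) > 1L)
        txt <- paste0(txt, paste0("(", parts[-length(parts)], ")", collapse = ""), parts[length(parts)])
      else txt <- paste0(txt, parts)
    }
    txt
  }
  g$bond_order_between <- function(a, b) {
    k <- match(b, g$adj[[a]])
    g$bord[[a]][k]
  }
  emit(root)
}

#' Canonical fragment SMILES of a molgraph
#' @keywords internal
canonical_fragment <- function(g) {
  write_smiles(g, canon_ranks(g, use_h = FALSE), include_h = FALSE)
}

#' Canonical SMILES of a full molecule graph (with explicit H where needed)
#' @keywords internal
canonical_molecule <- function(g) {
  write_smiles(g, canon_ranks(g, use_h = TRUE), include_h = TRUE)
}
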