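# Substructure matching: backtracking subgraph isomorphism (VF2-style).
#
# Matching semantics follow SMARTS conventions restricted to the supported
# pattern subset: an unconstrained property on a query atom (charge, H count,
# aromaticity for wildcards) matches anything; the default (unwritten) bond
# matches a single or an aromatic bond; "~" matches any bond. A molecule
# "contains" a pattern when at least one embedding exists.

#' Test whether a molecule contains a substructure pattern
#'
#' @param query a molgraph parsed with `query = TRUE` (or a fragment graph)
#' @param target a molecule molgraph
#' @return `TRUE` if at least one embedding exists
#' @keywords internal
match_exists <- function(query, target) {
  if (n_atoms(query) > n_atoms(target)) return(FALSE)
  q <- encode_graph(query, use_h = TRUE)
  t <- encode_graph(target, use_h = TRUE)
  # a pattern can itself serve as the target (fragment-inclusion tests);
  # its unwritten bonds then mean aromatic between aromatic atoms, single
  # otherwise, and "~" degrades to single
  if (nrow(t$bond) > 0L) {
    unresolved <- t$bond[, 3L] %in% c(0L, 9L)
    if (any(unresolved)) {
      both_arom <- t$arom[t$bond[, 1L]] == 1L & t$arom[t$bond[, 2L]] == 1L
      t$bond[unresolved, 3L] <- ifelse(both_arom[unresolved], 4L, 1L)
    }
  }
  .match_exists_cpp(q$elem, q$arom, q$charge, q$hcount, q$bond,
                    t$elem, t$arom, t$charge, t$hcount, t$bond)
}

# pattern cache: parsing and query compilation are pure, so memoize per text
.pattern_cache <- new.env(parent = emptyenv())

compile_pattern <- function(pattern) {
  hit <- .pattern_cache[[pattern]]
  if (!is.null(hit)) return(hit)
  g <- parse_smiles(pattern, query = TRUE)
  if (length(unique_components(g)) > 1L)
    stop(sprintf("pattern \"%s\" is disconnected", pattern))
  .pattern_cache[[pattern]] <- g
  g
}

#' Substructure containment of a pattern in molecules
#'
#' @param pattern a SMARTS-subset pattern or fragment SMILES string
#' @param graphs a list of molecule graphs (or a single graph)
#' @return logical vector, one element per molecule
#' @keywords internal
contains_pattern <- function(pattern, graphs) {
  q <- compile_pattern(pattern)
  if (inherits(graphs, "molgraph")) graphs <- list(graphs)
  vapply(graphs, function(t) match_exists(q, t), logical(1))
}
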