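# Candidate-substructure enumeration strategies. Each strategy maps one
# molecule to the set of fragments it contains; build_fragment_table()
# aggregates per-molecule sets into dataset-level support counts
# (each fragment counted at most once per molecule).

MINING_STRATEGIES <- c("circular", "path", "group", "bondbreak", "catalogue")

# BFS bond-distances from one atom
bond_distances <- function(g, from) {
  n <- n_atoms(g)
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    for (b in g$adj[[a]]) {
      if (is.na(d[b])) { d[b] <- d[a] + 1L; queue <- c(queue, b) }
    }
  }
  d
}

# internal per-molecule mining: returns unique fragments as a list of
# molgraphs keyed by canonical identity
mine_circular <- function(g, r_min = 1L, r_max = 4L) {
  stopifnot(r_min >= 1L, r_min <= r_max)
  n <- n_atoms(g)
  frags <- list()
  seen_sets <- character(0)
  for (centre in seq_len(n)) {
    d <- bond_distances(g, centre)
    for (r in r_min:r_max) {
      atoms <- which(!is.na(d) & d <= r)
      if (length(atoms) < 2L) next
      set_id <- paste(atoms, collapse = ",")
      if (set_id %in% seen_sets) next
      seen_sets <- c(seen_sets, set_id)
      frags[[length(frags) + 1L]] <- subgraph(g, atoms)
      if (length(atoms) == n) break  # whole molecule; larger radii identical
    }
  }
  dedupe_by_key(frags)
}

mine_paths <- function(g, l_min = 1L, l_max = 7L) {
  stopifnot(l_min >= 1L, l_min <= l_max)
  n <- n_atoms(g)
  frags <- list()
  seen <- new.env(parent = emptyenv())
  emit <- function(atoms, bonds) {
    # a path and its reverse are the same fragment: key on the cheaper of
    # the two orientations before graph extraction
    key <- paste(min(paste(atoms, collapse = ","),
                     paste(rev(atoms), collapse = ",")),
                 collapse = "")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    frags[[length(frags) + 1L]] <<- subgraph(g, atoms, keep_bonds = bonds)
  }
  bond_index <- function(a, b) {
    which((g$bond[, 1L] == a & g$bond[, 2L] == b) |
          (g$bond[, 1L] == b & g$bond[, 2L] == a))[1L]
  }
  walk <- function(atoms, bonds) {
    len <- length(bonds)
    if (len >= l_min) emit(atoms, bonds)
    if (len == l_max) return(invisible())
    tip <- atoms[length(atoms)]
    for (b in g$adj[[tip]]) {
      if (b %in% atoms) next
      walk(c(atoms, b), c(bonds, bond_index(tip, b)))
    }
  }
  for (s in seq_len(n)) walk(s, integer(0))
  dedupe_by_key(frags)
}

mine_groups <- function(g) {
  n <- n_atoms(g)
  frags <- list()
  # whole aromatic ring systems: components connected by aromatic bonds
  arom_bonds <- which(g$bond[, 3L] == 4L)
  if (length(arom_bonds) > 0L) {
    sub_b <- g$bond[arom_bonds, , drop = FALSE]
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(sub_b))) {
        a <- sub_b[k, 1L]; b <- sub_b[k, 2L]
        m <- min(comp[a], comp[b])
        if (comp[a] != m || comp[b] != m) { comp[a] <- m; comp[b] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    ring_atoms <- unique(as.vector(sub_b[, 1:2]))
    for (cid in unique(comp[ring_atoms])) {
      atoms <- intersect(which(comp == cid), ring_atoms)
      frags[[length(frags) + 1L]] <-
        subgraph(g, atoms, keep_bonds = arom_bonds[
          sub_b[, 1L] %in% atoms & sub_b[, 2L] %in% atoms])
    }
  }
  # heteroatom-seeded functional groups outside aromatic systems
  hetero <- g$elem != "C" & !g$arom
  multi_to_het <- vapply(seq_len(n), function(i) {
    if (g$elem[i] != "C" || g$arom[i]) return(FALSE)
    any(g$bord[[i]] %in% c(2L, 3L) &
          g$elem[g$adj[[i]]] != "C" & !g$arom[g$adj[[i]]])
  }, logical(1))
  seeds <- which(hetero | multi_to_het)
  include <- rep(FALSE, n)
  include[seeds] <- TRUE
  for (s in seeds) {
    multi <- g$adj[[s]][g$bord[[s]] %in% c(2L, 3L)]
    include[multi[!g$arom[multi]]] <- TRUE
  }
  if (any(include)) {
    atoms_all <- which(include)
    # connected components within the included set
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (s in atoms_all) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue) > 0L) {
        a <- queue[1L]; queue <- queue[-1L]
        for (b in g$adj[[a]]) {
          if (include[b] && is.na(comp[b])) { comp[b] <- cid; queue <- c(queue, b) }
        }
      }
    }
    for (k in seq_len(cid)) {
      atoms <- which(!is.na(comp) & comp == k)
      frags[[length(frags) + 1L]] <- subgraph(g, atoms)
    }
  }
  dedupe_by_key(frags)
}

# bridge (acyclic) single bonds: removing one must disconnect its endpoints
breakable_bonds <- function(g) {
  cand <- which(g$bond[, 3L] == 1L)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    k <- cand[i]
    a <- g$bond[k, 1L]; b <- g$bond[k, 2L]
    # BFS from a avoiding bond k
    seen <- logical(n_atoms(g)); seen[a] <- TRUE; queue <- a
    found <- FALSE
    while (length(queue) > 0L && !found) {
      x <- queue[1L]; queue <- queue[-1L]
      for (j in seq_along(g$adj[[x]])) {
        y <- g$adj[[x]][j]
        if ((x == a && y == b) || (x == b && y == a)) {
          # skip only the single direct use of bond k
          if (min(x, y) == min(a, b) && max(x, y) == max(a, b)) next
        }
        if (!seen[y]) {
          if (y == b) { found <- TRUE; break }
          seen[y] <- TRUE; queue <- c(queue, y)
        }
      }
    }
    keep[i] <- !found
  }
  cand[keep]
}

mine_bondbreak <- function(g, min_atoms = 2L, max_atoms = 15L,
                           max_breaks = 3L, cap = 10000L) {
  stopifnot(min_atoms >= 2L, min_atoms <= max_atoms)
  bb <- breakable_bonds(g)
  frags <- list()
  seen <- new.env(parent = emptyenv())
  truncated <- FALSE
  emit_components <- function(removed) {
    keep_bonds <- setdiff(seq_len(nrow(g$bond)), removed)
    # component labels ignoring removed bonds
    n <- n_atoms(g)
    comp <- rep(NA_integer_, n); cid <- 0L
    adj <- vector("list", n)
    for (k in keep_bonds) {
      a <- g$bond[k, 1L]; b <- g$bond[k, 2L]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    for (s in seq_len(n)) {
      if (!is.na(comp[s])) next
      cid <- cid + 1L; comp[s] <- cid; queue <- s
      while (length(queue) > 0L) {
        a <- queue[1L]; queue <- queue[-1L]
        for (b in adj[[a]]) if (is.na(comp[b])) { comp[b] <- cid; queue <- c(queue, b) }
      }
    }
    for (k in seq_len(cid)) {
      atoms <- which(comp == k)
      if (length(atoms) < min_atoms || length(atoms) > max_atoms) next
      set_id <- paste(atoms, collapse = ",")
      if (!is.null(seen[[set_id]])) next
      seen[[set_id]] <- TRUE
      if (length(frags) >= cap) { truncated <<- TRUE; return(invisible()) }
      frags[[length(frags) + 1L]] <<- subgraph(g, atoms)
    }
  }
  # breadth-first in the number of simultaneous breaks, so cap truncation
  # removes the most-fragmented candidates first
  for (k in 0:min(max_breaks, length(bb))) {
    if (truncated) break
    if (k == 0L) {
      emit_components(integer(0))
    } else {
      combos <- utils::combn(bb, k, simplify = FALSE)
      for (cmb in combos) {
        emit_components(cmb)
        if (truncated) break
      }
    }
  }
  if (truncated)
    warning(sprintf("bondbreak fragment cap (%d) reached; enumeration truncated", cap))
  dedupe_by_key(frags)
}

# collapse graphs with equal canonical identity keys
dedupe_by_key <- function(frags) {
  if (length(frags) == 0L)
    return(list(keys = character(0), graphs = list()))
  keys <- vapply(frags, canon_key, character(1))
  first <- !duplicated(keys)
  list(keys = keys[first], graphs = frags[first])
}

as_molgraph <- function(mol) {
  if (inherits(mol, "molgraph")) return(mol)
  parse_smiles(mol)
}

#' Enumerate circular (Morgan-style) atom environments of a molecule
#'
#' For every atom and every bond radius in `[r_min, r_max]`, the environment
#' subgraph (all atoms and bonds within that radius of the centre) is
#' extracted; identical environments are reported once.
#'
#' @param mol a SMILES string or molgraph
#' @param r_min,r_max bond-radius range (defaults 1 and 4)
#' @return character vector of canonical fragment SMILES
#' @export
enumerate_circular <- function(mol, r_min = 1L, r_max = 4L) {
  res <- mine_circular(as_molgraph(mol), r_min, r_max)
  sort(vapply(res$graphs, canonical_fragment, character(1)))
}

#' Enumerate simple linear paths of a molecule
#'
#' All simple paths of `l_min` to `l_max` bonds; a path and its reverse are
#' one fragment. Only the path's own bonds are part of the fragment.
#'
#' @param mol a SMILES string or molgraph
#' @param l_min,l_max path-length range in bonds (defaults 1 and 7)
#' @return character vector of canonical fragment SMILES
#' @export
enumerate_paths <- function(mol, l_min = 1L, l_max = 7L) {
  res <- mine_paths(as_molgraph(mol), l_min, l_max)
  sort(vapply(res$graphs, canonical_fragment, character(1)))
}

#' Enumerate heteroatom-seeded functional groups of a molecule
#'
#' Emits whole aromatic ring systems, plus connected groups grown from
#' non-aromatic heteroatoms and carbons multiply bonded to heteroatoms
#' (each seed merged with its multiply-bonded neighbours). Plain aliphatic
#' carbons are never emitted on their own.
#'
#' @param mol a SMILES string or molgraph
#' @return character vector of canonical fragment SMILES
#' @export
enumerate_groups <- function(mol) {
  res <- mine_groups(as_molgraph(mol))
  sort(vapply(res$graphs, canonical_fragment, character(1)))
}

#' Enumerate fragments by recursive acyclic-bond breaking
#'
#' Breaks acyclic single bonds in all combinations of up to `max_breaks`
#' simultaneous breaks; every connected fragment with a heavy-atom count in
#' `[min_atoms, max_atoms]` is reported once (including the unbroken
#' molecule itself when it fits the range).
#'
#' @param mol a SMILES string or molgraph
#' @param min_atoms,max_atoms heavy-atom bounds (defaults 2 and 15)
#' @param max_breaks maximum simultaneous bond breaks (default 3)
#' @param cap per-molecule fragment cap; enumeration truncates
#'   breadth-first with a warning when reached
#' @return character vector of canonical fragment SMILES
#' @export
enumerate_bondbreak <- function(mol, min_atoms = 2L, max_atoms = 15L,
                                max_breaks = 3L, cap = 10000L) {
  res <- mine_bondbreak(as_molgraph(mol), min_atoms, max_atoms, max_breaks, cap)
  sort(vapply(res$graphs, canonical_fragment, character(1)))
}

#' Count catalogue-pattern support on a dataset
#'
#' Matches every catalogue pattern against every compound and returns the
#' support table (patterns matching no compound are absent).
#'
#' @param dataset a `toxicity_dataset`
#' @param catalogue a `pattern_catalogue`
#' @return a `fragment_table`
#' @export
match_catalogue <- function(dataset, catalogue) {
  stopifnot(inherits(dataset, "toxicity_dataset"),
            inherits(catalogue, "pattern_catalogue"))
  pos <- dataset$records$label == 1L
  rows <- lapply(catalogue$patterns, function(p) {
    hit <- contains_pattern(p, dataset$graphs)
    if (!any(hit)) return(NULL)
    data.frame(pattern = p, origin = "catalogue",
               n_sub = sum(hit), n_sub_positive = sum(hit & pos),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pattern = character(0), origin = character(0),
               n_sub = integer(0), n_sub_positive = integer(0),
               stringsAsFactors = FALSE)
  new_fragment_table(tab, dataset, "catalogue", n_skipped = 0L)
}

new_fragment_table <- function(tab, dataset, strategy, n_skipped = 0L,
                               params = list()) {
  rownames(tab) <- NULL
  structure(
    list(endpoint = dataset$endpoint, strategy = strategy, table = tab,
         n_total = dataset$n_total, n_positive = dataset$n_positive,
         n_skipped = n_skipped, params = params),
    class = "fragment_table"
  )
}

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("<fragment_table> %s/%s: %d fragments over %d compounds\n",
              x$endpoint, x$strategy, nrow(x$table), x$n_total))
  invisible(x)
}

#' Build a dataset-level fragment support table
#'
#' Runs one mining strategy over every compound and unions the per-molecule
#' fragment sets into support counts: `n_sub` = number of compounds
#' containing the fragment, `n_sub_positive` = number of positive compounds
#' containing it. Each fragment is counted at most once per molecule.
#'
#' @param dataset a `toxicity_dataset`
#' @param strategy one of `"circular"`, `"path"`, `"group"`, `"bondbreak"`,
#'   `"catalogue"`
#' @param params strategy parameters: `r_min`/`r_max` (circular),
#'   `l_min`/`l_max` (path), `min_atoms`/`max_atoms`/`max_breaks`/`cap`
#'   (bondbreak), `catalogue` (a `pattern_catalogue`)
#' @return a `fragment_table`
#' @export
build_fragment_table <- function(dataset, strategy = MINING_STRATEGIES,
                                 params = list()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "toxicity_dataset"))
  if (strategy == "catalogue") {
    if (is.null(params$catalogue))
      stop("catalogue strategy requires params$catalogue")
    return(match_catalogue(dataset, params$catalogue))
  }
  miner <- switch(strategy,
    circular = function(g) mine_circular(g, params$r_min %||% 1L,
                                         params$r_max %||% 4L),
    path = function(g) mine_paths(g, params$l_min %||% 1L,
                                  params$l_max %||% 7L),
    group = mine_groups,
    bondbreak = function(g) mine_bondbreak(g, params$min_atoms %||% 2L,
                                           params$max_atoms %||% 15L,
                                           params$max_breaks %||% 3L,
                                           params$cap %||% 10000L)
  )
  pos <- dataset$records$label == 1L
  n_skipped <- 0L
  counts <- new.env(parent = emptyenv())
  reps <- new.env(parent = emptyenv())
  for (i in seq_len(dataset$n_total)) {
    g <- dataset$graphs[[i]]
    if (is.null(g)) {
      n_skipped <- n_skipped + 1L
      warning(sprintf("skipping unparseable record %s", dataset$records$id[i]))
      next
    }
    mined <- miner(g)
    for (k in seq_along(mined$keys)) {
      key <- mined$keys[k]
      prev <- counts[[key]]
      if (is.null(prev)) {
        counts[[key]] <- c(1L, as.integer(pos[i]))
        reps[[key]] <- mined$graphs[[k]]
      } else {
        counts[[key]] <- prev + c(1L, as.integer(pos[i]))
      }
    }
  }
  keys <- ls(counts, sorted = TRUE)
  tab <- data.frame(
    pattern = vapply(keys, function(k) canonical_fragment(reps[[k]]),
                     character(1), USE.NAMES = FALSE),
    origin = strategy,
    n_sub = vapply(keys, function(k) counts[[k]][1L], integer(1),
                   USE.NAMES = FALSE),
    n_sub_positive = vapply(keys, function(k) counts[[k]][2L], integer(1),
                            USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$pattern), , drop = FALSE]
  new_fragment_table(tab, dataset, strategy, n_skipped = n_skipped,
                     params = params)
}
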