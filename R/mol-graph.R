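# Molecular graphs parsed from SMILES / SMARTS-subset patterns.
#
# A molgraph is a plain list:
#   elem   character atomic symbols ("*" = any-atom query wildcard)
#   arom   logical aromatic flag (NA in queries = unconstrained)
#   charge integer formal charge (NA in queries = unconstrained)
#   hcount integer total hydrogen count (explicit or implicit; NA in queries
#          = unconstrained, an integer = exact-count constraint)
#   bond   integer matrix with columns a, b, order; order 1/2/3, 4 = aromatic,
#          0 = unspecified query bond (single-or-aromatic), 9 = any (~)
# Aromaticity is taken from the notation (lowercase atoms); full molecules
# are expected to arrive pre-canonicalized by OpenBabel so that aromatic
# systems are consistently written in aromatic form.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ELEMS <- c("b", "c", "n", "o", "p", "s")

# default valences used for implicit hydrogen assignment; multi-valent
# elements get the smallest valence >= current bond order sum
DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

ELEMENT_NUMBERS <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L, S = 16L,
  Cl = 17L, Br = 35L, I = 53L
)

new_molgraph <- function(elem, arom, charge, hcount, bond) {
  g <- list(
    elem = elem, arom = arom, charge = as.integer(charge),
    hcount = as.integer(hcount),
    bond = matrix(as.integer(bond), ncol = 3L,
                  dimnames = list(NULL, c("a", "b", "order")))
  )
  n <- length(elem)
  adj <- vector("list", n)
  bord <- vector("list", n)
  if (nrow(g$bond) > 0L) {
    for (k in seq_len(nrow(g$bond))) {
      a <- g$bond[k, 1L]; b <- g$bond[k, 2L]; o <- g$bond[k, 3L]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      bord[[a]] <- c(bord[[a]], o); bord[[b]] <- c(bord[[b]], o)
    }
  }
  g$adj <- adj
  g$bord <- bord
  class(g) <- "molgraph"
  g
}

n_atoms <- function(g) length(g$elem)

#' Number of heavy atoms in a SMILES string
#'
#' Parses the string with the package's SMILES reader and counts atoms
#' (hydrogens are implicit and not counted).
#'
#' @param smiles a single SMILES string
#' @return integer atom count
#' @export
heavy_atom_count <- function(smiles) {
  n_atoms(parse_smiles(smiles))
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset plus bracket atoms with charge, explicit
#' hydrogen counts and atom maps. Stereochemistry markers are accepted and
#' ignored. Disconnected structures (`.`) are rejected; strip salts first
#' (see [load_dataset()]).
#'
#' @param s SMILES string
#' @param query if `TRUE`, parse as a substructure query: `*`, `a`, `A`,
#'   `[#n]` atoms and `~` bonds are allowed, unwritten charge/H-count are
#'   unconstrained rather than zero/implicit.
#' @return a `molgraph` object (internal representation)
#' @keywords internal
parse_smiles <- function(s, query = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("expected a single non-empty SMILES string")
  chars <- strsplit(s, "")[[1]]
  np <- length(chars)

  elem <- character(); arom <- logical(); charge <- integer()
  hq <- integer()   # explicit H count (NA = unspecified)
  atom_map <- integer()

  bond_a <- integer(); bond_b <- integer(); bond_o <- integer()
  prev <- NA_integer_      # atom awaiting the next bond
  pend <- NA_integer_      # pending explicit bond order for next attachment
  stack <- integer()       # open branch points
  ring <- list()           # ring-closure digit -> c(atom, pending order)

  fail <- function(msg, i) {
    stop(sprintf("SMILES parse error at position %d in \"%s\": %s", i, s, msg))
  }

  add_atom <- function(el, ar, ch, h, map) {
    elem[[length(elem) + 1L]] <<- el
    arom[[length(arom) + 1L]] <<- ar
    charge[[length(charge) + 1L]] <<- as.integer(ch)
    hq[[length(hq) + 1L]] <<- as.integer(h)
    atom_map[[length(atom_map) + 1L]] <<- as.integer(map)
    idx <- length(elem)
    if (!is.na(prev)) {
      o <- if (!is.na(pend)) pend
      else if (!query && arom[prev] && ar) 4L
      else if (query) 0L else 1L
      bond_a[[length(bond_a) + 1L]] <<- prev
      bond_b[[length(bond_b) + 1L]] <<- idx
      bond_o[[length(bond_o) + 1L]] <<- o
    }
    prev <<- idx
    pend <<- NA_integer_
    idx
  }

  close_ring <- function(key, i) {
    if (is.na(prev)) fail("ring-closure digit before any atom", i)
    if (!is.null(ring[[key]])) {
      opener <- ring[[key]][1L]
      oord <- ring[[key]][2L]
      o <- if (!is.na(pend)) pend
      else if (!is.na(oord)) oord
      else if (!query && arom[opener] && arom[prev]) 4L
      else if (query) 0L else 1L
      if (opener == prev) fail("ring closure to the same atom", i)
      bond_a[[length(bond_a) + 1L]] <<- opener
      bond_b[[length(bond_b) + 1L]] <<- prev
      bond_o[[length(bond_o) + 1L]] <<- o
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <<- c(prev, pend)
      pend <<- NA_integer_
    }
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      if (ch == "~" && !query) fail("'~' bond is only valid in queries", i)
      pend <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L, "~" = 9L,
                     "/" = 1L, "\\" = 1L)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom", i)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unmatched ')'", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, i)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > np || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        fail("'%' must be followed by two digits", i)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L
    } else if (ch == ".") {
      fail("disconnected structures ('.') are not supported here; strip components first", i)
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) fail("unclosed '['", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, query, function(msg) fail(msg, i))
      add_atom(at$elem, at$arom, at$charge, at$h, at$map)
      i <- j + 1L
    } else if (ch == "*") {
      if (!query) fail("'*' atom is only valid in queries", i)
      add_atom("*", NA, NA_integer_, NA_integer_, NA_integer_)
      i <- i + 1L
    } else if (ch %in% c("a", "A") && query) {
      # bare SMARTS wildcards: a = any aromatic atom, A = any aliphatic atom
      add_atom("*", ch == "a", NA_integer_, NA_integer_, NA_integer_)
      i <- i + 1L
    } else {
      two <- if (i < np) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, if (query) NA_integer_ else 0L, NA_integer_,
                 NA_integer_)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE, if (query) NA_integer_ else 0L, NA_integer_,
                 NA_integer_)
        i <- i + 1L
      } else if (ch %in% AROMATIC_ELEMS) {
        add_atom(toupper(ch), TRUE, if (query) NA_integer_ else 0L,
                 NA_integer_, NA_integer_)
        i <- i + 1L
      } else {
        fail(sprintf("unexpected character '%s'", ch), i)
      }
    }
  }
  if (length(stack) > 0L) stop(sprintf("unmatched '(' in \"%s\"", s))
  if (length(ring) > 0L) stop(sprintf("unclosed ring bond in \"%s\"", s))
  if (length(elem) == 0L) stop(sprintf("no atoms in \"%s\"", s))

  g <- new_molgraph(elem, arom, charge, hq, cbind(bond_a, bond_b, bond_o))
  g$atom_map <- atom_map
  if (!query) {
    if (length(unique_components(g)) > 1L)
      stop(sprintf("\"%s\" is disconnected", s))
    g$hcount <- compute_hcounts(g)
    g$charge[is.na(g$charge)] <- 0L
  }
  g$query <- query
  g
}

# bracket atom body, e.g. "OH", "N+", "nH", "13CH3", "#7", "C@@H2", "O-2", "C:1"
parse_bracket_atom <- function(body, query, fail) {
  rest <- body
  take <- function(pattern) {
    m <- regmatches(rest, regexpr(pattern, rest))
    if (length(m) == 1L && nzchar(m)) {
      rest <<- substring(rest, nchar(m) + 1L)
      m
    } else ""
  }
  take("^[0-9]+")  # isotope label: accepted, ignored
  elem <- NA_character_; arom <- NA
  if (nzchar(take("^\\*"))) {
    if (!query) fail("'*' atom is only valid in queries")
    elem <- "*"
  } else {
    hash <- take("^#[0-9]+")
    if (nzchar(hash)) {
      if (!query) fail("'#n' atoms are only valid in queries")
      z <- as.integer(substring(hash, 2L))
      hit <- names(ELEMENT_NUMBERS)[match(z, ELEMENT_NUMBERS)]
      if (is.na(hit)) fail(sprintf("unsupported atomic number %d", z))
      elem <- hit
      arom <- NA  # aromaticity unconstrained for #n
    } else {
      sym <- take("^(Cl|Br|Si|Se|As|[BCNOPSFI]|[bcnops]|se|as)")
      if (!nzchar(sym)) fail(sprintf("cannot read element in \"[%s]\"", body))
      if (sym %in% c("Si", "Se", "As", "se", "as"))
        fail(sprintf("element \"%s\" is outside the supported set", sym))
      arom <- sym %in% AROMATIC_ELEMS
      elem <- if (arom) toupper(sym) else sym
    }
  }
  take("^@{1,2}")  # chirality: accepted, ignored
  h <- NA_integer_
  hm <- take("^H[0-9]*")
  if (nzchar(hm))
    h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
  chg <- NA_integer_
  cm <- take("^(\\+[0-9]+|-[0-9]+|\\++|-+)")
  if (nzchar(cm)) {
    chg <- if (grepl("^[+-][0-9]", cm)) {
      as.integer(cm)
    } else {
      sgn <- if (substring(cm, 1L, 1L) == "+") 1L else -1L
      sgn * nchar(cm)
    }
  }
  map <- NA_integer_
  mm <- take("^:[0-9]+")
  if (nzchar(mm)) map <- as.integer(substring(mm, 2L))
  if (nzchar(rest))
    fail(sprintf("unsupported bracket-atom content \"%s\" in \"[%s]\"", rest, body))
  if (!query) {
    if (is.na(chg)) chg <- 0L
    if (is.na(h)) h <- 0L  # bracket atoms carry their full explicit H count
  }
  list(elem = elem, arom = arom, charge = chg, h = h, map = map)
}

# implicit hydrogens from default valences; bracket atoms keep their explicit
# count (already set, non-NA). Aromatic C/N/B/P contribute one extra valence
# unit (their ring double bond); aromatic O/S contribute a lone pair instead.
AROMATIC_VALENCE_BUMP <- c("C", "N", "B", "P")

compute_hcounts <- function(g) {
  h <- g$hcount
  for (i in seq_len(n_atoms(g))) {
    if (!is.na(h[i])) next
    orders <- g$bord[[i]]
    bsum <- sum(ifelse(orders == 4L, 1L, orders))
    if (g$arom[i] && g$elem[i] %in% AROMATIC_VALENCE_BUMP) bsum <- bsum + 1L
    vals <- DEFAULT_VALENCE[[g$elem[i]]]
    if (is.null(vals)) { h[i] <- 0L; next }
    v <- vals[vals >= bsum]
    h[i] <- if (length(v) == 0L) 0L else min(v) - bsum
  }
  as.integer(h)
}

# connected components as a list of atom-index vectors
unique_components <- function(g) {
  n <- n_atoms(g)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer()
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, a)
      for (b in g$adj[[a]]) if (!seen[b]) { seen[b] <- TRUE; queue <- c(queue, b) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# subgraph on a set of atoms; keep_bonds = "induced" (all bonds between kept
# atoms) or an integer vector of bond-row indices (edge subgraph, e.g. paths)
subgraph <- function(g, atoms, keep_bonds = "induced") {
  atoms <- sort(unique(as.integer(atoms)))
  remap <- integer(n_atoms(g))
  remap[atoms] <- seq_along(atoms)
  if (identical(keep_bonds, "induced")) {
    keep <- which(g$bond[, 1L] %in% atoms & g$bond[, 2L] %in% atoms)
  } else {
    keep <- as.integer(keep_bonds)
  }
  b <- g$bond[keep, , drop = FALSE]
  sg <- new_molgraph(
    elem = g$elem[atoms], arom = g$arom[atoms], charge = g$charge[atoms],
    hcount = g$hcount[atoms],
    bond = cbind(remap[b[, 1L]], remap[b[, 2L]], b[, 3L])
  )
  sg$query <- isTRUE(g$query)
  sg
}
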