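# Seeded generator of labelled SMILES datasets with known ground-truth
# toxicophores. Molecules are assembled by attaching substituents (and, for
# designated positives, a toxicophore) to drug-like scaffolds via single
# bonds at hydrogen-bearing atoms, so every emitted SMILES is valid by
# construction and the toxicophore carriage of every record is known.

# ~20 drug-like ring scaffolds
DEFAULT_SCAFFOLDS <- c(
  "c1ccccc1",            # benzene
  "c1ccncc1",            # pyridine
  "c1cncnc1",            # pyrimidine
  "c1ccoc1",             # furan
  "c1ccsc1",             # thiophene
  "c1cc[nH]c1",          # pyrrole
  "c1c[nH]cn1",          # imidazole
  "c1cscn1",             # thiazole
  "c1ccc2ccccc2c1",      # naphthalene
  "c1ccc2ncccc2c1",      # quinoline
  "c1ccc2[nH]ccc2c1",    # indole
  "C1CCCCC1",            # cyclohexane
  "C1CCCC1",             # cyclopentane
  "C1CCNCC1",            # piperidine
  "C1CNCCN1",            # piperazine
  "C1COCCN1",            # morpholine
  "C1CCOC1",             # tetrahydrofuran
  "C1CCNC1",             # pyrrolidine
  "c1ccc(cc1)C1CCCCC1",  # phenylcyclohexane
  "c1ccc(cc1)-c1ccccc1"  # biphenyl
)

# ~15 benign substituents; the first atom is the attachment point
DEFAULT_DECORATIONS <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "N", "N(C)C", "F", "Cl", "Br",
  "C(F)(F)F", "CO", "SC", "C#N"
)

# named toxicophore substituents; the first atom is the attachment point
TOXICOPHORE_LIBRARY <- c(
  nitro = "[N+](=O)[O-]",
  aldehyde = "C=O",
  epoxide = "C1CO1",
  michael_acceptor = "C(=O)C=C",
  chloroacetyl = "C(=O)CCl"
)

#' Specification of a synthetic toxicity dataset
#'
#' The defaults describe the generator's reference condition: 500 molecules,
#' 40% positives, a single implanted nitro toxicophore, decoy carriage in
#' 10% of the remaining molecules and 5% label noise. Set
#' `positive_fraction = 0.1` to emulate a heavily imbalanced endpoint.
#'
#' @param n_molecules number of unique molecules (>= 10)
#' @param positive_fraction probability a molecule is designated positive
#' @param toxicophores character vector of toxicophore substituent SMILES
#'   (first atom = attachment point); names are kept for reporting. Defaults
#'   to the nitro group.
#' @param implant_prob probability a designated positive receives a
#'   toxicophore (its pre-noise label is its actual carriage)
#' @param decoy_prob probability that a molecule *not* designated as a
#'   toxic carrier still receives a toxicophore substituent while keeping
#'   its negative label — carriage without toxicity. This emulates endpoints
#'   where the fragment is not mechanistically sufficient, and is what makes
#'   heavily imbalanced datasets fail the precision floor the way real
#'   imbalanced endpoints do.
#' @param label_noise probability of flipping each final label
#' @param scaffold_pool,decoration_pool SMILES pools used for assembly
#' @param seed RNG seed; generation is fully deterministic given the spec
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(n_molecules = 500L, positive_fraction = 0.4,
                           toxicophores = TOXICOPHORE_LIBRARY["nitro"],
                           implant_prob = 1.0, decoy_prob = 0.10,
                           label_noise = 0.05,
                           scaffold_pool = DEFAULT_SCAFFOLDS,
                           decoration_pool = DEFAULT_DECORATIONS,
                           seed = 1L) {
  stopifnot(n_molecules >= 10L,
            positive_fraction >= 0, positive_fraction <= 1,
            implant_prob >= 0, implant_prob <= 1,
            decoy_prob >= 0, decoy_prob <= 1,
            label_noise >= 0, label_noise <= 1,
            length(scaffold_pool) > 0L, length(decoration_pool) > 0L,
            length(toxicophores) > 0L)
  if (is.null(names(toxicophores)))
    names(toxicophores) <- sprintf("tox%d", seq_along(toxicophores))
  structure(
    list(n_molecules = as.integer(n_molecules),
         positive_fraction = positive_fraction,
         toxicophores = toxicophores, implant_prob = implant_prob,
         decoy_prob = decoy_prob, label_noise = label_noise,
         scaffold_pool = scaffold_pool,
         decoration_pool = decoration_pool, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Join two graphs with a single bond. The host atom must bear a hydrogen;
# the incoming fragment's attachment atom either gives up a hydrogen or,
# when written H-free (e.g. the nitrogen of "[N+](=O)[O-]"), is taken to
# declare an open valence.
attach_fragment <- function(gA, atomA, gB, atomB) {
  stopifnot(gA$hcount[atomA] >= 1L)
  nA <- n_atoms(gA)
  bondB <- gB$bond
  if (nrow(bondB) > 0L) bondB[, 1:2] <- bondB[, 1:2] + nA
  g <- new_molgraph(
    elem = c(gA$elem, gB$elem), arom = c(gA$arom, gB$arom),
    charge = c(gA$charge, gB$charge), hcount = c(gA$hcount, gB$hcount),
    bond = rbind(gA$bond, bondB, c(atomA, atomB + nA, 1L))
  )
  g$hcount[atomA] <- g$hcount[atomA] - 1L
  if (g$hcount[atomB + nA] >= 1L)
    g$hcount[atomB + nA] <- g$hcount[atomB + nA] - 1L
  g$query <- FALSE
  g
}

open_positions <- function(g) which(g$hcount >= 1L)

# deterministic sample helpers driven by the current RNG stream
pick <- function(n) if (n == 1L) 1L else sample.int(n, 1L)

assemble_molecule <- function(scaffold_g, decoration_gs, tox_g = NULL) {
  g <- scaffold_g
  if (!is.null(tox_g)) {
    pos <- open_positions(g)
    if (length(pos) == 0L) return(NULL)
    g <- attach_fragment(g, pos[pick(length(pos))], tox_g, 1L)
  }
  for (dg in decoration_gs) {
    pos <- open_positions(g)
    if (length(pos) == 0L) return(NULL)
    g <- attach_fragment(g, pos[pick(length(pos))], dg, 1L)
  }
  g
}

#' Generate a synthetic toxicity dataset with known toxicophores
#'
#' Molecules are assembled from the spec's pools; designated positives
#' (probability `positive_fraction`) carry a toxicophore with probability
#' `implant_prob`, and other molecules carry a decoy copy with probability
#' `decoy_prob` while keeping their negative label. Pre-noise labels equal
#' designated toxicophore carriage; actual carriage of every record is
#' verified by substructure matching (molecules whose carriage disagrees
#' with their designation are regenerated, as are duplicates). Labels are
#' then flipped independently with probability `label_noise`. Fully
#' deterministic per spec.
#'
#' @param spec a [synthetic_spec()]
#' @return a `synthetic_dataset`: list with `dataset` (a
#'   `toxicity_dataset`), `truth` (per-record carriage data frame) and
#'   `spec`
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  scaffolds <- lapply(spec$scaffold_pool, parse_smiles)
  decorations <- lapply(spec$decoration_pool, parse_smiles)
  tox_graphs <- lapply(spec$toxicophores, parse_smiles)
  n <- spec$n_molecules

  smiles <- character(n)
  carrier <- logical(n)
  decoy <- logical(n)
  tox_name <- rep(NA_character_, n)
  seen <- new.env(parent = emptyenv())
  max_rounds <- 200L

  for (i in seq_len(n)) {
    ok <- FALSE
    # designation is drawn once per molecule (not per assembly attempt), so
    # the positive fraction is exactly Bernoulli(positive_fraction) and is
    # not biased by collision rates that differ between the two classes
    designated <- runif(1) < spec$positive_fraction
    implant <- designated && runif(1) < spec$implant_prob
    is_decoy <- !implant && runif(1) < spec$decoy_prob
    with_tox <- implant || is_decoy
    for (attempt in seq_len(max_rounds)) {
      ti <- if (with_tox) pick(length(tox_graphs)) else NA_integer_
      n_dec <- sample.int(3L, 1L)
      dec <- decorations[sample.int(length(decorations), n_dec,
                                    replace = TRUE)]
      g <- assemble_molecule(scaffolds[[pick(length(scaffolds))]], dec,
                             if (with_tox) tox_graphs[[ti]] else NULL)
      if (is.null(g)) next
      smi <- canonical_smiles(canonical_molecule(g))
      if (is.na(smi) || !is.null(seen[[smi]])) next
      # actual carriage must equal the designated carriage
      mg <- tryCatch(parse_smiles(smi), error = function(e) NULL)
      if (is.null(mg)) next
      actual <- any(vapply(spec$toxicophores, function(p)
        contains_pattern(p, mg), logical(1)))
      if (actual != with_tox) next
      seen[[smi]] <- TRUE
      smiles[i] <- smi
      carrier[i] <- implant
      decoy[i] <- is_decoy
      tox_name[i] <- if (with_tox) names(spec$toxicophores)[ti] else NA_character_
      ok <- TRUE
      break
    }
    if (!ok)
      stop("cannot assemble enough unique molecules; enlarge the scaffold/decoration pools")
  }

  label_pre <- as.integer(carrier)
  flip <- runif(n) < spec$label_noise
  label <- ifelse(flip, 1L - label_pre, label_pre)
  ids <- sprintf("s%04d", seq_len(n))
  ds <- toxicity_dataset(smiles, label, id = ids,
                         endpoint = sprintf("synthetic_seed%d", spec$seed),
                         canonicalize = FALSE)
  truth <- data.frame(id = ids, smiles = smiles, carrier = carrier,
                      decoy = decoy, toxicophore = tox_name,
                      label_pre_noise = label_pre,
                      label = label, flipped = flip,
                      stringsAsFactors = FALSE)
  structure(list(dataset = ds, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> n=%d, %d carriers, %d positive labels, seed=%d\n",
              nrow(x$truth), sum(x$truth$carrier), sum(x$truth$label),
              x$spec$seed))
  invisible(x)
}

#' Ground-truth recovery report for a mined alert set
#'
#' For each toxicophore of the generating spec, reports whether any mined
#' alert equals it (after normalization), is contained in it, or contains
#' it, together with the rank (by information gain) of the best-matching
#' alert. Toxicophores implanted in no molecule are marked not recoverable.
#'
#' @param alerts an `alert_set` mined on the synthetic dataset (or a
#'   training split of it)
#' @param synth a `synthetic_dataset`
#' @return data frame with one row per toxicophore
#' @export
recovery_report <- function(alerts, synth) {
  stopifnot(inherits(alerts, "alert_set"), inherits(synth, "synthetic_dataset"))
  ranked <- rank_top_k(alerts, max(1L, n_alerts(alerts)))
  tox <- synth$spec$toxicophores
  rows <- lapply(seq_along(tox), function(ti) {
    name <- names(tox)[ti]
    implanted <- sum(synth$truth$carrier &
                       synth$truth$toxicophore == name, na.rm = TRUE)
    if (implanted == 0L)
      return(data.frame(toxicophore = name, pattern = unname(tox[ti]),
                        implanted = 0L, recovered = FALSE,
                        relation = "not recoverable", best_rank = NA_integer_,
                        stringsAsFactors = FALSE))
    tox_canon <- normalize_pattern(tox[[ti]])$canonical
    relation <- "none"; best_rank <- NA_integer_
    if (nrow(ranked) > 0L) {
      for (r in seq_len(nrow(ranked))) {
        a <- ranked$pattern[r]
        rel <- if (normalize_pattern(a)$canonical == tox_canon) "equal"
        else if (pattern_includes(a, tox_canon)) "within"
        else if (pattern_includes(tox_canon, a)) "contains"
        else next
        relation <- rel; best_rank <- r
        break
      }
    }
    data.frame(toxicophore = name, pattern = unname(tox[ti]),
               implanted = implanted, recovered = relation != "none",
               relation = relation, best_rank = best_rank,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
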