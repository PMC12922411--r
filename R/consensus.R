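# Consensus benchmark construction across mining strategies: pattern
# normalization, inclusion-based consolidation to the simpler pattern,
# strategy intersection, pairwise overlap counting, and comparison of
# top-ranked alerts against a reference catalogue.

#' Normalize a substructure pattern
#'
#' Strips atom maps and hydrogen-count decorations and rewrites the pattern
#' as a canonical fragment SMILES, so that notational variants of the same
#' substructure compare equal. Query atoms that do not reduce to a plain
#' atom (wildcards) keep their canonical text form (`*`).
#'
#' @param pattern a SMARTS-subset pattern or fragment SMILES
#' @return list with `canonical` (string) and `heavy_atoms` (count)
#' @export
normalize_pattern <- function(pattern) {
  g <- parse_smiles(pattern, query = TRUE)
  g$hcount[] <- NA_integer_   # drop H decorations
  g$atom_map <- NULL          # drop position markings
  list(canonical = canonical_fragment(g), heavy_atoms = n_atoms(g),
       rings = nrow(g$bond) - n_atoms(g) + 1L)
}

# deterministic "simpler" ordering: fewer heavy atoms, then fewer rings,
# then lexicographic canonical SMILES
normalize_many <- function(patterns, sources = NULL) {
  norm <- lapply(patterns, normalize_pattern)
  df <- data.frame(
    canonical = vapply(norm, `[[`, character(1), "canonical"),
    heavy_atoms = vapply(norm, `[[`, integer(1), "heavy_atoms"),
    rings = vapply(norm, `[[`, integer(1), "rings"),
    stringsAsFactors = FALSE
  )
  if (is.null(sources)) sources <- rep(list(character(0)), nrow(df))
  # merge duplicates, unioning sources
  out <- df[!duplicated(df$canonical), , drop = FALSE]
  out$sources <- lapply(out$canonical, function(cn) {
    sort(unique(unlist(sources[df$canonical == cn])))
  })
  rownames(out) <- NULL
  out
}

pattern_includes <- function(inner, outer) {
  # inner is a substructure of outer
  match_exists(compile_pattern(inner), compile_pattern(outer))
}

#' Consolidate normalized patterns by inclusion
#'
#' When one pattern is a substructure of another, the two are considered
#' the same alert and the simpler one (fewer heavy atoms, then fewer rings,
#' then lexicographically smaller canonical SMILES) survives with the
#' union of the sources. Applied to a fixed point; the result is
#' independent of input order.
#'
#' @param patterns character vector of patterns (or a data frame from an
#'   earlier normalization)
#' @param sources optional list of source tags, parallel to `patterns`
#' @return data frame with columns `canonical`, `heavy_atoms`, `rings`,
#'   `sources`
#' @export
consolidate_patterns <- function(patterns, sources = NULL) {
  df <- if (is.data.frame(patterns)) patterns
  else normalize_many(patterns, sources)
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$heavy_atoms, df$rings, df$canonical), , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !alive[j]) next
      # df is sorted simplest-first, so only "i inside j" can collapse j
      if (j > i && pattern_includes(df$canonical[i], df$canonical[j])) {
        df$sources[[i]] <- sort(unique(c(df$sources[[i]], df$sources[[j]])))
        alive[j] <- FALSE
      }
    }
  }
  out <- df[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a consensus benchmark alert set across strategies
#'
#' Strategies contributing fewer than `min_set_size` alerts are excluded;
#' each remaining strategy's patterns are normalized and consolidated; the
#' benchmark is the set of consolidated patterns present in every remaining
#' strategy. An empty intersection is a valid outcome; exclusion of all
#' strategies sets an explanatory flag.
#'
#' @param sets named list of `alert_set` objects (one per strategy)
#' @param min_set_size minimum alert count for a strategy to participate
#'   (default 20)
#' @return a `consensus_set` with fields `endpoint`, `included_strategies`,
#'   `benchmark` (data frame), `overlap` (matrix), `flag`
#' @export
build_benchmark <- function(sets, min_set_size = 20L) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  endpoint <- sets[[1L]]$endpoint
  sizes <- vapply(sets, n_alerts, integer(1))
  included <- names(sets)[sizes >= min_set_size]
  consolidated <- lapply(names(sets), function(s) {
    if (n_alerts(sets[[s]]) == 0L)
      return(data.frame(canonical = character(0), heavy_atoms = integer(0),
                        rings = integer(0),
                        sources = I(list()), stringsAsFactors = FALSE))
    consolidate_patterns(sets[[s]]$alerts$pattern,
                         rep(list(s), n_alerts(sets[[s]])))
  })
  names(consolidated) <- names(sets)
  flag <- NULL
  if (length(included) == 0L) {
    benchmark <- data.frame(canonical = character(0),
                            heavy_atoms = integer(0), rings = integer(0),
                            sources = I(list()), stringsAsFactors = FALSE)
    flag <- sprintf("all strategies below min_set_size = %d", min_set_size)
  } else {
    common <- Reduce(intersect, lapply(included, function(s)
      consolidated[[s]]$canonical))
    first <- consolidated[[included[1L]]]
    benchmark <- first[first$canonical %in% common, , drop = FALSE]
    benchmark$sources <- rep(list(included), nrow(benchmark))
    rownames(benchmark) <- NULL
  }
  structure(
    list(endpoint = endpoint, included_strategies = included,
         benchmark = benchmark,
         overlap = if (length(sets) >= 2L) pairwise_overlap(sets) else NULL,
         consolidated = consolidated, flag = flag),
    class = "consensus_set"
  )
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %s: %d benchmark alerts from {%s}\n",
              x$endpoint, nrow(x$benchmark),
              paste(x$included_strategies, collapse = ", ")))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Pairwise overlap counts between strategies' alert sets
#'
#' Entry (i, j) is the number of identical substructures (after
#' normalization and consolidation) shared by strategies i and j; the
#' diagonal holds each strategy's own consolidated set size.
#'
#' @param sets named list of `alert_set` objects (at least 2)
#' @return symmetric integer matrix
#' @export
pairwise_overlap <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  cons <- lapply(names(sets), function(s) {
    if (n_alerts(sets[[s]]) == 0L) return(character(0))
    consolidate_patterns(sets[[s]]$alerts$pattern)$canonical
  })
  names(cons) <- names(sets)
  k <- length(sets)
  m <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- if (i == j) length(cons[[i]])
      else length(intersect(cons[[i]], cons[[j]]))
      m[i, j] <- v; m[j, i] <- v
    }
  }
  m
}

#' Compare top-ranked alerts with a reference alert collection
#'
#' Takes the top `k` alerts by information gain and reports, for each, its
#' relation to the reference catalogue: `"equal"` (same normalized
#' pattern), `"within"` (the alert is a substructure of a reference
#' pattern), `"contains"` (a reference pattern is a substructure of the
#' alert) or `"none"`. The summary `overlap` counts alerts with any
#' relation.
#'
#' @param alerts a scored `alert_set`
#' @param reference a `pattern_catalogue`
#' @param k number of top alerts to compare (default 10)
#' @return list with `detail` data frame and `overlap` count
#' @export
compare_to_reference <- function(alerts, reference, k = 10L) {
  stopifnot(inherits(alerts, "alert_set"),
            inherits(reference, "pattern_catalogue"))
  top <- rank_top_k(alerts, k)
  ref_norm <- vapply(reference$patterns,
                     function(p) normalize_pattern(p)$canonical, character(1))
  relation <- character(nrow(top))
  matched_ref <- character(nrow(top))
  for (i in seq_len(nrow(top))) {
    a <- normalize_pattern(top$pattern[i])$canonical
    rel <- "none"; hit <- NA_character_
    for (j in seq_along(ref_norm)) {
      r <- ref_norm[j]
      if (a == r) { rel <- "equal"; hit <- reference$patterns[j]; break }
    }
    if (rel == "none") {
      for (j in seq_along(ref_norm)) {
        r <- ref_norm[j]
        if (pattern_includes(a, r)) { rel <- "within"; hit <- reference$patterns[j]; break }
        if (pattern_includes(r, a)) { rel <- "contains"; hit <- reference$patterns[j]; break }
      }
    }
    relation[i] <- rel; matched_ref[i] <- hit
  }
  detail <- data.frame(pattern = top$pattern, ig = top$ig,
                       relation = relation, reference = matched_ref,
                       stringsAsFactors = FALSE)
  list(detail = detail, overlap = sum(relation != "none"), k = nrow(top))
}
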