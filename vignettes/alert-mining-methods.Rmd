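---
title: "Mining and evaluating structural alerts with samine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evaluating structural alerts with samine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A structural alert (SA) is a substructure whose presence in a molecule flags
potential toxicity. Given a table of compounds with binary toxicity labels,
the task is to find substructures that are (i) frequent enough to matter,
(ii) strongly enriched among toxic compounds, and (iii) informative about
the label. `samine` implements the full workflow: candidate fragment
enumeration by several strategies, statistical filtering, per-substructure
scoring, evaluation of an alert set as a classifier, consensus construction
across strategies, and integration with a fingerprint-based QSAR model.

## Data model and pretreatment

`load_dataset()` reads a CSV/TSV with a SMILES column and a binary label
column and applies three pretreatment steps before anything else runs:

1. **Washing.** Multi-component SMILES (salts, solvates) are reduced to the
   single covalent fragment with the most heavy atoms; ties break by the
   lexicographically smallest canonical SMILES. This is a deliberate,
   rule-explicit stand-in for vendor "wash" tools whose exact settings are
   not public.
2. **Canonicalization.** Every structure is rewritten as OpenBabel
   canonical SMILES (via ChemmineOB). Canonical equality within one kernel
   is the identity used everywhere; equality across different toolkits'
   canonical forms is not promised.
3. **Deduplication.** Records with the same canonical SMILES collapse to
   one. If duplicates disagree on the label the compound is dropped
   entirely and counted — silently averaging contradictory toxicity calls
   would bias every downstream statistic.

Labels must be in `{0, 1, true, false}`; anything else is an error rather
than a guess.

## The fragment kernel

Fragment-level work — extracting subgraphs, deciding when two fragments are
the same, and matching a fragment back against molecules — is done by an
in-package molecular-graph layer with compiled (Rcpp) kernels for canonical
ranking and subgraph isomorphism. This layer exists because general
cheminformatics toolkits are built around whole, valence-complete
molecules: a three-atom aromatic chain extracted from a benzene ring is not
a valid molecule, and round-tripping it through a molecule-centric
canonicalizer destroys its identity. Fragment identity here is the
canonical SMILES of the extracted subgraph, computed by Morgan-style
iterative refinement plus backtracking over residual symmetry. Hydrogen
counts are excluded from fragment identity (a fragment is an
attachment-free query), and an unwritten charge equals zero charge.

Matching follows SMARTS conventions on a documented subset: element symbols
with aromatic lowercase, bracket atoms with charge/H-count/atom maps,
`[#n]`, `*`, `a`/`A`, and bond symbols `-`, `=`, `#`, `:`, `~`; an
unwritten bond matches single or aromatic. Logical SMARTS operators
(`!`, `,`, `&`, `;`) are rejected with a clear error — supporting them
would mean reimplementing a SMARTS engine, and every pattern the toolkit
itself emits stays inside the subset. Catalogue files using richer SMARTS
are reported line-by-line at load time.

## Mining strategies

All strategies share one counting semantics: a fragment is counted at most
once per molecule, and `n_sub` / `n_sub_positive` are numbers of compounds
(not occurrences).

* **circular** — for every atom and every bond radius in `[r_min, r_max]`
  (defaults 1–4), the environment subgraph within that radius. Radius
  counts bonds, so an isolated atom yields nothing.
* **path** — all simple linear paths of `[l_min, l_max]` bonds (defaults
  1–7); a path and its reverse are one fragment; branched subgraphs are
  not paths.
* **group** — whole aromatic ring systems, plus connected groups grown
  from non-aromatic heteroatoms and carbons multiply bonded to
  heteroatoms, each merged with its multiply-bonded neighbours. Plain
  aliphatic carbons never appear alone. This seed rule set is one explicit
  concretization of "functional groups based on heteroatoms and aromatic
  atoms"; it is isolated in one function so an alternative rule set can be
  swapped in.
* **bondbreak** — recursively breaks acyclic single bonds in all
  combinations of up to `max_breaks` simultaneous breaks (default 3),
  keeping every connected fragment with 2–15 heavy atoms. Exhaustive
  recursion is exponential, so a per-molecule cap (default 10,000
  fragments) truncates breadth-first — molecules small enough to
  enumerate completely are enumerated completely, and the truncation is
  deterministic and warned about.
* **catalogue** — matches a user-supplied SMARTS list (KRFP-style) and
  counts supports.

## Filtering and scoring

`apply_filter()` reduces a fragment table to qualified alerts in one of two
modes:

* **significance** (default): keep fragments with `n_sub >= 5`, precision
  `PR >= 0.75` and a one-sided binomial p-value, Bonferroni-corrected,
  `<= 0.05`. The test asks: if compounds containing this fragment were
  toxic at the dataset base rate, how likely is a positive count this
  extreme? The multiplicity `m` counts only fragments that reached the hit
  floor — fragments below it were never candidate hypotheses. Comparisons
  are inclusive at the thresholds.
* **support**: keep fragments with focus support (fraction of positives
  containing it) at least 10% and complement support (fraction of
  negatives) at most 5% — the filter semantics of closed-subgraph miners.

An empty result is a *reportable outcome* carrying a failure flag, never an
exception: whether a strategy can extract any qualifying alert from a
dataset at fixed thresholds is itself one of the quantities this toolkit
measures (`summarize_run()` tabulates it across endpoints).

Each retained alert is scored with precision `PR = N_sub_pos / N_sub`,
coverage `CR = N_sub / N_total`, and information gain

`IG = E(p) − P(t)·E(p|t) − P(t̄)·E(p|t̄)`,

where `E` is the binary entropy and `t` the event "compound contains the
fragment". Entropies are base-2 (bits) by default; the base only rescales
reported magnitudes and never changes a ranking, and is configurable. As
printed in some descriptions the second conditional appears with the class
index flipped; the implementation uses the standard entropy decomposition
(the positive-class probability on both branches), which is the only
reading that makes `IG` a non-negative gain bounded by the total entropy.
Negative floating-point dust clamps to zero. `rank_top_k()` orders by IG
with deterministic tie-breaking (higher PR, then higher CR, then pattern).

## Alert sets as classifiers

`sa_predict()` labels a compound positive when it contains at least one
alert — no vote counting, matching how alert collections are used in
practice. `repeated_holdout()` implements the evaluation protocol: five
random 8:2 splits (seeds 1–5 by default, recorded in the report), mining
and filtering on the training portion only, evaluation on both portions,
ACC/PPV/MCC per repetition and means over successful repetitions. Splits
use `floor(n × 0.8)` training compounds and are simple random by default
("randomly divided" says nothing about stratification); a `stratified`
flag exists for heavily imbalanced endpoints. PPV with no positive
predictions is reported missing (not zero) and excluded from means with a
count; an MCC with an empty marginal is 0.

## Consensus and reference comparison

To compare or merge alert sets from different strategies the patterns must
first be made comparable: `normalize_pattern()` strips atom maps and
H-count decorations and rewrites to canonical fragment SMILES;
`consolidate_patterns()` then treats substructure inclusion as identity,
keeping the *simpler* pattern — fewer heavy atoms, then fewer rings, then
lexicographic order. Consolidation sorts simplest-first and absorbs
superstructures in one pass, which provably reaches a fixed point and makes
the result independent of input order. `build_benchmark()` excludes
strategies with fewer than 20 alerts and intersects the consolidated sets
of the rest; intersection is by normalized equality (inclusion has already
been collapsed by consolidation, which resolves the ambiguity of whether
the intersection itself should also test inclusion). `pairwise_overlap()`
uses the same normalization so both analyses are consistent; its diagonal
holds each strategy's consolidated set size.

## QSAR integration

`featurize_ecfp()` computes an ECFP4-equivalent circular fingerprint with
the package's own fragment kernel: for every atom, the canonical identity
of its radius-0, -1 and -2 bond environments (element, aromaticity,
charge, hydrogen count, degree at radius 0; canonical subgraph identity
with hydrogen counts at higher radii) is hashed into a 2048-bit vector
(length configurable), and
`train_qsar()` fits a 500-tree probability random forest (`ranger`, fixed
seed, single-threaded for reproducibility). Forest size and fingerprint
length are conventional defaults for this model family. The integrated
rule is a strict conjunction: positive only when the forest score is
**strictly greater than** 0.5 *and* at least one alert is present. Two
consequences are exact and tested, not empirical: the integrated positive
set is the intersection of the two components' positive sets, and the
integrated false-positive count cannot exceed either component's.
`compare_models()` evaluates QSAR-only, alerts-only and integrated
predictions on one shared held-out split, mining and training on the same
training portion to avoid leakage.

## The synthetic-data generator

Real alert-mining studies rest on curated endpoint collections that cannot
ship with a package. The generator builds datasets with *known* ground
truth instead: molecules are assembled by attaching substituents to
drug-like scaffolds (about 20 ring systems, 15 benign substituents,
shipped in code) via single bonds at hydrogen-bearing positions, so every
SMILES is valid by construction. Designated toxic molecules receive a
toxicophore substituent (default: the nitro group); labels equal designated
carriage, then flip independently with the label-noise rate. Every
molecule's actual carriage is verified by substructure matching and
molecules whose carriage disagrees with their designation are regenerated,
so the truth table is exact. Generation is fully deterministic per seed,
and the class designation is drawn once per molecule — not per assembly
attempt — so the positive fraction is exactly binomial and not biased by
collision rates that differ between classes.

The reference condition is `n = 500`, positive fraction 0.4, one nitro
toxicophore, implant probability 1, decoy probability 0.10, label noise
0.05. Two parameters deserve explanation:

* **Label noise 0.05** represents assay irreproducibility at the scale
  reported for curated binary toxicity data.
* **Decoy probability 0.10** gives non-toxic molecules a 10% chance of
  carrying the toxicophore anyway (carriage without toxicity). Without
  decoys, the toxicophore's precision is `1 − noise` regardless of class
  balance and mining can never fail — unlike real endpoints, where a
  fragment is rarely mechanistically sufficient. With decoys the
  precision of a toxicophore alert scales as
  `PR ≈ f·p / (f·p + (1−f)·d)` for positive fraction `f`, implant rate
  `p` and decoy rate `d`: at `f = 0.4` this is ≈ 0.93 (well above the
  0.75 floor, so mining and recovery succeed), while at `f = 0.1` it is
  ≈ 0.67 (below the floor, so significance-mode mining raises its failure
  flag on most seeds — reproducing the behaviour of heavily imbalanced
  endpoints, where roughly one-in-ten positive rates make eligible
  substructures genuinely hard to find). Contexts lucky enough to escape
  decoys are small, and the Bonferroni-corrected binomial test removes
  them.

What the generator does *not* emulate: realistic property distributions,
activity cliffs, scaffold bias between classes, tautomerism, or
stereochemistry-dependent toxicity. Passing the recovery and tolerance
harnesses therefore shows the pipeline's statistics and bookkeeping are
correct, not that any particular real endpoint will yield alerts.

## Numerical and degenerate-input choices

* Exact binomial tails via `pbinom`; Bonferroni caps adjusted p-values
  at 1.
* IG clamps at 0; the IG implementation is property-tested to 1e-12
  against an oracle that physically partitions the records and recomputes
  entropies.
* A pattern used as a matching *target* resolves unwritten bonds by its
  endpoints (aromatic–aromatic means aromatic, otherwise single), so
  fragment-vs-fragment inclusion is well defined.
* Isolated atoms yield no circular fragments; single-atom group fragments
  (e.g. a hydroxyl oxygen) are legitimate patterns.
* Aromatic oxygen and sulfur contribute a lone pair, not a ring double
  bond, to the implicit-hydrogen model (the classic thiophene pitfall).
* All randomness flows through explicit seeds: generator specs, split
  seeds, forest seeds. Two runs with the same inputs produce byte-identical
  primary outputs.

## Problem sizes

The shipped validation harness uses datasets of 120–500 molecules, five
generator seeds per condition, five-repetition holdouts and ten-seed
integration comparisons — sizes at which every algorithm in the package
runs exhaustively (no sampling shortcuts) while the full suite stays
desk-scale. All counting statistics are exact at any size; only the
random-forest component and the generator's stochastic conditions are
sampled, and both are seed-pinned.

## Known limitations

* The SMILES/SMARTS subset excludes stereochemistry, isotope-specific
  matching and logical SMARTS operators; elements outside B, C, N, O, P,
  S and the halogens are rejected at parse time (records containing them
  are dropped and counted during loading).
* Closed-subgraph mining is not implemented; the focus/complement support
  *filter* of that method family is (support mode), applicable to any
  fragment table.
* Canonical identity is kernel-specific; alert files exchanged with other
  toolkits should be compared through `normalize_pattern()` /
  `consolidate_patterns()`, which tolerate notational variation but still
  assume the subset grammar.
* Per-occurrence counting (a fragment counted once per embedding) is
  deliberately out of scope; all statistics are per-molecule.
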