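# Session-level caches for expensive fixtures, so independent tests can
# share the same generated datasets and mined alert sets.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

# the reference synthetic condition at a given seed
synth_default <- function(seed, n = 500L) {
  cached(sprintf("synth_%d_%d", seed, n), {
    generate_synthetic(synthetic_spec(n_molecules = n, seed = seed))
  })
}

# small synthetic dataset for fast unit tests
synth_small <- function(seed = 11L, n = 120L, ...) {
  key <- paste0("small_", seed, "_", n, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, {
    generate_synthetic(synthetic_spec(n_molecules = n, seed = seed, ...))
  })
}

mined_default <- function(seed, strategy, n = 500L) {
  cached(sprintf("mined_%d_%s_%d", seed, strategy, n), {
    mine_alerts(synth_default(seed, n)$dataset, strategy)
  })
}

# in-package canonical SMILES of one molecule (kernel canonicalizer)
canonical_smiles_internal <- function(s) {
  samine:::canonical_molecule(samine:::parse_smiles(s))
}

# small hand-made dataset from explicit SMILES and labels (no OpenBabel wash)
tiny_dataset <- function(smiles, label, endpoint = "tiny") {
  toxicity_dataset(smiles, label, endpoint = endpoint, canonicalize = FALSE)
}

# alert_set from bare patterns (for consensus/reporting fixtures)
fake_alert_set <- function(patterns, strategy = "fake", endpoint = "fixture",
                           n_sub = 10L, pr = 0.9) {
  n <- length(patterns)
  df <- data.frame(
    pattern = patterns, origin = rep(strategy, n),
    n_sub = rep(as.integer(n_sub), n),
    n_sub_positive = rep(as.integer(round(n_sub * pr)), n),
    pr = rep(pr, n), cr = rep(0.1, n),
    ig = seq(0.5, 0.1, length.out = max(n, 1L))[seq_len(n)],
    p_value = rep(0.01, n), strategy = rep(strategy, n),
    stringsAsFactors = FALSE
  )
  samine:::new_alert_set(df, endpoint, strategy)
}
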