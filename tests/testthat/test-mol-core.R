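# The molecular-graph layer: SMILES parsing, canonical identity and
# substructure matching, cross-checked against OpenBabel.

MOL_POOL <- c(
  "CCO", "OCC", "c1ccccc1", "Nc1ccccc1", "c1ccc(N)cc1",
  "CC(=O)Nc1ccc(O)cc1", "O=[N+]([O-])c1ccccc1", "C1CO1", "c1cc[nH]c1",
  "c1ccsc1", "c1ccoc1", "c1ccc2ccccc2c1", "C1CCC2CCCCC2C1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CN1CCCC1c1cccnc1",
  "Clc1ccc(cc1)C(F)(F)F", "CSc1nc(N(C)C)cs1", "OCC1OC(O)C(O)C(O)C1O"
)

test_that("canonical form is invariant to the input spelling", {
  pairs <- list(
    c("CCO", "OCC"),
    c("Nc1ccccc1", "c1ccc(N)cc1"),
    c("C1CCC2CCCCC2C1", "C1CC2CCCCC2CC1"),
    c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O"),
    c("c1cc[nH]c1", "[nH]1cccc1"),
    c("CC(=O)Nc1ccc(O)cc1", "Oc1ccc(NC(C)=O)cc1")
  )
  for (p in pairs) {
    expect_identical(
      canonical_smiles_internal(p[1]), canonical_smiles_internal(p[2]),
      info = paste(p, collapse = " vs ")
    )
  }
})

test_that("canonical identity agrees with OpenBabel's on full molecules", {
  mine <- unname(vapply(MOL_POOL, canonical_smiles_internal, character(1)))
  ob <- canonical_smiles(MOL_POOL)
  # equal in-package canonical form <=> equal OpenBabel canonical form
  for (i in seq_along(MOL_POOL)) {
    for (j in seq_len(i - 1L)) {
      expect_identical(mine[i] == mine[j], ob[i] == ob[j],
                       info = paste(MOL_POOL[i], MOL_POOL[j]))
    }
  }
  # and every in-package canonical SMILES is readable by OpenBabel with the
  # same meaning
  expect_identical(canonical_smiles(mine), ob)
})

test_that("implicit hydrogen model matches aromatic heteroatom conventions", {
  g <- samine:::parse_smiles("c1ccsc1")
  expect_identical(g$hcount[g$elem == "S"], 0L)
  g <- samine:::parse_smiles("c1ccoc1")
  expect_identical(g$hcount[g$elem == "O"], 0L)
  g <- samine:::parse_smiles("c1cc[nH]c1")
  expect_identical(g$hcount[g$elem == "N"], 1L)
  g <- samine:::parse_smiles("c1ccncc1")
  expect_identical(g$hcount[g$elem == "N"], 0L)
  g <- samine:::parse_smiles("CCO")
  expect_identical(g$hcount, c(3L, 2L, 1L))
})

test_that("substructure matching agrees with OpenBabel SMARTS search", {
  patterns <- c("c1ccccc1", "NC=O", "C=O", "[OH]", "[NH2]", "CO", "CCl",
                "c[N+](=O)[O-]", "CC(C)C", "c1ccncc1", "C1CO1", "ccN")
  graphs <- lapply(MOL_POOL, samine:::parse_smiles)
  obmols <- ChemmineOB::forEachMol("SMILES", paste(MOL_POOL, collapse = "\n"),
                                   identity)
  for (p in patterns) {
    mine <- contains_pattern(p, graphs)
    ob <- ChemmineOB::smartsSearch_OB(obmols, p, uniqueMatches = TRUE) > 0
    expect_identical(mine, ob, info = p)
  }
})

test_that("matching ignores attachment context but honours constraints", {
  apap <- samine:::parse_smiles("CC(=O)Nc1ccc(O)cc1")
  expect_true(contains_pattern("ccc", apap))       # partial aromatic chain
  expect_true(contains_pattern("[OH]", apap))      # phenol O carries one H
  expect_false(contains_pattern("[NH2]", apap))    # amide N has one H, not two
  expect_false(contains_pattern("O=S", apap))
  # default bond matches single or aromatic, explicit '=' does not
  expect_true(contains_pattern("cc", samine:::parse_smiles("c1ccccc1")))
  expect_false(contains_pattern("C=C", samine:::parse_smiles("CC")))
})

test_that("unsupported SMARTS constructs are rejected with a clear error", {
  expect_error(samine:::compile_pattern("[!C]"), "bracket-atom|element")
  expect_error(samine:::compile_pattern("not_smarts"), "parse error")
  expect_error(samine:::compile_pattern("CC.CC"), "disconnected")
  expect_error(samine:::parse_smiles("C(C"), "unmatched")
  expect_error(samine:::parse_smiles("C1CC"), "unclosed ring")
})

test_that("fragment canonical form is stable under graph relabelling", {
  set.seed(42)
  for (smi in MOL_POOL[1:10]) {
    g <- samine:::parse_smiles(smi)
    frags <- enumerate_circular(g, 1, 3)
    # reparse each fragment and re-canonicalize: must be a fixed point
    for (f in frags) {
      g2 <- samine:::parse_smiles(f, query = TRUE)
      expect_identical(samine:::canonical_fragment(g2), f, info = f)
    }
  }
})
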