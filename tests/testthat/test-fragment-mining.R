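# Fragment enumeration strategies and dataset-level support counting.

test_that("circular environments match hand enumeration on small molecules", {
  expect_length(enumerate_circular("c1ccccc1", 1, 1), 1L)  # all centres alike
  expect_length(enumerate_circular("CCO", 1, 1), 3L)       # CC, CCO, CO
  expect_setequal(enumerate_circular("CCO", 1, 1), c("CC", "CCO", "CO"))
  expect_length(enumerate_circular("C", 1, 4), 0L)         # no bonded shell
})

test_that("circular fragments at radius r nest inside radius r + 1", {
  g <- samine:::parse_smiles("CC(=O)Nc1ccc(O)cc1")
  for (centre in seq_len(samine:::n_atoms(g))) {
    d <- samine:::bond_distances(g, centre)
    for (r in 1:3) {
      inner <- which(!is.na(d) & d <= r)
      outer <- which(!is.na(d) & d <= r + 1)
      if (length(inner) < 2L) next
      fi <- samine:::canonical_fragment(samine:::subgraph(g, inner))
      fo <- samine:::canonical_fragment(samine:::subgraph(g, outer))
      expect_true(contains_pattern(fi, samine:::parse_smiles(fo, query = TRUE)),
                  info = sprintf("centre %d radius %d", centre, r))
    }
  }
})

test_that("path enumeration matches manual path listings", {
  expect_setequal(enumerate_paths("CCO", 1, 2), c("CC", "CO", "CCO"))
  expect_length(enumerate_paths("c1ccccc1", 1, 1), 1L)   # aromatic c:c
  # heteroatom chain: all simple paths are distinct, count = sum(n - k)
  expect_length(enumerate_paths("FCNOS", 1, 4), 4 + 3 + 2 + 1)
  expect_error(enumerate_paths("C", 1, 2), NA)  # degenerate: no paths
  expect_length(enumerate_paths("C", 1, 2), 0L)
})

test_that("functional-group mining follows the seed rules", {
  expect_length(enumerate_groups("CCCCCC"), 0L)  # no heteroatom, no aromatics
  apap <- enumerate_groups("CC(=O)Nc1ccc(O)cc1")
  expect_setequal(apap, c("C(N)=O", "c1ccccc1", "O"))
  expect_setequal(enumerate_groups("Oc1ccccc1"), c("c1ccccc1", "O"))
  # nitro group comes out whole (charged seeds merged with =O neighbour)
  expect_true(any(grepl("N", enumerate_groups("O=[N+]([O-])CC"))))
})

test_that("bond breaking enumerates all fragments within the atom bounds", {
  expect_setequal(enumerate_bondbreak("CCO"), c("CC", "CO", "CCO"))
  expect_identical(enumerate_bondbreak("c1ccccc1"), "c1ccccc1")  # nothing to break
  expect_identical(enumerate_bondbreak("CCO", min_atoms = 3), "CCO")
  # cap truncation warns and returns a deterministic subset
  expect_warning(
    small <- enumerate_bondbreak("CCCCCCCCCC", cap = 5),
    "cap"
  )
  expect_length(small, 5L)
})

test_that("every emitted fragment matches its source molecule", {
  synth <- synth_small()
  idx <- seq(1, 120, by = 10)
  for (i in idx) {
    g <- synth$dataset$graphs[[i]]
    frags <- c(enumerate_circular(g, 1, 3), enumerate_paths(g, 1, 4),
               enumerate_groups(g), enumerate_bondbreak(g, max_breaks = 2))
    for (f in unique(frags)) {
      expect_true(contains_pattern(f, g),
                  info = sprintf("%s in %s", f, synth$dataset$records$smiles[i]))
    }
  }
})

test_that("support counts aggregate per molecule with dedup", {
  # benzene has one distinct radius-1 environment; hexane has two (terminal
  # and interior carbon)
  ds <- tiny_dataset(c("c1ccccc1", "CCCCCC"), c(1, 0))
  tab <- build_fragment_table(ds, "circular", list(r_min = 1, r_max = 1))
  expect_setequal(tab$table$pattern, c("ccc", "CC", "CCC"))
  expect_true(all(tab$table$n_sub == 1L))
  expect_identical(sum(tab$table$n_sub_positive), 1L)

  # a fragment shared by several molecules is counted once per molecule
  ds2 <- tiny_dataset(c("CCO", "CCCO", "OCCN"), c(1, 1, 0))
  tab2 <- build_fragment_table(ds2, "path", list(l_min = 1, l_max = 1))
  co <- tab2$table[tab2$table$pattern == "CO", ]
  expect_identical(co$n_sub, 3L)
  expect_identical(co$n_sub_positive, 2L)
})

test_that("adding a molecule never decreases any fragment's support", {
  synth <- synth_small()
  ds_small <- samine:::dataset_subset(synth$dataset, 1:30)
  ds_big <- samine:::dataset_subset(synth$dataset, 1:31)
  t1 <- build_fragment_table(ds_small, "circular", list(r_max = 2))$table
  t2 <- build_fragment_table(ds_big, "circular", list(r_max = 2))$table
  common <- intersect(t1$pattern, t2$pattern)
  expect_identical(sort(t1$pattern), sort(common))  # no fragment disappears
  m1 <- t1$n_sub[match(common, t1$pattern)]
  m2 <- t2$n_sub[match(common, t2$pattern)]
  expect_true(all(m2 >= m1))
})

test_that("catalogue matching counts supports per pattern", {
  ds <- tiny_dataset(c("CCO", "CC"), c(1, 0))
  cat1 <- pattern_catalogue(c("[OH]", "C=O"))
  tab <- match_catalogue(ds, cat1)
  expect_identical(tab$table$pattern, "[OH]")  # unmatched patterns absent
  expect_identical(tab$table$n_sub, 1L)
  expect_identical(tab$table$n_sub_positive, 1L)

  ds10 <- tiny_dataset(sprintf("C%sO", strrep("C", 1:10)),
                       c(rep(1, 4), rep(0, 6)))
  tab10 <- match_catalogue(ds10, pattern_catalogue("CO"))
  expect_identical(tab10$table$n_sub, 10L)
  expect_identical(tab10$table$n_sub_positive, 4L)
})

test_that("build_fragment_table is deterministic and validates its inputs", {
  synth <- synth_small()
  ds <- samine:::dataset_subset(synth$dataset, 1:20)
  a <- build_fragment_table(ds, "circular")
  b <- build_fragment_table(ds, "circular")
  expect_identical(a$table, b$table)
  expect_error(build_fragment_table(ds, "catalogue"), "catalogue")
  expect_error(build_fragment_table(ds, "unknown"))
})
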