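# Consensus benchmark construction: normalization, inclusion-based
# consolidation, strategy intersection, pairwise overlap and reference
# comparison.

test_that("normalization strips decorations and is idempotent", {
  aniline <- normalize_pattern("Nc1ccccc1")$canonical
  expect_identical(normalize_pattern("[cH]1[cH][cH][cH][cH]c1[NH2]")$canonical,
                   aniline)
  expect_identical(normalize_pattern("[C:1][O:2]")$canonical,
                   normalize_pattern("CO")$canonical)
  expect_identical(normalize_pattern(aniline)$canonical, aniline)
  expect_identical(normalize_pattern("c1ccccc1")$heavy_atoms, 6L)
  expect_identical(normalize_pattern("c1ccccc1")$rings, 1L)
})

test_that("consolidation collapses inclusion pairs to the simpler pattern", {
  out <- consolidate_patterns(c("Oc1ccccc1", "c1ccccc1"),
                              sources = list("a", "b"))
  expect_identical(out$canonical, "c1ccccc1")
  expect_identical(out$sources[[1]], c("a", "b"))

  disjoint <- consolidate_patterns(c("CCO", "c1ccccc1"))
  expect_identical(nrow(disjoint), 2L)

  chain <- consolidate_patterns(c("CCO", "CCOC", "CCOCC"))
  expect_identical(chain$canonical, "CCO")

  # order independence
  set.seed(5)
  pats <- c("Oc1ccccc1", "c1ccccc1", "CCO", "CCOC", "Nc1ccccc1")
  a <- consolidate_patterns(pats)
  b <- consolidate_patterns(sample(pats))
  expect_identical(a$canonical, b$canonical)
})

test_that("benchmark excludes small sets and intersects the rest", {
  # non-including patterns so consolidation leaves them alone
  pool <- c("CF", "CCl", "CBr", "CI", "CN", "CO", "CS", "C=O", "C=C",
            "C#N", "NO", "NN", "OO", "CC")
  sets <- list(
    tiny = fake_alert_set(pool[1:2], strategy = "tiny"),
    big1 = fake_alert_set(pool[1:6], strategy = "big1"),
    big2 = fake_alert_set(pool[3:8], strategy = "big2")
  )
  cs <- build_benchmark(sets, min_set_size = 3L)
  expect_setequal(cs$included_strategies, c("big1", "big2"))
  expect_setequal(cs$benchmark$canonical,
                  vapply(pool[3:6], function(p) normalize_pattern(p)$canonical,
                         character(1)))
  expect_true(all(vapply(cs$benchmark$sources, function(s)
    setequal(s, c("big1", "big2")), logical(1))))

  # empty intersection is a valid outcome, not an error
  cs2 <- build_benchmark(list(a = fake_alert_set(pool[1:3], strategy = "a"),
                              b = fake_alert_set(pool[4:6], strategy = "b")),
                         min_set_size = 3L)
  expect_identical(nrow(cs2$benchmark), 0L)
  expect_null(cs2$flag)

  # all strategies excluded sets the explanatory flag
  cs3 <- build_benchmark(list(a = fake_alert_set(pool[1], strategy = "a")),
                         min_set_size = 20L)
  expect_identical(nrow(cs3$benchmark), 0L)
  expect_match(cs3$flag, "min_set_size")
})

test_that("annotation variants of one alert family consolidate into the benchmark", {
  sets <- list(
    s1 = fake_alert_set(c("[cH]1[cH][cH][cH][cH]c1[N+](=O)[O-]", "CF", "CCl"),
                        strategy = "s1"),
    s2 = fake_alert_set(c("O=[N+]([O-])c1ccccc1", "CF", "CBr"),
                        strategy = "s2"),
    s3 = fake_alert_set(c("c1ccc(cc1)[N+](=O)[O-]", "CF", "CI"),
                        strategy = "s3")
  )
  cs <- build_benchmark(sets, min_set_size = 3L)
  nitrobenzene <- normalize_pattern("O=[N+]([O-])c1ccccc1")$canonical
  expect_true(nitrobenzene %in% cs$benchmark$canonical)
  expect_true(normalize_pattern("CF")$canonical %in% cs$benchmark$canonical)
})

test_that("pairwise overlap is symmetric with set sizes on the diagonal", {
  sets <- list(
    a = fake_alert_set(c("CF", "CCl", "CBr"), strategy = "a"),
    b = fake_alert_set(c("CF", "CCl", "CBr"), strategy = "b"),
    c = fake_alert_set(c("CI", "CN"), strategy = "c")
  )
  m <- pairwise_overlap(sets)
  expect_identical(m["a", "b"], 3L)
  expect_identical(m["a", "c"], 0L)
  expect_identical(m["b", "c"], 0L)
  expect_identical(diag(m), c(a = 3L, b = 3L, c = 2L))
  expect_identical(m, t(m))

  # hand-counted three-set fixture with partial overlaps
  sets2 <- list(
    x = fake_alert_set(c("CF", "CCl", "C=O"), strategy = "x"),
    y = fake_alert_set(c("CCl", "C=O", "CI"), strategy = "y"),
    z = fake_alert_set(c("C=O", "NN"), strategy = "z")
  )
  m2 <- pairwise_overlap(sets2)
  expect_identical(m2["x", "y"], 2L)
  expect_identical(m2["x", "z"], 1L)
  expect_identical(m2["y", "z"], 1L)
})

test_that("reference comparison classifies equality and inclusion", {
  alerts <- fake_alert_set(c("Nc1ccccc1", "CCO", "C1CO1"))
  # all top alerts present verbatim
  ref_all <- pattern_catalogue(c("Nc1ccccc1", "CCO", "C1CO1"))
  res <- compare_to_reference(alerts, ref_all, k = 3)
  expect_identical(res$overlap, 3L)
  expect_true(all(res$detail$relation == "equal"))

  # aniline alert overlaps an aromatic-amine reference via inclusion
  ref_amine <- pattern_catalogue("cN")
  res2 <- compare_to_reference(fake_alert_set("Nc1ccccc1"), ref_amine, k = 10)
  expect_identical(res2$overlap, 1L)
  expect_identical(res2$detail$relation, "contains")

  # empty reference: zero overlap
  res3 <- compare_to_reference(alerts, pattern_catalogue(character(0)), k = 3)
  expect_identical(res3$overlap, 0L)
})
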