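# Statistical qualification: binomial significance, Bonferroni behaviour,
# threshold semantics and the failure-flag contract.

make_table <- function(df, n_total, n_positive, strategy = "circular") {
  df$origin <- rep(strategy, nrow(df))
  ds <- list(endpoint = "fixture", n_total = as.integer(n_total),
             n_positive = as.integer(n_positive))
  samine:::new_fragment_table(df, ds, strategy)
}

test_that("fragment p-values equal exact binomial tails", {
  expect_equal(fragment_pvalue(5, 5, 10, 5), 0.5^5, tolerance = 1e-15)
  expect_equal(fragment_pvalue(7, 0, 10, 5), 1.0)
  expect_equal(fragment_pvalue(10, 8, 100, 30), ref_binom_tail(8, 10, 0.3),
               tolerance = 1e-12)
  expect_error(fragment_pvalue(5, 5, 0, 0), "n_total")
})

test_that("significance mode enforces hits, precision and adjusted p", {
  tab <- make_table(data.frame(
    pattern = c("A", "B", "C"),
    n_sub = c(4L, 20L, 20L),
    n_sub_positive = c(4L, 20L, 12L)
  ), n_total = 40, n_positive = 20)
  res <- apply_filter(tab, filter_config())
  # A fails min_hits regardless of perfect precision; C fails precision
  expect_identical(res$alerts$pattern, "B")
  expect_equal(res$alerts$p_value, min(1, 0.5^20 * 2), tolerance = 1e-12)
  expect_null(res$failure)
})

test_that("disabling Bonferroni never shrinks the retained set", {
  set.seed(7)
  for (rep in 1:20) {
    n_total <- 100L; n_positive <- 40L
    k <- 30L
    n_sub <- sample(1:60, k, replace = TRUE)
    n_pos <- vapply(n_sub, function(s) rbinom(1, s, 0.55), integer(1))
    tab <- make_table(data.frame(pattern = sprintf("p%02d", 1:k),
                                 n_sub = n_sub, n_sub_positive = n_pos),
                      n_total, n_positive)
    with_bf <- apply_filter(tab, filter_config(bonferroni = TRUE))
    without <- apply_filter(tab, filter_config(bonferroni = FALSE))
    expect_true(all(with_bf$alerts$pattern %in% without$alerts$pattern))
    # raising thresholds never grows the set
    stricter <- apply_filter(tab, filter_config(min_hits = 10,
                                                min_precision = 0.9,
                                                alpha = 0.01))
    expect_true(all(stricter$alerts$pattern %in% with_bf$alerts$pattern))
    # every retained alert satisfies every active threshold
    if (n_alerts(with_bf) > 0) {
      expect_true(all(with_bf$alerts$n_sub >= 5))
      expect_true(all(with_bf$alerts$pr >= 0.75))
      expect_true(all(with_bf$alerts$p_value <= 0.05))
    }
  }
})

test_that("support mode reproduces brute-force focus/complement counts", {
  set.seed(13)
  n_total <- 80L; n_positive <- 30L
  k <- 25L
  n_sub <- sample(1:50, k, replace = TRUE)
  n_pos <- vapply(n_sub, function(s)
    min(rbinom(1, s, 0.5), n_positive), integer(1))
  tab <- make_table(data.frame(pattern = sprintf("p%02d", 1:k),
                               n_sub = n_sub, n_sub_positive = n_pos),
                    n_total, n_positive)
  cfg <- filter_config(mode = "support")
  res <- apply_filter(tab, cfg)
  brute <- tab$table$pattern[
    tab$table$n_sub_positive / n_positive >= cfg$focus_support_min &
      (tab$table$n_sub - tab$table$n_sub_positive) / (n_total - n_positive) <=
        cfg$complement_support_max
  ]
  expect_setequal(res$alerts$pattern, brute)
})

test_that("an empty qualification is a flagged outcome, never an error", {
  tab <- make_table(data.frame(pattern = "weak", n_sub = 20L,
                               n_sub_positive = 10L),
                    n_total = 100, n_positive = 50)
  res <- apply_filter(tab, filter_config())
  expect_identical(n_alerts(res), 0L)
  expect_true(res$failure$failed)
  expect_match(res$failure$reason, "significance")

  empty <- make_table(data.frame(pattern = character(0),
                                 n_sub = integer(0),
                                 n_sub_positive = integer(0)),
                      n_total = 10, n_positive = 5)
  expect_true(apply_filter(empty, filter_config())$failure$failed)
})

test_that("external screening uses inclusive bounds and preserves order", {
  a <- fake_alert_set(c("CC", "CO", "CN"))
  a$alerts$n_sub <- c(5L, 100L, 4L)
  a$alerts$n_sub_positive <- c(4L, 74L, 4L)   # PR 0.80, 0.74, 1.00
  s <- screen_external(a)
  expect_identical(s$alerts$pattern, "CC")    # 0.74 removed, n_sub 4 removed
  boundary <- fake_alert_set("CC")
  boundary$alerts$n_sub <- 5L
  boundary$alerts$n_sub_positive <- 4L        # PR exactly 0.80 >= 0.75, hits 5
  expect_identical(n_alerts(screen_external(boundary)), 1L)
  empty <- screen_external(fake_alert_set(character(0)))
  expect_identical(n_alerts(empty), 0L)
  expect_null(empty$failure)
})

test_that("catalogue-style frequency floor applies as an extra threshold", {
  tab <- make_table(data.frame(pattern = c("rare", "common"),
                               n_sub = c(5L, 50L),
                               n_sub_positive = c(5L, 50L)),
                    n_total = 2000, n_positive = 500)
  res <- apply_filter(tab, filter_config(freq_min = 0.005))
  expect_identical(res$alerts$pattern, "common")
})
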