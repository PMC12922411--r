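# Alert sets as classifiers: prediction, confusion counts, metric
# identities and the repeated-holdout protocol.

test_that("prediction is alert presence, with no vote counting", {
  ds <- tiny_dataset(c("CCO", "CCN", "c1ccccc1O"), c(1, 0, 1))
  alerts <- fake_alert_set(c("[OH]", "c1ccccc1"))
  expect_identical(sa_predict(alerts, ds), c(1L, 0L, 1L))  # 2 hits still 1
  empty <- fake_alert_set(character(0))
  expect_identical(sa_predict(empty, ds), c(0L, 0L, 0L))
})

test_that("confusion counts match hand tabulation on a fixed fixture", {
  ds <- tiny_dataset(c("CCO", "CCN", "OCCC", "CC"), c(1, 1, 0, 0))
  alerts <- fake_alert_set("[OH]")
  cc <- sa_confusion(alerts, ds)
  expect_identical(cc, confusion_counts(tp = 1, fp = 1, tn = 1, fn = 1))
  empty <- sa_confusion(fake_alert_set(character(0)), ds)
  expect_identical(empty, confusion_counts(tp = 0, fp = 0, tn = 2, fn = 2))
})

test_that("metric landmarks and degenerate conventions hold", {
  m <- sa_metrics(confusion_counts(25, 25, 25, 25))
  expect_equal(m$acc, 0.5); expect_equal(m$ppv, 0.5); expect_equal(m$mcc, 0)
  m <- sa_metrics(confusion_counts(50, 0, 50, 0))
  expect_equal(m$acc, 1); expect_equal(m$ppv, 1); expect_equal(m$mcc, 1)
  m <- sa_metrics(confusion_counts(40, 10, 35, 15))
  expect_equal(m$acc, 0.75)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$mcc, (40 * 35 - 10 * 15) / sqrt(50 * 55 * 45 * 50),
               tolerance = 1e-15)
  # no positive prediction: PPV is missing, not zero; MCC defined as 0
  m <- sa_metrics(confusion_counts(0, 0, 30, 10))
  expect_true(is.na(m$ppv))
  expect_identical(m$mcc, 0)
})

test_that("metrics agree with vector-based recomputation on random counts", {
  set.seed(33)
  for (i in 1:200) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    total <- cc$tp + cc$fp + cc$tn + cc$fn
    if (total == 0) next
    pred <- c(rep(1, cc$tp), rep(1, cc$fp), rep(0, cc$tn), rep(0, cc$fn))
    obs <- c(rep(1, cc$tp), rep(0, cc$fp), rep(0, cc$tn), rep(1, cc$fn))
    m <- sa_metrics(cc)
    r <- ref_metrics(pred, obs)
    expect_lt(abs(m$acc - r$acc), 1e-12)
    expect_identical(is.na(m$ppv), is.na(r$ppv))
    if (!is.na(m$ppv)) expect_lt(abs(m$ppv - r$ppv), 1e-12)
    expect_lt(abs(m$mcc - r$mcc), 1e-12)
  }
})

test_that("holdout splits honour the floor rule, disjointness and the seed", {
  sp <- holdout_split(100, train_frac = 0.8, seed = 3)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(holdout_split(100, seed = 3), sp)
  expect_false(identical(holdout_split(100, seed = 4)$train, sp$train))
  # odd sizes floor the training share
  expect_length(holdout_split(103, seed = 1)$train, 82L)
  # stratified splits preserve the floor rule per class
  labs <- rep(c(0L, 1L), c(90, 10))
  st <- holdout_split(100, labs, seed = 5, stratified = TRUE)
  expect_identical(sum(labs[st$train] == 1L), 8L)
})

test_that("repeated holdout mines on the training portion only", {
  synth <- synth_small(seed = 21, n = 150)
  rep1 <- repeated_holdout(synth$dataset, "group", seeds = 1:2)
  expect_identical(nrow(rep1$per_rep), 4L)
  # no leakage: re-splitting with the same seed and re-mining reproduces
  # the reported training confusion exactly
  sp <- holdout_split(synth$dataset$n_total, seed = 1)
  train <- samine:::dataset_subset(synth$dataset, sp$train)
  alerts <- mine_alerts(train, "group")
  cc <- sa_confusion(alerts, train)
  row <- rep1$per_rep[rep1$per_rep$seed == 1 & rep1$per_rep$set == "train", ]
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn),
                   c(row$tp, row$fp, row$tn, row$fn))
  # determinism of the full protocol
  rep2 <- repeated_holdout(synth$dataset, "group", seeds = 1:2)
  expect_identical(rep1$per_rep, rep2$per_rep)
  expect_identical(rep1$means, rep2$means)
})

test_that("a noise-free perfectly-predictive toxicophore yields test ACC 1", {
  clean <- generate_synthetic(synthetic_spec(
    n_molecules = 150, label_noise = 0, decoy_prob = 0, seed = 31))
  rep1 <- repeated_holdout(clean$dataset, "group", seeds = 1:3)
  test_rows <- rep1$per_rep[rep1$per_rep$set == "test" & !rep1$per_rep$failed, ]
  expect_gt(nrow(test_rows), 0L)
  expect_true(all(test_rows$acc > 0.97))
  expect_gt(rep1$means$test$mcc, 0.9)
})

test_that("failed repetitions are flagged, excluded from means and warned", {
  imb <- generate_synthetic(synthetic_spec(
    n_molecules = 150, positive_fraction = 0.08, decoy_prob = 0.3, seed = 41))
  expect_warning(
    rep1 <- repeated_holdout(imb$dataset, "group", seeds = 1:2),
    "failed"
  )
  expect_true(any(rep1$per_rep$failed))
  if (rep1$all_failed) {
    expect_identical(rep1$means$test$n_reps, 0L)
  } else {
    expect_identical(rep1$means$test$n_reps,
                     sum(!rep1$per_rep$failed & rep1$per_rep$set == "test"))
  }
})
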