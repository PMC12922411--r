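# An alert set as a binary classifier: a compound is predicted toxic when
# it contains at least one alert. Evaluation follows a repeated random
# 8:2 holdout protocol with ACC, PPV and MCC.

#' Predict toxicity labels from an alert set
#'
#' A compound is predicted positive when it contains at least one of the
#' alert patterns (no vote counting). An empty alert set predicts 0 for
#' every compound.
#'
#' @param alerts an `alert_set`
#' @param dataset a `toxicity_dataset` (or a list of molgraphs)
#' @return integer vector of predicted labels
#' @export
sa_predict <- function(alerts, dataset) {
  stopifnot(inherits(alerts, "alert_set"))
  graphs <- if (inherits(dataset, "toxicity_dataset")) dataset$graphs
  else dataset
  hit <- rep(FALSE, length(graphs))
  for (p in alerts$alerts$pattern) {
    todo <- which(!hit)
    if (length(todo) == 0L) break
    hit[todo] <- contains_pattern(p, graphs[todo])
  }
  as.integer(hit)
}

#' Confusion counts of an alert set on a dataset
#'
#' @param alerts an `alert_set`
#' @param dataset a `toxicity_dataset`
#' @return a `confusion_counts` list with tp, fp, tn, fn
#' @export
sa_confusion <- function(alerts, dataset) {
  stopifnot(inherits(dataset, "toxicity_dataset"), dataset$n_total > 0L)
  pred <- sa_predict(alerts, dataset)
  obs <- dataset$records$label
  confusion_counts(tp = sum(pred == 1L & obs == 1L),
                   fp = sum(pred == 1L & obs == 0L),
                   tn = sum(pred == 0L & obs == 0L),
                   fn = sum(pred == 0L & obs == 1L))
}

#' Construct confusion counts
#' @param tp,fp,tn,fn non-negative counts
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' ACC = (TP+TN)/total; PPV = TP/(TP+FP), reported as `NA` when no positive
#' prediction was made (undefined, not zero); MCC with the usual product
#' denominator, defined as 0 when any marginal is empty.
#'
#' @param counts a `confusion_counts`
#' @return list with `acc`, `ppv`, `mcc`
#' @export
sa_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0L) stop("empty confusion counts")
  acc <- (tp + tn) / total
  ppv <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  list(acc = acc, ppv = ppv, mcc = mcc)
}

#' Random 8:2 train/test split indices
#'
#' Training size is `floor(n * train_frac)`; the remainder is the test set.
#' With `stratified = TRUE` the floor-rule is applied within each label
#' class (useful for heavily imbalanced endpoints).
#'
#' @param n number of records
#' @param labels integer labels (needed for stratified splits)
#' @param train_frac training fraction (default 0.8)
#' @param seed RNG seed
#' @param stratified split within label classes
#' @return list with integer index vectors `train` and `test`
#' @export
holdout_split <- function(n, labels = NULL, train_frac = 0.8, seed = 1L,
                          stratified = FALSE) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  if (stratified) {
    stopifnot(!is.null(labels), length(labels) == n)
    train <- integer(0)
    for (lv in sort(unique(labels))) {
      idx <- which(labels == lv)
      train <- c(train, sort(sample(idx, floor(length(idx) * train_frac))))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, floor(n * train_frac)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Repeated-holdout evaluation of a mining strategy
#'
#' For each seed the dataset is split 8:2, alerts are mined and filtered on
#' the training portion only, and the resulting alert set is evaluated on
#' both portions. Repetitions in which mining fails (no qualifying alert)
#' are recorded as failures and excluded from the means, with a warning.
#'
#' @param dataset a `toxicity_dataset`
#' @param strategy mining strategy (see [build_fragment_table()])
#' @param params strategy parameters
#' @param config a [filter_config()]
#' @param train_frac training fraction (default 0.8)
#' @param seeds one seed per repetition (default 1:5)
#' @param stratified use stratified splits
#' @return an `evaluation_report`: per-repetition rows (`set` = train/test)
#'   with confusion counts and metrics, plus means over successful
#'   repetitions
#' @export
repeated_holdout <- function(dataset, strategy = MINING_STRATEGIES,
                             params = list(), config = filter_config(),
                             train_frac = 0.8, seeds = 1:5,
                             stratified = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(dataset, "toxicity_dataset"))
  rows <- list()
  failures <- integer(0)
  for (seed in seeds) {
    sp <- holdout_split(dataset$n_total, dataset$records$label, train_frac,
                        seed, stratified)
    train <- dataset_subset(dataset, sp$train)
    test <- dataset_subset(dataset, sp$test)
    alerts <- mine_alerts(train, strategy, params, config)
    if (isTRUE(alerts$failure$failed)) {
      failures <- c(failures, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, set = c("train", "test"), failed = TRUE, n_alerts = 0L,
        tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
        fn = NA_integer_, acc = NA_real_, ppv = NA_real_, mcc = NA_real_,
        stringsAsFactors = FALSE
      )
      next
    }
    eval_part <- function(ds, which) {
      cc <- sa_confusion(alerts, ds)
      m <- sa_metrics(cc)
      data.frame(seed = seed, set = which, failed = FALSE,
                 n_alerts = n_alerts(alerts),
                 tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                 acc = m$acc, ppv = m$ppv, mcc = m$mcc,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(eval_part(train, "train"),
                                       eval_part(test, "test"))
  }
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL
  if (length(failures) > 0L)
    warning(sprintf("mining failed in %d of %d repetitions (seed %s)",
                    length(failures), length(seeds),
                    paste(failures, collapse = ", ")))
  ok <- per_rep[!per_rep$failed, , drop = FALSE]
  mean_block <- function(set) {
    part <- ok[ok$set == set, , drop = FALSE]
    if (nrow(part) == 0L)
      return(list(acc = NA_real_, ppv = NA_real_, mcc = NA_real_,
                  n_reps = 0L, ppv_missing = 0L))
    list(acc = mean(part$acc),
         ppv = if (all(is.na(part$ppv))) NA_real_ else
           mean(part$ppv, na.rm = TRUE),
         mcc = mean(part$mcc),
         n_reps = nrow(part),
         ppv_missing = sum(is.na(part$ppv)))
  }
  structure(
    list(endpoint = dataset$endpoint, strategy = strategy,
         per_rep = per_rep,
         means = list(train = mean_block("train"), test = mean_block("test")),
         seeds = seeds, train_frac = train_frac,
         failed_seeds = failures,
         all_failed = length(failures) == length(seeds)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s/%s: %d repetitions (%d failed)\n",
              x$endpoint, x$strategy, length(x$seeds), length(x$failed_seeds)))
  for (set in c("train", "test")) {
    m <- x$means[[set]]
    cat(sprintf("  %s means: ACC=%.3f PPV=%.3f MCC=%.3f (n=%d)\n",
                set, m$acc, m$ppv, m$mcc, m$n_reps))
  }
  invisible(x)
}
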