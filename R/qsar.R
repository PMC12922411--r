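# Fingerprint-based random-forest toxicity model and the integrated
# decision rule: predict toxic only when the model score exceeds the
# threshold AND the compound carries at least one structural alert.

# deterministic polynomial string hash into [0, n_bits)
hash_to_bit <- function(keys, n_bits) {
  vapply(keys, function(k) {
    bytes <- utf8ToInt(k)
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    as.integer(h %% n_bits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Circular fingerprints (ECFP4-equivalent) for a set of molecules
#'
#' For every atom, the canonical identity of its bond-radius 0, 1 and 2
#' environments (including hydrogen counts, as in ECFP atom invariants) is
#' hashed into a fixed-length bit vector. Radius 2 environments make the
#' result the functional equivalent of a folded ECFP4 fingerprint.
#' Deterministic per molecule.
#'
#' @param smiles character vector of SMILES
#' @param n_bits fingerprint length (default 2048)
#' @param radius maximum environment radius in bonds (default 2)
#' @return 0/1 integer matrix, one row per molecule
#' @export
featurize_ecfp <- function(smiles, n_bits = 2048L, radius = 2L) {
  stopifnot(length(smiles) >= 1L, n_bits >= 64L, radius >= 1L)
  out <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(smiles)) {
    g <- parse_smiles(smiles[i])
    keys <- paste0("a0|", g$elem, "|", as.integer(g$arom), "|", g$charge,
                   "|", g$hcount, "|", lengths(g$adj))
    for (centre in seq_len(n_atoms(g))) {
      d <- bond_distances(g, centre)
      for (r in seq_len(radius)) {
        atoms <- which(!is.na(d) & d <= r)
        if (length(atoms) < 2L) next
        keys <- c(keys, paste0("e", r, "|",
                               canon_key(subgraph(g, atoms), use_h = TRUE)))
      }
    }
    out[i, unique(hash_to_bit(unique(keys), n_bits)) + 1L] <- 1L
  }
  out
}

#' Train a random-forest toxicity model on fingerprints
#'
#' @param dataset a `toxicity_dataset` with both classes present
#' @param seed RNG seed for the forest
#' @param num_trees forest size (default 500)
#' @param n_bits fingerprint length (default 2048)
#' @return a `qsar_model`
#' @export
train_qsar <- function(dataset, seed = 1L, num_trees = 500L,
                       n_bits = 2048L) {
  stopifnot(inherits(dataset, "toxicity_dataset"))
  y <- dataset$records$label
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  x <- featurize_ecfp(dataset$records$smiles, n_bits)
  colnames(x) <- sprintf("b%04d", seq_len(ncol(x)))
  fit <- ranger::ranger(
    x = x, y = factor(y, levels = c(0L, 1L)),
    num.trees = num_trees, probability = TRUE, seed = seed,
    num.threads = 1L
  )
  structure(list(fit = fit, n_bits = n_bits, seed = seed,
                 num_trees = num_trees),
            class = "qsar_model")
}

#' Toxicity scores from a QSAR model
#'
#' @param model a `qsar_model`
#' @param dataset a `toxicity_dataset` or character vector of SMILES
#' @return numeric scores in `[0, 1]` (probability of the toxic class)
#' @export
qsar_score <- function(model, dataset) {
  stopifnot(inherits(model, "qsar_model"))
  smiles <- if (inherits(dataset, "toxicity_dataset"))
    dataset$records$smiles else dataset
  x <- featurize_ecfp(smiles, model$n_bits)
  colnames(x) <- sprintf("b%04d", seq_len(ncol(x)))
  predict(model$fit, data = x, num.threads = 1L)$predictions[, "1"]
}

#' Build an integrated QSAR + alert model
#'
#' @param qsar a `qsar_model`
#' @param alerts an `alert_set` mined on the same training split
#' @param threshold score cutoff; predictions are positive only for scores
#'   strictly greater than this (default 0.5)
#' @return an `integrated_model`
#' @export
integrated_model <- function(qsar, alerts, threshold = 0.5) {
  stopifnot(inherits(qsar, "qsar_model"), inherits(alerts, "alert_set"))
  structure(list(qsar = qsar, alerts = alerts, threshold = threshold),
            class = "integrated_model")
}

#' Integrated prediction: high score AND alert presence
#'
#' A compound is predicted toxic only when the model score strictly exceeds
#' the threshold and the compound contains at least one structural alert.
#'
#' @param model an `integrated_model`
#' @param dataset a `toxicity_dataset`
#' @return integer vector of predicted labels
#' @export
integrated_predict <- function(model, dataset) {
  stopifnot(inherits(model, "integrated_model"))
  score <- qsar_score(model$qsar, dataset)
  alert_hit <- sa_predict(model$alerts, dataset)
  as.integer(score > model$threshold & alert_hit == 1L)
}

confusion_from_vectors <- function(pred, obs) {
  confusion_counts(tp = sum(pred == 1L & obs == 1L),
                   fp = sum(pred == 1L & obs == 0L),
                   tn = sum(pred == 0L & obs == 0L),
                   fn = sum(pred == 0L & obs == 1L))
}

#' Compare QSAR-only, alerts-only and integrated models on one split
#'
#' Splits the dataset 8:2 with the given seed, mines alerts and trains the
#' forest on the same training portion, and evaluates all three decision
#' rules on the shared held-out test set. By construction the integrated
#' model's positive-prediction set is the intersection of the other two
#' models' positive sets.
#'
#' @param dataset a `toxicity_dataset`
#' @param strategy mining strategy
#' @param params strategy parameters
#' @param config a [filter_config()]
#' @param seed seed for the split and forest
#' @param train_frac training fraction (default 0.8)
#' @param threshold score cutoff (default 0.5, strict)
#' @param num_trees,n_bits forest and fingerprint sizes
#' @return a `model_comparison`: per-model confusion counts and metrics on
#'   the test set, plus the raw prediction vectors
#' @export
compare_models <- function(dataset, strategy = MINING_STRATEGIES,
                           params = list(), config = filter_config(),
                           seed = 1L, train_frac = 0.8, threshold = 0.5,
                           num_trees = 500L, n_bits = 2048L) {
  strategy <- match.arg(strategy)
  sp <- holdout_split(dataset$n_total, dataset$records$label, train_frac,
                      seed)
  train <- dataset_subset(dataset, sp$train)
  test <- dataset_subset(dataset, sp$test)
  alerts <- mine_alerts(train, strategy, params, config)
  qsar <- train_qsar(train, seed = seed, num_trees = num_trees,
                     n_bits = n_bits)
  score <- qsar_score(qsar, test)
  obs <- test$records$label
  pred_qsar <- as.integer(score > threshold)
  pred_alerts <- sa_predict(alerts, test)
  pred_integrated <- as.integer(pred_qsar == 1L & pred_alerts == 1L)
  one <- function(pred) {
    cc <- confusion_from_vectors(pred, obs)
    c(list(counts = cc), sa_metrics(cc))
  }
  structure(
    list(endpoint = dataset$endpoint, strategy = strategy, seed = seed,
         n_train = train$n_total, n_test = test$n_total,
         mining_failed = isTRUE(alerts$failure$failed),
         n_alerts = n_alerts(alerts),
         qsar = one(pred_qsar), alerts = one(pred_alerts),
         integrated = one(pred_integrated),
         predictions = data.frame(id = test$records$id, obs = obs,
                                  score = score, qsar = pred_qsar,
                                  alert = pred_alerts,
                                  integrated = pred_integrated,
                                  stringsAsFactors = FALSE)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s/%s seed=%d (test n=%d)\n",
              x$endpoint, x$strategy, x$seed, x$n_test))
  for (m in c("qsar", "alerts", "integrated")) {
    v <- x[[m]]
    cat(sprintf("  %-10s ACC=%.3f PPV=%s MCC=%.3f\n", m, v$acc,
                ifelse(is.na(v$ppv), "NA", sprintf("%.3f", v$ppv)), v$mcc))
  }
  invisible(x)
}
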