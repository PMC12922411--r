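# Independent reference computations used as oracles. These work from raw
# label/prediction vectors and first principles, not through the package's
# own code paths.

# information gain by physically partitioning the records and recomputing
# the entropy of each part
ref_information_gain <- function(labels, carries, base = 2) {
  ent <- function(v) {
    if (length(v) == 0) return(0)
    p <- mean(v)
    s <- 0
    if (p > 0) s <- s - p * log(p, base)
    if (p < 1) s <- s - (1 - p) * log(1 - p, base)
    s
  }
  n <- length(labels)
  ent(labels) -
    (sum(carries) / n) * ent(labels[carries]) -
    (sum(!carries) / n) * ent(labels[!carries])
}

# ACC/PPV/MCC straight from prediction and observation vectors
ref_metrics <- function(pred, obs) {
  tp <- sum(pred == 1 & obs == 1); fp <- sum(pred == 1 & obs == 0)
  tn <- sum(pred == 0 & obs == 0); fn <- sum(pred == 0 & obs == 1)
  acc <- (tp + tn) / length(pred)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  d <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (d == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(d)
  list(acc = acc, ppv = ppv, mcc = mcc)
}

# exact one-sided binomial tail by direct summation
ref_binom_tail <- function(k, n, p0) {
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
             numeric(1)))
}
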