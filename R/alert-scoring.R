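# Per-substructure statistics: precision (PR), coverage rate (CR),
# binary entropy and information gain (IG), plus IG-based ranking.
#
# PR = N_sub_positive / N_sub          (fraction of carriers that are toxic)
# CR = N_sub / N_total                 (fraction of the dataset carrying it)
# IG = E(p_all) - P(t) E(p|t) - P(!t) E(p|!t), the entropy reduction from
# partitioning the dataset on fragment carriage. Entropies are in bits
# (base 2) by default; rankings do not depend on the base.

#' Precision of a substructure
#'
#' @param n_sub compounds containing the substructure (must be >= 1)
#' @param n_sub_positive positive compounds containing it
#' @return `n_sub_positive / n_sub`, vectorized
#' @export
alert_precision <- function(n_sub, n_sub_positive) {
  stopifnot(all(n_sub >= 1L), all(n_sub_positive >= 0L),
            all(n_sub_positive <= n_sub))
  n_sub_positive / n_sub
}

#' Coverage rate of a substructure
#'
#' @param n_sub compounds containing the substructure
#' @param n_total compounds in the dataset (must be >= 1)
#' @return `n_sub / n_total`, vectorized
#' @export
alert_coverage <- function(n_sub, n_total) {
  stopifnot(all(n_total >= 1L), all(n_sub >= 0L), all(n_sub <= n_total))
  n_sub / n_total
}

#' Binary entropy
#'
#' `-p log(p) - (1-p) log(1-p)` with `0 log 0 = 0`; base 2 by default so
#' the maximum (at p = 0.5) is one bit.
#'
#' @param p probability in `[0, 1]`, vectorized
#' @param base logarithm base
#' @return entropy values
#' @export
binary_entropy <- function(p, base = 2) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log(q, base = base))
  term(p) + term(1 - p)
}

#' Information gain of a substructure
#'
#' Entropy of the dataset's label distribution minus the weighted entropies
#' of the two sub-populations split by substructure carriage. Zero when the
#' split is uninformative; bounded above by the total entropy. Tiny negative
#' values from floating-point cancellation clamp to zero.
#'
#' @param n_sub,n_sub_positive substructure support counts (vectorized)
#' @param n_total,n_positive dataset totals
#' @param base logarithm base (2 = bits)
#' @return information gain values
#' @export
information_gain <- function(n_sub, n_sub_positive, n_total, n_positive,
                             base = 2) {
  if (length(n_sub) == 0L) return(numeric(0))
  if (any(n_total < 1L)) stop("n_total must be at least 1")
  if (any(n_sub_positive > n_positive))
    stop("n_sub_positive cannot exceed n_positive")
  if (any(n_sub - n_sub_positive > n_total - n_positive))
    stop("negative carriers cannot exceed dataset negatives")
  p_all <- n_positive / n_total
  p_t <- n_sub / n_total
  p_match <- ifelse(n_sub == 0L, 0, n_sub_positive / pmax(n_sub, 1L))
  rest <- n_total - n_sub
  p_nomatch <- ifelse(rest == 0L, 0,
                      (n_positive - n_sub_positive) / pmax(rest, 1L))
  ig <- binary_entropy(p_all, base) -
    p_t * binary_entropy(p_match, base) -
    (1 - p_t) * binary_entropy(p_nomatch, base)
  pmax(ig, 0)
}

#' Score a fragment table without filtering
#'
#' Attaches PR, CR, IG and the raw binomial p-value to every fragment.
#'
#' @param table a `fragment_table`
#' @return an `alert_set` holding all fragments with scores
#' @export
score_alerts <- function(table) {
  stopifnot(inherits(table, "fragment_table"))
  tab <- table$table
  df <- data.frame(
    pattern = tab$pattern, origin = tab$origin,
    n_sub = tab$n_sub, n_sub_positive = tab$n_sub_positive,
    pr = if (nrow(tab)) tab$n_sub_positive / tab$n_sub else numeric(0),
    cr = if (nrow(tab)) tab$n_sub / table$n_total else numeric(0),
    ig = information_gain(tab$n_sub, tab$n_sub_positive, table$n_total,
                          table$n_positive),
    p_value = if (nrow(tab)) fragment_pvalue(tab$n_sub, tab$n_sub_positive,
                                             table$n_total, table$n_positive)
    else numeric(0),
    strategy = rep(table$strategy, nrow(tab)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$ig, -df$pr, -df$cr, df$pattern), , drop = FALSE]
  new_alert_set(df, table$endpoint, table$strategy, config = NULL)
}

#' Top-k alerts ranked by information gain
#'
#' Descending IG; ties broken by higher PR, then higher CR, then
#' lexicographic pattern, so the ranking is deterministic for any input
#' order.
#'
#' @param alerts an `alert_set` (or its `alerts` data frame)
#' @param k number of alerts to keep
#' @return data frame of the top `k` alerts
#' @export
rank_top_k <- function(alerts, k = 10L) {
  stopifnot(k >= 1L)
  df <- if (inherits(alerts, "alert_set")) alerts$alerts else alerts
  df <- df[order(-df$ig, -df$pr, -df$cr, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}
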