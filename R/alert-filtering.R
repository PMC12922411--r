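# Statistical qualification of candidate fragments into an alert set.
#
# Two modes mirror the two families of mining tools: "significance" keeps
# fragments with enough hits, high enough precision and a small
# (Bonferroni-adjusted) one-sided binomial p-value against the dataset base
# rate; "support" keeps fragments frequent in the positive class (focus
# support) and rare in the negative class (complement support).

#' Filter configuration for alert qualification
#'
#' Defaults follow the uniform running parameters used across mining tools:
#' at least 5 hits, precision at least 0.75, significance level 0.05 with
#' Bonferroni correction; support mode uses minimum focus support 10% and
#' maximum complement support 5%.
#'
#' @param min_hits minimum number of compounds containing the fragment
#' @param min_precision minimum fraction of those compounds that are positive
#' @param alpha significance level for the binomial test
#' @param bonferroni apply Bonferroni correction over the fragments that
#'   reach `min_hits`
#' @param mode `"significance"` or `"support"`
#' @param focus_support_min minimum fraction of positives containing the
#'   fragment (support mode)
#' @param complement_support_max maximum fraction of negatives containing
#'   the fragment (support mode)
#' @param freq_min optional minimum dataset frequency `n_sub / n_total`
#'   (catalogue-style screening); `NA` disables it
#' @return a `filter_config`
#' @export
filter_config <- function(min_hits = 5L, min_precision = 0.75, alpha = 0.05,
                          bonferroni = TRUE,
                          mode = c("significance", "support"),
                          focus_support_min = 0.10,
                          complement_support_max = 0.05,
                          freq_min = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(min_precision > 0, min_precision <= 1, alpha > 0, alpha <= 1,
            focus_support_min > 0, focus_support_min <= 1,
            complement_support_max >= 0, complement_support_max <= 1)
  structure(
    list(min_hits = as.integer(min_hits), min_precision = min_precision,
         alpha = alpha, bonferroni = isTRUE(bonferroni), mode = mode,
         focus_support_min = focus_support_min,
         complement_support_max = complement_support_max,
         freq_min = freq_min),
    class = "filter_config"
  )
}

#' One-sided binomial significance of a fragment's positive enrichment
#'
#' Probability of observing at least `n_sub_positive` positives among the
#' `n_sub` compounds containing the fragment when compounds were toxic at
#' the dataset base rate `n_positive / n_total`.
#'
#' @param n_sub compounds containing the fragment
#' @param n_sub_positive positive compounds containing it
#' @param n_total,n_positive dataset totals
#' @return p-value in `[0, 1]` (vectorized over fragments)
#' @export
fragment_pvalue <- function(n_sub, n_sub_positive, n_total, n_positive) {
  if (any(n_total < 1L)) stop("n_total must be at least 1")
  stopifnot(all(n_sub >= 1L), all(n_sub_positive >= 0L),
            all(n_sub_positive <= n_sub))
  p0 <- n_positive / n_total
  pbinom(n_sub_positive - 1L, n_sub, p0, lower.tail = FALSE)
}

new_alert_set <- function(df, endpoint, strategy, config = NULL,
                          failure = NULL) {
  rownames(df) <- NULL
  structure(
    list(endpoint = endpoint, strategy = strategy, alerts = df,
         config = config, failure = failure),
    class = "alert_set"
  )
}

#' @export
print.alert_set <- function(x, ...) {
  cat(sprintf("<alert_set> %s/%s: %d alerts", x$endpoint, x$strategy,
              nrow(x$alerts)))
  if (isTRUE(x$failure$failed))
    cat(sprintf("  [FAILED: %s]", x$failure$reason))
  cat("\n")
  if (nrow(x$alerts) > 0L)
    print(utils::head(x$alerts[, c("pattern", "n_sub", "n_sub_positive",
                                   "pr", "cr", "ig", "p_value")], 10L))
  invisible(x)
}

#' Number of alerts in an alert set
#' @param x an `alert_set`
#' @export
n_alerts <- function(x) nrow(x$alerts)

#' Reduce a fragment table to a qualified alert set
#'
#' In significance mode a fragment is retained when `n_sub >= min_hits`,
#' its precision is at least `min_precision` and its (optionally
#' Bonferroni-adjusted) binomial p-value is at most `alpha`; the correction
#' multiplies each p-value by the number of fragments reaching `min_hits`
#' (fragments below the hit floor are never candidate hypotheses). In
#' support mode a fragment is retained when its focus support reaches
#' `focus_support_min` and its complement support does not exceed
#' `complement_support_max`. An empty result is a reportable outcome (the
#' strategy "failed" on this dataset), not an error.
#'
#' @param table a `fragment_table`
#' @param config a [filter_config()]
#' @return an `alert_set` with PR/CR/IG scores; the `failure` field is set
#'   when no fragment qualifies
#' @export
apply_filter <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "fragment_table"),
            inherits(config, "filter_config"))
  tab <- table$table
  n_total <- table$n_total
  n_positive <- table$n_positive
  if (nrow(tab) > 0L) {
    pr <- tab$n_sub_positive / tab$n_sub
    if (config$mode == "significance") {
      candidate <- tab$n_sub >= config$min_hits
      if (!is.na(config$freq_min))
        candidate <- candidate & (tab$n_sub / n_total >= config$freq_min)
      m <- sum(candidate)
      p_raw <- rep(NA_real_, nrow(tab))
      if (m > 0L)
        p_raw[candidate] <- fragment_pvalue(tab$n_sub[candidate],
                                            tab$n_sub_positive[candidate],
                                            n_total, n_positive)
      p_adj <- if (config$bonferroni) pmin(1, p_raw * m) else p_raw
      keep <- candidate & pr >= config$min_precision &
        !is.na(p_adj) & p_adj <= config$alpha
    } else {
      n_neg <- n_total - n_positive
      focus <- if (n_positive > 0L) tab$n_sub_positive / n_positive else 0
      complement <- if (n_neg > 0L) (tab$n_sub - tab$n_sub_positive) / n_neg
      else 0
      keep <- focus >= config$focus_support_min &
        complement <= config$complement_support_max
      p_adj <- fragment_pvalue(tab$n_sub, tab$n_sub_positive, n_total,
                               n_positive)
    }
    kept <- tab[keep, , drop = FALSE]
    p_kept <- p_adj[keep]
  } else {
    kept <- tab
    p_kept <- numeric(0)
  }
  df <- data.frame(
    pattern = kept$pattern, origin = kept$origin,
    n_sub = kept$n_sub, n_sub_positive = kept$n_sub_positive,
    pr = if (nrow(kept)) kept$n_sub_positive / kept$n_sub else numeric(0),
    cr = if (nrow(kept)) kept$n_sub / n_total else numeric(0),
    ig = information_gain(kept$n_sub, kept$n_sub_positive, n_total,
                          n_positive),
    p_value = p_kept,
    strategy = rep(table$strategy, nrow(kept)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$ig, -df$pr, -df$cr, df$pattern), , drop = FALSE]
  failure <- if (nrow(df) == 0L) {
    list(failed = TRUE,
         reason = sprintf("no fragment satisfies %s-mode thresholds",
                          config$mode))
  } else NULL
  new_alert_set(df, table$endpoint, table$strategy, config, failure)
}

#' Post-hoc screen applied to externally derived alert sets
#'
#' Keeps alerts with at least `min_hits` supporting compounds and precision
#' at least `min_precision` (both bounds inclusive); input order is
#' preserved. Used to put rule sets mined under other constraints on the
#' same footing as significance-mode sets.
#'
#' @param alerts an `alert_set` carrying support counts on the screening
#'   dataset
#' @param min_hits,min_precision screening thresholds
#' @return the screened `alert_set`
#' @export
screen_external <- function(alerts, min_hits = 5L, min_precision = 0.75) {
  stopifnot(inherits(alerts, "alert_set"))
  df <- alerts$alerts
  keep <- df$n_sub >= min_hits & (df$n_sub_positive / df$n_sub) >= min_precision
  new_alert_set(df[keep, , drop = FALSE], alerts$endpoint, alerts$strategy,
                alerts$config, failure = NULL)
}

#' Mine and filter in one step
#'
#' Convenience wrapper: [build_fragment_table()] followed by
#' [apply_filter()].
#'
#' @inheritParams build_fragment_table
#' @param config a [filter_config()]
#' @return an `alert_set`
#' @export
mine_alerts <- function(dataset, strategy = MINING_STRATEGIES,
                        params = list(), config = filter_config()) {
  strategy <- match.arg(strategy)
  apply_filter(build_fragment_table(dataset, strategy, params), config)
}
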