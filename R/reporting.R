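# Run manifests and the tolerance/count summary tables: which strategies
# succeeded on which endpoints, and how many alerts each produced.

#' Manifest of one mining invocation
#'
#' @param alerts an `alert_set` (possibly failed)
#' @param seeds seeds used, if any
#' @return a `run_manifest`
#' @export
run_manifest <- function(alerts, seeds = NULL) {
  stopifnot(inherits(alerts, "alert_set"))
  structure(
    list(endpoint = alerts$endpoint, strategy = alerts$strategy,
         outcome = if (isTRUE(alerts$failure$failed))
           sprintf("failed: %s", alerts$failure$reason) else "ok",
         failed = isTRUE(alerts$failure$failed),
         n_alerts = n_alerts(alerts),
         config = alerts$config, seeds = seeds,
         package_version = as.character(utils::packageVersion("samine"))),
    class = "run_manifest"
  )
}

#' Summarize a set of mining runs into tolerance and count tables
#'
#' Produces the per-(endpoint, strategy) alert-count table with failures
#' marked, and the per-strategy failure tally — the bookkeeping used to
#' compare how tolerant different strategies are of different datasets.
#'
#' @param manifests list of `run_manifest` objects
#' @return list with `counts` (data frame endpoint x strategy, `NA` count
#'   and `failed = TRUE` for failures) and `failure_tally` (named integer
#'   vector per strategy)
#' @export
summarize_run <- function(manifests) {
  stopifnot(length(manifests) >= 1L)
  df <- do.call(rbind, lapply(manifests, function(m) {
    data.frame(endpoint = m$endpoint, strategy = m$strategy,
               n_alerts = if (m$failed) NA_integer_ else m$n_alerts,
               failed = m$failed, outcome = m$outcome,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  strategies <- unique(df$strategy)
  tally <- vapply(strategies, function(s)
    sum(df$failed[df$strategy == s]), integer(1))
  list(counts = df, failure_tally = tally)
}

#' Write a run summary as JSON
#'
#' @param summary output of [summarize_run()]
#' @param path output path
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(
    list(counts = summary$counts,
         failure_tally = as.list(summary$failure_tally)),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
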