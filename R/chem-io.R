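# Reading, washing and canonicalizing labelled compound tables, plus
# SMARTS catalogue and alert-set file I/O.

#' Canonicalize SMILES strings with OpenBabel
#'
#' Converts each input to OpenBabel canonical SMILES. Strings OpenBabel
#' cannot parse yield `NA`.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES, `NA` where parsing failed
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  res <- rep(NA_character_, n)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  # OpenBabel stops a batch at the first unreadable record, so resume past
  # each failure until the remainder converts
  while (length(todo) > 0L) {
    ids <- sprintf("x%d", todo)
    src <- paste0(paste(smiles[todo], ids), "\n", collapse = "")
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = src)),
      error = function(e) ""
    )
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) next
      idx <- match(parts[2L], ids)
      if (!is.na(idx)) {
        res[todo[idx]] <- parts[1L]
        got <- c(got, idx)
      }
    }
    if (length(got) == 0L) {
      # first pending molecule is unreadable; skip it and continue
      todo <- todo[-1L]
    } else {
      done_up_to <- max(got)
      if (done_up_to >= length(todo)) break
      # everything after the last converted molecule failed at position
      # done_up_to + 1; drop that one and retry the rest
      todo <- todo[-seq_len(done_up_to + 1L)]
    }
  }
  res
}

coerce_binary_label <- function(x) {
  out <- rep(NA_integer_, length(x))
  if (is.logical(x)) return(as.integer(x))
  s <- trimws(tolower(as.character(x)))
  out[s %in% c("1", "true")] <- 1L
  out[s %in% c("0", "false")] <- 0L
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop(sprintf("labels must be in {0, 1, true, false}; offending value(s): %s",
                 paste(unique(s[bad])[seq_len(min(3, length(unique(s[bad]))))],
                       collapse = ", ")))
  out
}

# strip salts/solvents: keep the covalent fragment with the most heavy atoms,
# breaking ties by lexicographically smallest canonical SMILES
wash_components <- function(canonical_parts) {
  parts <- canonical_parts[!is.na(canonical_parts)]
  if (length(parts) == 0L) return(NA_character_)
  counts <- vapply(parts, function(p) {
    tryCatch(n_atoms(parse_smiles(p)), error = function(e) NA_integer_)
  }, integer(1))
  parts <- parts[!is.na(counts)]
  counts <- counts[!is.na(counts)]
  if (length(parts) == 0L) return(NA_character_)
  best <- parts[counts == max(counts)]
  sort(best)[1L]
}

#' Construct a toxicity dataset from SMILES and binary labels
#'
#' Builds the central container of the package: unique canonical SMILES with
#' binary toxicity labels, plus parsed molecular graphs used by mining and
#' matching. Duplicate molecules with agreeing labels collapse to one record;
#' duplicates with conflicting labels are dropped entirely.
#'
#' @param smiles character vector of SMILES (already canonical if
#'   `canonicalize = FALSE`)
#' @param label binary labels (1 = toxic/positive)
#' @param id optional record identifiers
#' @param endpoint endpoint name
#' @param canonicalize wash (largest covalent fragment) and canonicalize via
#'   OpenBabel before deduplication
#' @return a `toxicity_dataset`
#' @export
toxicity_dataset <- function(smiles, label, id = NULL, endpoint = "endpoint",
                             canonicalize = TRUE) {
  label <- coerce_binary_label(label)
  stopifnot(length(smiles) == length(label))
  if (is.null(id)) id <- sprintf("m%04d", seq_along(smiles))
  id <- as.character(id)
  keep <- !is.na(smiles) & nzchar(smiles) & !is.na(label)
  n_blank <- sum(!keep)
  smiles <- smiles[keep]; label <- label[keep]; id <- id[keep]

  if (canonicalize) {
    parts <- strsplit(smiles, ".", fixed = TRUE)
    flat <- unlist(parts)
    can_flat <- canonical_smiles(flat)
    idx <- rep(seq_along(parts), lengths(parts))
    washed <- vapply(seq_along(parts), function(i) {
      wash_components(can_flat[idx == i])
    }, character(1))
  } else {
    washed <- smiles
  }

  graphs <- lapply(washed, function(s) {
    if (is.na(s)) return(NULL)
    tryCatch(parse_smiles(s), error = function(e) NULL)
  })
  parseable <- !vapply(graphs, is.null, logical(1))
  n_unparseable <- sum(!parseable) + n_blank
  washed <- washed[parseable]; label <- label[parseable]; id <- id[parseable]
  graphs <- graphs[parseable]

  # deduplicate on canonical SMILES; conflicting labels drop the compound
  first_idx <- !duplicated(washed)
  lab_by_smi <- split(label, factor(washed, levels = unique(washed)))
  n_lab <- vapply(lab_by_smi, function(l) length(unique(l)), integer(1))
  conflicted <- names(n_lab)[n_lab > 1L]
  sel <- first_idx & !(washed %in% conflicted)

  records <- data.frame(
    id = id[sel], smiles = washed[sel], label = label[sel],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      endpoint = endpoint,
      records = records,
      graphs = graphs[sel],
      n_total = nrow(records),
      n_positive = sum(records$label),
      dropped = list(unparseable = n_unparseable,
                     conflicts = length(conflicted))
    ),
    class = "toxicity_dataset"
  )
}

#' @export
print.toxicity_dataset <- function(x, ...) {
  cat(sprintf("<toxicity_dataset> %s: %d compounds (%d positive, %.1f%%)\n",
              x$endpoint, x$n_total, x$n_positive,
              if (x$n_total > 0) 100 * x$n_positive / x$n_total else 0))
  if (x$dropped$unparseable > 0 || x$dropped$conflicts > 0)
    cat(sprintf("  dropped: %d unparseable, %d label-conflicted\n",
                x$dropped$unparseable, x$dropped$conflicts))
  invisible(x)
}

# subset preserving parsed graphs (used by holdout splitting)
dataset_subset <- function(ds, idx, endpoint = ds$endpoint) {
  records <- ds$records[idx, , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(endpoint = endpoint, records = records, graphs = ds$graphs[idx],
         n_total = nrow(records), n_positive = sum(records$label),
         dropped = list(unparseable = 0L, conflicts = 0L)),
    class = "toxicity_dataset"
  )
}

#' Load a labelled compound table
#'
#' Reads a CSV/TSV file with a SMILES column and a binary label column,
#' applies the standard pretreatment (largest-covalent-fragment wash,
#' OpenBabel canonicalization, deduplication) and returns a
#' [toxicity_dataset()]. Rows whose SMILES cannot be parsed are dropped and
#' counted; duplicated molecules with conflicting labels are dropped and
#' counted.
#'
#' @param path file path (`.csv` comma-separated, otherwise tab-separated;
#'   override with `sep`)
#' @param smiles_col,label_col column names
#' @param endpoint endpoint name (defaults to the file name)
#' @param sep field separator; `NULL` = infer from extension
#' @return a `toxicity_dataset`
#' @export
load_dataset <- function(path, smiles_col = "smiles", label_col = "label",
                         endpoint = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   comment.char = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path))
  for (col in c(smiles_col, label_col)) {
    if (!col %in% names(df))
      stop(sprintf("column \"%s\" not found in %s (columns: %s)",
                   col, path, paste(names(df), collapse = ", ")))
  }
  if (is.null(endpoint)) endpoint <- sub("\\.[^.]+$", "", basename(path))
  id <- if ("id" %in% names(df)) as.character(df$id) else
    sprintf("m%04d", seq_len(nrow(df)))
  ds <- toxicity_dataset(df[[smiles_col]], df[[label_col]], id = id,
                         endpoint = endpoint)
  if (ds$n_total == 0L && ds$dropped$conflicts == 0L)
    stop(sprintf("no parseable compounds in %s", path))
  ds
}

#' Write a toxicity dataset to a CSV file
#'
#' Exports canonical SMILES and labels; re-loading the file reproduces the
#' dataset (loading is idempotent on its own output).
#'
#' @param ds a `toxicity_dataset`
#' @param path output path
#' @export
write_dataset <- function(ds, path) {
  write.table(ds$records, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an alert set to a tab-separated file
#'
#' Columns: pattern, n_sub, n_sub_positive, pr, cr, ig, p_value, strategy.
#' Metadata (endpoint, filter configuration) is stored in commented header
#' lines so that [read_alert_set()] round-trips the object.
#'
#' @param alerts an `alert_set`
#' @param path output path
#' @export
write_alert_set <- function(alerts, path) {
  stopifnot(inherits(alerts, "alert_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("## endpoint=%s", alerts$endpoint), con)
  writeLines(sprintf("## strategy=%s", alerts$strategy), con)
  writeLines(sprintf("## failed=%s", isTRUE(alerts$failure$failed)), con)
  df <- alerts$alerts
  cols <- c("pattern", "n_sub", "n_sub_positive", "pr", "cr", "ig",
            "p_value", "strategy")
  df <- df[, cols, drop = FALSE]
  for (num in c("pr", "cr", "ig", "p_value"))
    df[[num]] <- formatC(df[[num]], digits = 17, format = "g")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(df) > 0L)
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' Read an alert set written by [write_alert_set()]
#'
#' @param path file path
#' @return an `alert_set`
#' @export
read_alert_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^## ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^## ", "", ml), "=", fixed = TRUE)[[1]]
    meta[[kv[1L]]] <- if (length(kv) > 1L) kv[2L] else ""
  }
  body <- lines[!grepl("^## ", lines)]
  df <- read.table(text = paste(body, collapse = "\n"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(pattern = "character", n_sub = "integer",
                                  n_sub_positive = "integer", pr = "numeric",
                                  cr = "numeric", ig = "numeric",
                                  p_value = "numeric", strategy = "character"))
  df <- data.frame(pattern = df$pattern, origin = df$strategy,
                   df[, c("n_sub", "n_sub_positive", "pr", "cr", "ig",
                          "p_value", "strategy")],
                   stringsAsFactors = FALSE)
  new_alert_set(df, endpoint = meta$endpoint %||% "endpoint",
                strategy = meta$strategy %||% "unknown",
                config = NULL,
                failure = if (identical(meta$failed, "TRUE"))
                  list(failed = TRUE, reason = "flagged in file") else NULL)
}

#' Load a SMARTS pattern catalogue
#'
#' One pattern per line; `#`-prefixed comment lines and blank lines are
#' skipped. Lines that do not parse as a supported substructure pattern are
#' rejected with a warning naming their line numbers; duplicate patterns
#' collapse to one.
#'
#' @param path file path
#' @param name catalogue name (defaults to the file name)
#' @return a `pattern_catalogue`
#' @export
load_catalogue <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  cand <- which(!grepl("^\\s*(#|$)", lines))
  if (length(cand) == 0L) stop(sprintf("no patterns in %s", path))
  pats <- trimws(sub("\\s.*$", "", trimws(lines[cand])))
  ok <- vapply(pats, function(p) {
    tryCatch({ compile_pattern(p); TRUE }, error = function(e) FALSE)
  }, logical(1))
  if (!any(ok))
    stop(sprintf("no valid patterns in %s (first rejected line: %d)",
                 path, cand[1L]))
  if (any(!ok))
    warning(sprintf("rejected %d invalid pattern line(s) in %s: line(s) %s",
                    sum(!ok), path,
                    paste(cand[!ok], collapse = ", ")))
  pattern_catalogue(unique(pats[ok]), name = name)
}

#' Construct a pattern catalogue from SMARTS strings
#'
#' @param patterns character vector of SMARTS-subset patterns
#' @param name catalogue name
#' @return a `pattern_catalogue`
#' @export
pattern_catalogue <- function(patterns, name = "catalogue") {
  patterns <- unique(as.character(patterns))
  for (p in patterns) compile_pattern(p)  # validates
  structure(list(name = name, patterns = patterns),
            class = "pattern_catalogue")
}

#' @export
print.pattern_catalogue <- function(x, ...) {
  cat(sprintf("<pattern_catalogue> %s: %d patterns\n", x$name,
              length(x$patterns)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
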