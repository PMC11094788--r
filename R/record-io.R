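# Reaction-record I/O. Records travel as line-delimited JSON (one reaction
# per line); finished datasets are written as Parquet (default) or CSV.
# Every cleaning run can log its funnel (reactions remaining after each
# step) through the funnel_audit helpers.

.record_list_fields <- c("labeled_reactants", "labeled_products",
                         "labeled_solvents", "labeled_catalysts",
                         "labeled_reagents")
.record_chr_fields <- c("record_id", "mapped_rxn", "procedure_details",
                        "grant_date", "experiment_date", "source_file")
.record_dbl_fields <- c("temperature_celsius", "time_hours")

record_from_json <- function(line) {
  obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  if (is.null(obj$record_id)) abort("missing required field `record_id`")
  row <- list()
  for (f in .record_chr_fields) {
    v <- obj[[f]]
    row[[f]] <- if (is.null(v) || !length(v)) NA_character_ else as.character(v)[1]
  }
  for (f in .record_dbl_fields) {
    v <- obj[[f]]
    row[[f]] <- if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)[1]
  }
  for (f in .record_list_fields) {
    v <- obj[[f]]
    row[[f]] <- list(if (is.null(v)) character(0) else as.character(v))
  }
  v <- obj$yields_percent
  row$yields_percent <- list(if (is.null(v)) numeric(0) else as.numeric(v))
  row$is_mapped <- isTRUE(obj$is_mapped) ||
    (!is.na(row$mapped_rxn) && grepl(":[0-9]+\\]", row$mapped_rxn))
  as_tibble(row)
}

#' Read reaction records from a JSONL file
#'
#' Reads one reaction record per line. Malformed lines are quarantined into
#' an error report (available via [record_errors()] and optionally written
#' to a sidecar file), never silently dropped: noisy patent-scale data
#' should not abort a run.
#'
#' `is_mapped` is derived as: the mapped reaction string is present and
#' carries at least one atom-map index.
#'
#' @param path Path to a JSONL file.
#' @param error_sidecar Optional path; when given, the per-line error report
#'   is written there as JSONL.
#' @return A tibble of reaction records in file order (list-columns for
#'   labeled components and yields), with the error report attached as
#'   attribute `"errors"`.
#' @export
read_reaction_records <- function(path, error_sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  errs <- list()
  for (i in seq_along(lines)) {
    rows[[i]] <- tryCatch(record_from_json(lines[[i]]), error = function(e) {
      errs[[length(errs) + 1L]] <<- tibble(line = i, message = conditionMessage(e))
      NULL
    })
  }
  records <- dplyr::bind_rows(rows)
  if (!nrow(records)) records <- empty_records()
  errors <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble(line = integer(0), message = character(0))
  if (!is.null(error_sidecar) && nrow(errors)) {
    writeLines(vapply(seq_len(nrow(errors)), function(i) {
      jsonlite::toJSON(as.list(errors[i, ]), auto_unbox = TRUE)
    }, character(1)), error_sidecar)
  }
  attr(records, "errors") <- errors
  records
}

empty_records <- function() {
  out <- tibble(
    record_id = character(0), mapped_rxn = character(0),
    procedure_details = character(0), grant_date = character(0),
    experiment_date = character(0), source_file = character(0),
    temperature_celsius = numeric(0), time_hours = numeric(0)
  )
  for (f in .record_list_fields) out[[f]] <- list()
  out$yields_percent <- list()
  out$is_mapped <- logical(0)
  out
}

#' Error report of a record read
#'
#' @param records A tibble returned by [read_reaction_records()].
#' @return Tibble with columns `line` and `message`.
#' @export
record_errors <- function(records) {
  attr(records, "errors") %||% tibble(line = integer(0), message = character(0))
}

#' Write reaction records to a JSONL file
#'
#' Inverse of [read_reaction_records()]; one JSON object per line.
#'
#' @param records Tibble of reaction records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reaction_records <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, ])
    for (f in names(row)) if (is.list(row[[f]])) row[[f]] <- row[[f]][[1]]
    row <- row[!vapply(row, function(v) length(v) == 1 && is.na(v), logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cleaned dataset to disk
#'
#' Writes a flat (no list-columns) table of cleaned reaction rows as
#' Parquet (default) or CSV. Round-tripping through [read_dataset()]
#' returns identical values, nulls included.
#'
#' @param rows A data frame sharing one column schema across rows.
#' @param path Output path.
#' @param format `"parquet"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(rows, path, format = c("parquet", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  bad <- names(rows)[vapply(rows, is.list, logical(1))]
  if (length(bad)) {
    abort(sprintf("dataset rows must be flat; list column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (format == "parquet") {
    arrow::write_parquet(rows, path)
  } else {
    readr::write_csv(rows, path, na = "")
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path File path.
#' @param format `"parquet"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return A tibble.
#' @export
read_dataset <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.csv$", path)) "csv" else "parquet")
  if (format == "parquet") {
    as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                    show_col_types = FALSE)
  }
}

#' Start a cleaning-funnel audit
#'
#' A funnel audit is an ordered log of `(step, reactions_remaining)` pairs.
#' Counts must be non-increasing across shrinking steps; steps declared
#' size-preserving (rare spectators mapped to "other") or size-doubling
#' (equivalent-SMILES augmentation) are exempt.
#'
#' @param step Name of the first step (conventionally `"full data set"`).
#' @param n Number of reactions at that step.
#' @return A `funnel_audit` tibble with columns `step` and
#'   `reactions_remaining`.
#' @export
funnel_audit <- function(step = "full data set", n = 0L) {
  stopifnot(n >= 0)
  structure(tibble(step = step, reactions_remaining = as.integer(n)),
            class = c("funnel_audit", "tbl_df", "tbl", "data.frame"))
}

#' Append a step to a funnel audit
#'
#' @param audit A [funnel_audit()].
#' @param step Step name.
#' @param n Reactions remaining after the step.
#' @param size_class `"shrink"` (count may not increase), `"preserve"`
#'   (count must be unchanged) or `"double"` (count must be exactly twice
#'   the previous step's).
#' @return The extended audit.
#' @export
record_funnel <- function(audit, step, n,
                          size_class = c("shrink", "preserve", "double")) {
  stopifnot(inherits(audit, "funnel_audit"), n >= 0)
  size_class <- match.arg(size_class)
  prev <- audit$reactions_remaining[nrow(audit)]
  ok <- switch(size_class,
    shrink = n <= prev,
    preserve = n == prev,
    double = n == 2L * prev
  )
  if (!ok) {
    abort(sprintf(
      "funnel violation at step '%s': %d reactions after %d (size class '%s')",
      step, n, prev, size_class))
  }
  out <- dplyr::bind_rows(audit, tibble(step = step, reactions_remaining = as.integer(n)))
  structure(out, class = class(audit))
}

#' Write a funnel audit as CSV
#'
#' @param audit A [funnel_audit()].
#' @param path Output path (columns `step,reactions_remaining`).
#' @return `path`, invisibly.
#' @export
write_funnel_csv <- function(audit, path) {
  readr::write_csv(audit, path)
  invisible(path)
}

#' @export
print.funnel_audit <- function(x, ...) {
  cat("<funnel_audit>\n")
  w <- max(nchar(x$step))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-*s %10s\n", w, x$step[i],
                format(x$reactions_remaining[i], big.mark = ",")))
  }
  invisible(x)
}

#' @rdname autoplot-rxncurate
#' @method autoplot funnel_audit
#' @export
autoplot.funnel_audit <- function(object, ...) {
  df <- object
  df$step <- factor(df$step, levels = rev(df$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reactions_remaining, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "reactions remaining", y = NULL,
                  title = "Cleaning funnel") +
    ggplot2::theme_minimal()
}
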