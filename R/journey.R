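#' @useDynLib dhitext, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef predict quantile rbinom rexp rnorm rpois runif sd var
#' @importFrom utils head read.csv tail write.csv
NULL

#' Recognized text snippet classes
#'
#' A snippet is one timestamped free-text unit of a user journey:
#' an `intervention` text (free-text answer inside the program), a
#' `user_message` or `coach_message` from the guided-support messaging
#' channel, or a `diary` / `exercise` entry.
#'
#' @return character vector of the five class labels.
#' @export
snippet_classes <- function() {
  c("intervention", "user_message", "coach_message", "diary", "exercise")
}

.ts_formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")

# parse ISO-8601-ish timestamps at second resolution, UTC assumed
parse_timestamp <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  pending <- !is.na(x) & nzchar(x)
  for (fmt in .ts_formats) {
    if (!any(pending)) break
    p <- as.POSIXct(x[pending], format = fmt, tz = "UTC")
    out[pending][!is.na(p)] <- p[!is.na(p)]
    pending[pending] <- is.na(p)
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_timestamps <- function(raw, parsed, what) {
  bad <- which(is.na(parsed))
  if (length(bad)) {
    stop(sprintf("%s: unparseable timestamp in row(s) %s (e.g. %s)", what,
                 paste(head(bad, 10L), collapse = ", "),
                 deparse(raw[bad[1]])), call. = FALSE)
  }
}

.read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  as.data.frame(do.call(rbind, lapply(recs, function(r)
    lapply(r, function(v) if (is.null(v)) NA else v))))
}

#' Read text snippets from a delimited or JSON-lines file
#'
#' Expects columns/keys `snippet_id`, `user_id`, `timestamp` (ISO-8601,
#' second resolution, UTC assumed when no offset is given), `text`, and
#' `snippet_class` (one of [snippet_classes()]). Input row order is
#' preserved; a missing column or any unparseable timestamp or unknown
#' class aborts the load with the offending rows named.
#'
#' @param path file path.
#' @param format `"csv"` (RFC-4180, UTF-8, header row) or `"jsonl"`.
#' @return data.frame with one row per snippet; `timestamp` is POSIXct (UTC),
#'   `snippet_class` is a factor over [snippet_classes()].
#' @export
read_snippets <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             encoding = "UTF-8")
  } else {
    .read_jsonl(path)
  }
  df[] <- lapply(df, function(col) as.character(unlist(col)))
  as_snippets(df)
}

#' Coerce a data.frame to the snippet schema
#'
#' @param df data.frame with character columns `snippet_id`, `user_id`,
#'   `timestamp`, `text`, `snippet_class`.
#' @return validated snippet data.frame (see [read_snippets()]).
#' @export
as_snippets <- function(df) {
  .require_columns(df, c("snippet_id", "user_id", "timestamp", "text",
                         "snippet_class"), "snippets")
  ts <- if (inherits(df$timestamp, "POSIXct")) df$timestamp else
    parse_timestamp(as.character(df$timestamp))
  .check_timestamps(as.character(df$timestamp), ts, "snippets")
  cls <- as.character(df$snippet_class)
  unknown <- which(!cls %in% snippet_classes())
  if (length(unknown)) {
    stop(sprintf("snippets: unknown snippet_class in row(s) %s (e.g. %s)",
                 paste(head(unknown, 10L), collapse = ", "),
                 deparse(cls[unknown[1]])), call. = FALSE)
  }
  text <- as.character(df$text)
  text[is.na(text)] <- ""
  out <- data.frame(
    snippet_id = as.character(df$snippet_id),
    user_id = as.character(df$user_id),
    timestamp = ts,
    text = text,
    snippet_class = factor(cls, levels = snippet_classes()),
    stringsAsFactors = FALSE
  )
  # empty texts are retained but flagged for downstream reporting
  out$empty_text <- !nzchar(trimws(out$text))
  rownames(out) <- NULL
  out
}

#' Write snippets to CSV or JSON-lines
#'
#' @param snippets snippet data.frame (see [read_snippets()]).
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_snippets <- function(snippets, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- data.frame(
    snippet_id = snippets$snippet_id,
    user_id = snippets$user_id,
    timestamp = format_timestamp(snippets$timestamp),
    text = snippets$text,
    snippet_class = as.character(snippets$snippet_class),
    stringsAsFactors = FALSE
  )
  .write_table(out, path, format)
}

.write_table <- function(out, path, format) {
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read symptom reports (touchpoints)
#'
#' Expects columns/keys `user_id`, `timestamp`, `measure_name`, `value`.
#' Binary event measures are coded 0/1; severity scales are real-valued.
#'
#' @inheritParams read_snippets
#' @return data.frame with `timestamp` POSIXct (UTC) and numeric `value`.
#' @export
read_reports <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             encoding = "UTF-8")
  } else {
    .read_jsonl(path)
  }
  df[] <- lapply(df, function(col) as.character(unlist(col)))
  as_reports(df)
}

#' Coerce a data.frame to the symptom report schema
#'
#' @param df data.frame with columns `user_id`, `timestamp`, `measure_name`,
#'   `value`.
#' @return validated report data.frame.
#' @export
as_reports <- function(df) {
  .require_columns(df, c("user_id", "timestamp", "measure_name", "value"),
                   "reports")
  ts <- if (inherits(df$timestamp, "POSIXct")) df$timestamp else
    parse_timestamp(as.character(df$timestamp))
  .check_timestamps(as.character(df$timestamp), ts, "reports")
  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(value) & !is.na(df$value))
  if (length(bad)) {
    stop(sprintf("reports: non-numeric value in row(s) %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    user_id = as.character(df$user_id),
    timestamp = ts,
    measure_name = as.character(df$measure_name),
    value = value,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write symptom reports to CSV or JSON-lines
#'
#' @param reports report data.frame (see [read_reports()]).
#' @inheritParams write_snippets
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  out <- data.frame(
    user_id = reports$user_id,
    timestamp = format_timestamp(reports$timestamp),
    measure_name = reports$measure_name,
    value = reports$value,
    stringsAsFactors = FALSE
  )
  .write_table(out, path, format)
}

#' Assemble per-user journeys from snippets and reports
#'
#' A journey is the time-ordered trace of one user: their text snippets and
#' their symptom reports. Users appearing in only one of the two tables
#' still yield a journey (with the other component empty). Sorting by
#' timestamp is stable, so records sharing a timestamp keep input order.
#'
#' @param snippets snippet data.frame (possibly empty).
#' @param reports report data.frame (possibly empty).
#' @return named list of `user_journey` objects, one per user, each a list
#'   with elements `user_id`, `snippets`, `reports`, `baseline_outcome`,
#'   `followup_outcome`.
#' @export
build_journeys <- function(snippets = NULL, reports = NULL) {
  empty_sn <- as_snippets(data.frame(snippet_id = character(),
                                     user_id = character(),
                                     timestamp = character(),
                                     text = character(),
                                     snippet_class = character()))
  empty_rp <- as_reports(data.frame(user_id = character(),
                                    timestamp = character(),
                                    measure_name = character(),
                                    value = character()))
  if (is.null(snippets)) snippets <- empty_sn
  if (is.null(reports)) reports <- empty_rp
  users <- sort(unique(c(snippets$user_id, reports$user_id)))
  out <- lapply(users, function(u) {
    sn <- snippets[snippets$user_id == u, , drop = FALSE]
    sn <- sn[order(sn$timestamp, method = "radix"), , drop = FALSE]
    rownames(sn) <- NULL
    rp <- reports[reports$user_id == u, , drop = FALSE]
    rp <- rp[order(rp$timestamp, method = "radix"), , drop = FALSE]
    rownames(rp) <- NULL
    structure(list(user_id = u, snippets = sn, reports = rp,
                   baseline_outcome = NA_real_, followup_outcome = NA_real_),
              class = "user_journey")
  })
  names(out) <- users
  out
}

#' @export
print.user_journey <- function(x, ...) {
  cat(sprintf("<user_journey %s: %d snippets, %d reports>\n",
              x$user_id, nrow(x$snippets), nrow(x$reports)))
  invisible(x)
}

#' Attach baseline and follow-up outcome scores to journeys
#'
#' Pulls two named measures (e.g. a baseline and a 6-month follow-up
#' severity score) out of each journey's reports and stores them in the
#' journey's `baseline_outcome` / `followup_outcome` slots. When a user has
#' several reports of the measure, the earliest (baseline) or latest
#' (follow-up) is used.
#'
#' @param journeys named list from [build_journeys()].
#' @param baseline_measure,followup_measure measure names to look up.
#' @return the journeys, with outcome slots filled (NA when absent).
#' @export
attach_outcomes <- function(journeys, baseline_measure, followup_measure) {
  lapply(journeys, function(j) {
    rp <- j$reports
    b <- rp$value[rp$measure_name == baseline_measure]
    f <- rp$value[rp$measure_name == followup_measure]
    j$baseline_outcome <- if (length(b)) b[1] else NA_real_
    j$followup_outcome <- if (length(f)) f[length(f)] else NA_real_
    j
  })
}

#' Extract the coach-user message thread from each journey
#'
#' Filters each journey down to the snippets whose class is `coach_message`
#' or `user_message`, in time order, relabelling them as a sender sequence.
#'
#' @param journeys named list from [build_journeys()].
#' @return named list of `message_thread` objects: data.frames with columns
#'   `timestamp`, `sender` (`"coach"`/`"user"`), `text`.
#' @export
extract_threads <- function(journeys) {
  out <- lapply(journeys, function(j) {
    sn <- j$snippets
    keep <- sn$snippet_class %in% c("coach_message", "user_message")
    sn <- sn[keep, , drop = FALSE]
    th <- data.frame(
      timestamp = sn$timestamp,
      sender = ifelse(as.character(sn$snippet_class) == "coach_message",
                      "coach", "user"),
      text = sn$text,
      stringsAsFactors = FALSE
    )
    rownames(th) <- NULL
    class(th) <- c("message_thread", "data.frame")
    th
  })
  names(out) <- names(journeys)
  out
}
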