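#' Aggregate snippet features to one row per user
#'
#' Collapses the snippet-level feature matrix into a user-level table for
#' outcome prediction. Per user: the mean over snippets of every
#' non-metadata snippet feature; additionally the sample SD (n-1
#' denominator) of each of the 15 sentiment features; five metadata
#' aggregates (total word count, total character count, number of
#' messages, mean message length in words, messages per day); and the two
#' communication metrics (response rate, mean response time). Under the
#' case-study message configuration this yields 5 + 2 + 79 + 50 + 44 + 10
#' + 30 = 220 aggregates. Baseline and follow-up outcomes are taken from
#' the journeys' outcome slots (see [attach_outcomes()]).
#'
#' "Messages per day" divides the message count by the user's journey span
#' in days (last minus first snippet timestamp, floored at 1 day). A user
#' with a single snippet gets zero SDs, with a warning. Undefined
#' communication metrics (users without coach messages, or without any
#' response pair) are imputed per `impute`: the across-user median of the
#' defined values (default), zero, or dropping the user.
#'
#' @param features snippet feature matrix from [featurize()] (with its
#'   `schema` attribute), covering the snippets to aggregate (for the
#'   message analysis, the featurized message snippets).
#' @param journeys named list from [build_journeys()], with outcomes
#'   attached.
#' @param threads named list from [extract_threads()].
#' @param impute `"median"`, `"zero"` or `"drop_user"`.
#' @return data.frame, one row per user with >= 1 featurized snippet:
#'   `user_id`, `baseline`, `outcome`, `n_user_messages`, then the named
#'   aggregate columns.
#' @export
aggregate_users <- function(features, journeys, threads,
                            impute = c("median", "zero", "drop_user")) {
  impute <- match.arg(impute)
  schema <- attr(features, "schema")
  if (is.null(schema)) stop("features must carry a schema attribute",
                            call. = FALSE)
  rows <- lapply(journeys, function(j) {
    ids <- intersect(j$snippets$snippet_id, rownames(features))
    if (!length(ids)) return(NULL)
    x <- features[ids, , drop = FALSE]
    sn <- j$snippets[match(ids, j$snippets$snippet_id), , drop = FALSE]
    aggregate_user(x, sn, threads[[j$user_id]], schema,
                   user_id = j$user_id,
                   baseline = j$baseline_outcome,
                   outcome = j$followup_outcome)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # impute undefined communication metrics
  for (col in c("comm_response_rate", "comm_mean_response_time")) {
    nas <- is.na(out[[col]])
    if (!any(nas)) next
    if (impute == "drop_user") {
      out <- out[!nas, , drop = FALSE]
    } else if (impute == "zero") {
      out[[col]][nas] <- 0
    } else {
      med <- stats::median(out[[col]], na.rm = TRUE)
      out[[col]][nas] <- if (is.na(med)) 0 else med
    }
  }
  rownames(out) <- NULL
  out
}

#' Aggregate one user's snippet features
#'
#' Workhorse behind [aggregate_users()]; exposed for testing and custom
#' pipelines.
#'
#' @param x feature matrix rows of one user's snippets.
#' @param snippets the matching snippet data.frame rows (for timestamps).
#' @param thread the user's `message_thread` (may be NULL or empty).
#' @param schema the feature schema data.frame (`name`, `family`).
#' @param user_id,baseline,outcome identifiers carried into the row.
#' @return one-row data.frame.
#' @export
aggregate_user <- function(x, snippets, thread, schema, user_id = "user",
                           baseline = NA_real_, outcome = NA_real_) {
  if (!nrow(x)) stop("user has no snippets to aggregate", call. = FALSE)
  if (nrow(x) == 1L) {
    warning("single snippet for user ", user_id,
            "; sentiment SDs set to 0", call. = FALSE)
  }
  fam <- schema$family
  wc <- x[, "meta_word_count"]  # raw per-snippet word counts (unnormalized)
  span_days <- as.numeric(difftime(max(snippets$timestamp),
                                   min(snippets$timestamp), units = "days"))
  span_days <- max(span_days, 1)
  meta <- c(
    meta_total_word_count = sum(wc),
    meta_total_char_count = sum(x[, "meta_char_count"]),
    meta_n_messages = nrow(x),
    meta_mean_message_length = mean(wc),
    meta_messages_per_day = nrow(x) / span_days
  )
  cf <- if (!is.null(thread) && nrow(thread)) comm_features(thread) else
    list(response_rate = NA_real_, mean_response_time = NA_real_,
         n_coach = 0L, n_user = 0L)
  comm <- c(comm_response_rate = cf$response_rate,
            comm_mean_response_time = cf$mean_response_time)
  keep <- fam != "metadata"
  means <- colMeans(x[, keep, drop = FALSE])
  sent_cols <- schema$name[fam == "sentiment"]
  sds <- apply(x[, sent_cols, drop = FALSE], 2L, function(v)
    if (length(v) < 2L) 0 else sd(v))
  names(sds) <- paste0(sent_cols, "_sd")
  vals <- c(meta, comm, means, sds)
  out <- data.frame(user_id = user_id, baseline = baseline,
                    outcome = outcome, n_user_messages = cf$n_user,
                    t(vals), check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Ordinary least-squares time trend of a feature series
#'
#' Slope (per day) of the feature value regressed on time since the first
#' snippet. Offered as an optional extra aggregation; not part of the
#' default user-level schema.
#'
#' @param values numeric feature values.
#' @param times POSIXct timestamps, same length.
#' @return slope in feature units per day; NA with fewer than 2 points.
#' @export
trend_feature <- function(values, times) {
  if (length(values) < 2L) return(NA_real_)
  days <- as.numeric(difftime(times, min(times), units = "days"))
  if (var(days) == 0) return(NA_real_)
  cov(days, values) / var(days)
}

#' @importFrom stats cov
NULL

#' Apply the user inclusion filters
#'
#' Retains users who reported both their baseline and follow-up outcome
#' and sent strictly more than `min_messages` messages to their coach
#' (the case-study filter is "more than 2", so exactly 2 messages is
#' excluded).
#'
#' @param rows user table from [aggregate_users()].
#' @param require_baseline,require_followup require the respective score.
#' @param min_messages strict lower bound on user-sent messages.
#' @return the filtered rows.
#' @export
filter_users <- function(rows, require_baseline = TRUE,
                         require_followup = TRUE, min_messages = 2L) {
  keep <- rep(TRUE, nrow(rows))
  if (require_baseline) keep <- keep & !is.na(rows$baseline)
  if (require_followup) keep <- keep & !is.na(rows$outcome)
  keep <- keep & rows$n_user_messages > min_messages
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
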