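#' Nearest-in-time symptom match for one snippet
#'
#' Picks the same-user symptom report minimizing the absolute time gap to
#' the snippet, looking both before and after the authoring time. Ties
#' between equidistant reports go to the earlier report (deterministic).
#'
#' @param snippet_time POSIXct authoring time of the snippet.
#' @param reports the user's report data.frame (any order).
#' @return list `(label, match_gap_hours)`; errors if `reports` is empty.
#' @export
match_nearest <- function(snippet_time, reports) {
  if (!nrow(reports)) stop("no reports to match against", call. = FALSE)
  gaps <- abs(as.numeric(difftime(reports$timestamp, snippet_time,
                                  units = "hours")))
  best <- which(gaps == min(gaps))
  if (length(best) > 1L) best <- best[which.min(reports$timestamp[best])]
  list(label = reports$value[best], match_gap_hours = gaps[best])
}

#' Fixed-window symptom average for one snippet
#'
#' Averages report values within `halfwidth` hours on either side of the
#' snippet's timestamp (symmetric window, boundary inclusive).
#'
#' @inheritParams match_nearest
#' @param halfwidth_hours positive window half-width, in hours.
#' @return list `(label, n_contributing)`; `label` is NA when no report
#'   falls in the window.
#' @export
window_average <- function(snippet_time, reports, halfwidth_hours) {
  stopifnot(halfwidth_hours > 0)
  gaps <- abs(as.numeric(difftime(reports$timestamp, snippet_time,
                                  units = "hours")))
  inwin <- gaps <= halfwidth_hours
  n <- sum(inwin)
  list(label = if (n) mean(reports$value[inwin]) else NA_real_,
       n_contributing = n)
}

#' Pair snippet features with symptom labels
#'
#' Builds the snippet-level training table for symptom inference: one row
#' per matchable snippet carrying its feature vector, the symptom label
#' drawn from the same user's reports, the user id and the match gap.
#' In `"nearest"` mode the label is the value of the closest report
#' (before or after the snippet), and snippets whose nearest report is
#' farther than `max_gap_hours` are excluded — the case-study default of
#' 24 h reflects labelling snippets with the occurrence of a binge episode
#' within a 24-hour window. In `"window"` mode the label is the mean
#' report value inside a symmetric window.
#'
#' @param journeys named list from [build_journeys()].
#' @param features feature matrix from [featurize()] (rownames are snippet
#'   ids); only snippets present here are aligned.
#' @param measure name of the symptom measure to use as label.
#' @param mode `"nearest"` or `"window"`.
#' @param max_gap_hours relevance bound on the nearest-match gap
#'   (default 24; `Inf` disables the bound).
#' @param halfwidth_hours window half-width for `"window"` mode.
#' @return object of class `aligned_dataset`: list with `data` (data.frame
#'   `user_id`, `snippet_id`, `label`, `gap_hours`), `x` (feature matrix,
#'   rows matching `data`), `mode`, and `n_excluded` (snippets dropped for
#'   want of a usable report).
#' @export
build_aligned_dataset <- function(journeys, features, measure,
                                  mode = c("nearest", "window"),
                                  max_gap_hours = 24,
                                  halfwidth_hours = 24) {
  mode <- match.arg(mode)
  rows <- list(); keep_ids <- character(); n_excluded <- 0L
  for (j in journeys) {
    rp <- j$reports[j$reports$measure_name == measure, , drop = FALSE]
    sn <- j$snippets[j$snippets$snippet_id %in% rownames(features), ,
                     drop = FALSE]
    if (!nrow(sn)) next
    if (!nrow(rp)) {
      n_excluded <- n_excluded + nrow(sn)
      next
    }
    for (i in seq_len(nrow(sn))) {
      if (mode == "nearest") {
        m <- match_nearest(sn$timestamp[i], rp)
        if (m$match_gap_hours > max_gap_hours) {
          n_excluded <- n_excluded + 1L
          next
        }
        lab <- m$label; gap <- m$match_gap_hours
      } else {
        m <- window_average(sn$timestamp[i], rp, halfwidth_hours)
        if (is.na(m$label)) {
          n_excluded <- n_excluded + 1L
          next
        }
        lab <- m$label; gap <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        user_id = j$user_id, snippet_id = sn$snippet_id[i], label = lab,
        gap_hours = gap, stringsAsFactors = FALSE)
      keep_ids <- c(keep_ids, sn$snippet_id[i])
    }
  }
  data <- if (length(rows)) do.call(rbind, rows) else
    data.frame(user_id = character(), snippet_id = character(),
               label = numeric(), gap_hours = numeric(),
               stringsAsFactors = FALSE)
  rownames(data) <- NULL
  if (n_excluded > 0L) {
    message(n_excluded, " snippet(s) excluded (no usable report)")
  }
  structure(list(data = data,
                 x = features[keep_ids, , drop = FALSE],
                 mode = mode, max_gap_hours = max_gap_hours,
                 halfwidth_hours = halfwidth_hours,
                 n_excluded = n_excluded),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset: %d rows (%s mode), %d excluded>\n",
              nrow(x$data), x$mode, x$n_excluded))
  invisible(x)
}

#' Write an aligned dataset as CSV (labels, gaps and feature columns)
#' @param aligned an `aligned_dataset`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_aligned <- function(aligned, path) {
  df <- cbind(aligned$data,
              as.data.frame(aligned$x, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
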