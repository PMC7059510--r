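#' Coach response rate of a message thread
#'
#' Fraction of coach messages whose immediate successor in the
#' time-ordered thread is a user message. Message content is deliberately
#' ignored: responsiveness is defined purely by adjacency in the sender
#' sequence. A terminal coach message has no successor and so can never
#' count toward the numerator (it still counts in the denominator). For
#' the sender sequence CCUCUCUCCCUU this gives 4/7 (7 coach and 5 user
#' messages, 4 coach messages directly followed by a user message).
#'
#' @param thread a `message_thread` ([extract_threads()]), or any
#'   data.frame with a `sender` column of `"coach"`/`"user"` in time
#'   order.
#' @return proportion in \[0, 1\], or NA if the thread has no coach
#'   message.
#' @export
response_rate <- function(thread) {
  s <- thread$sender
  n_coach <- sum(s == "coach")
  if (n_coach == 0L) return(NA_real_)
  followed <- s[-length(s)] == "coach" & s[-1] == "user"
  sum(followed) / n_coach
}

#' Mean coach-to-user response time of a thread
#'
#' Averages `user timestamp - coach timestamp` over exactly the
#' coach-message / immediately-following-user-message pairs that
#' [response_rate()] counts.
#'
#' @inheritParams response_rate
#' @param unit `"hours"` (default) or `"days"`.
#' @return non-negative mean response time, or NA when no qualifying pair
#'   exists.
#' @export
mean_response_time <- function(thread, unit = c("hours", "days")) {
  unit <- match.arg(unit)
  s <- thread$sender
  if (length(s) < 2L) return(NA_real_)
  i <- which(s[-length(s)] == "coach" & s[-1] == "user")
  if (!length(i)) return(NA_real_)
  gaps <- as.numeric(difftime(thread$timestamp[i + 1L],
                              thread$timestamp[i], units = unit))
  mean(gaps)
}

#' Communication feature summary of a thread
#'
#' @inheritParams response_rate
#' @return named list: `response_rate`, `mean_response_time` (hours),
#'   `n_coach`, `n_user`. Undefined metrics are NA and are imputed at
#'   aggregation time (see [aggregate_users()]).
#' @export
comm_features <- function(thread) {
  list(response_rate = response_rate(thread),
       mean_response_time = mean_response_time(thread),
       n_coach = sum(thread$sender == "coach"),
       n_user = sum(thread$sender == "user"))
}

#' Build a message thread from a sender string (testing/fixture helper)
#'
#' Turns a compact sender sequence such as `"CCUCUCUCCCUU"` into a
#' `message_thread` with messages one hour apart.
#'
#' @param senders string over the alphabet C (coach) / U (user).
#' @param start start timestamp.
#' @param spacing_hours gap between consecutive messages.
#' @return a `message_thread` data.frame.
#' @export
thread_from_senders <- function(senders,
                                start = as.POSIXct("2020-01-01 00:00:00",
                                                   tz = "UTC"),
                                spacing_hours = 1) {
  ch <- strsplit(senders, "", fixed = TRUE)[[1]]
  stopifnot(all(ch %in% c("C", "U")))
  th <- data.frame(
    timestamp = start + 3600 * spacing_hours * (seq_along(ch) - 1L),
    sender = ifelse(ch == "C", "coach", "user"),
    text = "",
    stringsAsFactors = FALSE
  )
  class(th) <- c("message_thread", "data.frame")
  th
}
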