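# builds a feature matrix + schema with the tiny pipeline families
mk_user_features <- function(n_snippets, seed = 1) {
  set.seed(seed)
  schema <- rbind(
    data.frame(name = c("meta_word_count", "meta_char_count"),
               family = "metadata"),
    data.frame(name = paste0("wu_", letters[1:3]), family = "word_usage"),
    data.frame(name = paste0("emb_", 1:2), family = "embedding"),
    data.frame(name = "pos_NN", family = "pos"),
    data.frame(name = c("topic_1", "topic_2", "topic_sd", "topic_loglik"),
               family = "topic"),
    data.frame(name = sentiment_feature_names(), family = "sentiment"))
  mat <- matrix(rnorm(n_snippets * nrow(schema)), nrow = n_snippets,
                dimnames = list(sprintf("s%03d", seq_len(n_snippets)),
                                schema$name))
  mat[, "meta_word_count"] <- rpois(n_snippets, 20) + 1
  mat[, "meta_char_count"] <- mat[, "meta_word_count"] * 5
  attr(mat, "schema") <- schema
  mat
}

mk_journey_for <- function(mat, span_days = 10, uid = "u1",
                           baseline = 3, outcome = 2) {
  n <- nrow(mat)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  sn <- snippet_df(rownames(mat), uid,
                   format(t0 + seq(0, span_days, length.out = n) * 86400),
                   "x", "user_message")
  j <- build_journeys(sn, NULL)[[uid]]
  j$baseline_outcome <- baseline
  j$followup_outcome <- outcome
  j
}

test_that("per-user aggregation reproduces closed-form statistics", {
  mat <- mk_user_features(6)
  j <- mk_journey_for(mat)
  th <- thread_from_senders("CUCU")
  schema <- attr(mat, "schema")
  row <- aggregate_user(mat, j$snippets, th, schema, user_id = "u1",
                        baseline = 3, outcome = 2)
  # metadata aggregates
  expect_equal(row$meta_total_word_count, sum(mat[, "meta_word_count"]))
  expect_equal(row$meta_n_messages, 6)
  expect_equal(row$meta_mean_message_length,
               mean(mat[, "meta_word_count"]))
  expect_equal(row$meta_messages_per_day, 6 / 10)
  expect_equal(row$comm_response_rate, 1)
  # column-wise oracle for every mean aggregate
  for (nm in schema$name[schema$family != "metadata"]) {
    expect_equal(row[[nm]], mean(mat[, nm]), label = nm)
  }
  # sample SD for each sentiment feature
  for (nm in schema$name[schema$family == "sentiment"]) {
    expect_equal(row[[paste0(nm, "_sd")]], sd(mat[, nm]), label = nm)
  }
})

test_that("two-point sentiment aggregates follow the n-1 convention", {
  mat <- mk_user_features(2)
  mat[, "nrc_joy"] <- c(1, 3)
  row <- aggregate_user(mat, mk_journey_for(mat)$snippets,
                        thread_from_senders("CU"), attr(mat, "schema"))
  expect_equal(row$nrc_joy, 2)
  expect_equal(row$nrc_joy_sd, sd(c(1, 3)))  # = sqrt(2)
  # identical snippets -> all SDs zero
  mat2 <- mk_user_features(3)
  mat2[2, ] <- mat2[1, ]; mat2[3, ] <- mat2[1, ]
  row2 <- aggregate_user(mat2, mk_journey_for(mat2)$snippets,
                         thread_from_senders("CU"), attr(mat2, "schema"))
  sds <- unlist(row2[paste0(sentiment_feature_names(), "_sd")])
  expect_equal(unname(sds), rep(0, 15))
  # single snippet -> zero SDs with a warning
  mat1 <- mk_user_features(1)
  expect_warning(
    row1 <- aggregate_user(mat1, mk_journey_for(mat1)$snippets,
                           thread_from_senders("CU"),
                           attr(mat1, "schema")), "single")
  expect_equal(unname(unlist(row1[paste0(sentiment_feature_names(), "_sd")])),
               rep(0, 15))
})

test_that("messages per day halves when the journey span doubles", {
  mat <- mk_user_features(8)
  r1 <- aggregate_user(mat, mk_journey_for(mat, span_days = 10)$snippets,
                       thread_from_senders("CU"), attr(mat, "schema"))
  r2 <- aggregate_user(mat, mk_journey_for(mat, span_days = 20)$snippets,
                       thread_from_senders("CU"), attr(mat, "schema"))
  expect_equal(r1$meta_messages_per_day, 2 * r2$meta_messages_per_day)
  # sub-day journeys floor the denominator at one day
  r3 <- aggregate_user(mat, mk_journey_for(mat, span_days = 0.1)$snippets,
                       thread_from_senders("CU"), attr(mat, "schema"))
  expect_equal(r3$meta_messages_per_day, 8)
})

test_that("undefined communication metrics are imputed by policy", {
  mat <- mk_user_features(4)
  sn_all <- list(); journeys <- list(); threads <- list()
  mats <- list()
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  feats_rows <- list()
  for (u in 1:3) {
    uid <- paste0("u", u)
    m <- mk_user_features(4, seed = u)
    rownames(m) <- sprintf("%s_s%02d", uid, 1:4)
    mats[[uid]] <- m
    sn <- snippet_df(rownames(m), uid, format(t0 + (1:4) * 86400), "x",
                     "user_message")
    sn_all[[uid]] <- sn
  }
  big <- do.call(rbind, mats)
  attr(big, "schema") <- attr(mat, "schema")
  journeys <- build_journeys(do.call(rbind, sn_all), NULL)
  threads <- list(u1 = thread_from_senders("CUCU"),
                  u2 = thread_from_senders("UU"),     # no coach: undefined
                  u3 = thread_from_senders("CCUU"))
  out_med <- aggregate_users(big, journeys, threads, impute = "median")
  expect_equal(nrow(out_med), 3L)
  expect_false(anyNA(out_med$comm_response_rate))
  defined <- c(1, 1 / 2)  # u1 CUCU -> 2/2; u3 CCUU -> 1/2
  expect_equal(out_med$comm_response_rate[out_med$user_id == "u2"],
               median(defined))
  out_zero <- aggregate_users(big, journeys, threads, impute = "zero")
  expect_equal(out_zero$comm_response_rate[out_zero$user_id == "u2"], 0)
  out_drop <- aggregate_users(big, journeys, threads, impute = "drop_user")
  expect_false("u2" %in% out_drop$user_id)
})

test_that("time trends recover the closed-form OLS slope", {
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  expect_equal(trend_feature(c(5, 5, 5), t0 + (0:2) * 86400), 0)
  expect_equal(trend_feature(c(0, 1), t0 + c(0, 86400)), 1)
  expect_true(is.na(trend_feature(3, t0)))
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    days <- sort(runif(n, 0, 30))
    vals <- rnorm(n)
    slope <- unname(coef(lm(vals ~ days))[2])
    expect_equal(trend_feature(vals, t0 + days * 86400), slope,
                 tolerance = 1e-9)
  }
})

test_that("user filters demand both scores and more than two messages", {
  rows <- data.frame(
    user_id = c("a", "b", "c", "d"),
    baseline = c(3, NA, 3, 3), outcome = c(2, 2, NA, 2),
    n_user_messages = c(3, 5, 5, 2))
  kept <- filter_users(rows, min_messages = 2)
  expect_identical(kept$user_id, "a")
  # exactly 2 messages is excluded ("more than 2"), 3 retained
  rows2 <- data.frame(user_id = c("x", "y"), baseline = 1, outcome = 1,
                      n_user_messages = c(2, 3))
  expect_identical(filter_users(rows2)$user_id, "y")
  # brute-force predicate scan on a random cohort
  set.seed(52)
  cohort <- data.frame(
    user_id = paste0("u", 1:60),
    baseline = ifelse(runif(60) < 0.8, rnorm(60, 3), NA),
    outcome = ifelse(runif(60) < 0.8, rnorm(60, 2), NA),
    n_user_messages = rpois(60, 3))
  kept <- filter_users(cohort)
  oracle <- cohort[!is.na(cohort$baseline) & !is.na(cohort$outcome) &
                     cohort$n_user_messages > 2, ]
  expect_identical(kept$user_id, oracle$user_id)
})
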