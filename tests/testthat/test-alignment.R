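mk_reports <- function(times, values) {
  report_df(rep("u1", length(times)), times, values)
}

test_that("nearest matching picks the closer report, earlier on ties", {
  rp <- mk_reports(c("2023-01-01T10:00:00", "2023-01-01T15:00:00"),
                   c(1, 0))
  m <- match_nearest(parse_timestamp("2023-01-01T12:00:00"), rp)
  expect_equal(m$label, 1)
  expect_equal(m$match_gap_hours, 2)
  # equidistant at +/- 2h: earlier report wins
  rp2 <- mk_reports(c("2023-01-01T14:00:00", "2023-01-01T10:00:00"),
                    c(0, 1))
  m2 <- match_nearest(parse_timestamp("2023-01-01T12:00:00"), rp2)
  expect_equal(m2$label, 1)
  expect_error(match_nearest(parse_timestamp("2023-01-01T12:00:00"),
                             rp2[0, ]), "no reports")
})

test_that("nearest matching equals an exhaustive min-gap scan", {
  set.seed(41)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  for (i in 1:50) {
    rp <- report_df(rep("u1", 12), format(t0 + runif(12, 0, 60) * 86400),
                    rbinom(12, 1, 0.5))
    st <- t0 + runif(1, 0, 60) * 86400
    m <- match_nearest(st, rp)
    gaps <- abs(as.numeric(difftime(rp$timestamp, st, units = "hours")))
    expect_equal(m$match_gap_hours, min(gaps))
    # no other report has a strictly smaller gap
    expect_false(any(gaps < m$match_gap_hours - 1e-12))
  }
})

test_that("window averaging means the in-window reports", {
  rp <- mk_reports(c("2023-01-01T10:00:00", "2023-01-01T13:00:00"),
                   c(1, 0))
  st <- parse_timestamp("2023-01-01T12:00:00")
  w <- window_average(st, rp, halfwidth_hours = 6)
  expect_equal(w$label, 0.5)
  expect_equal(w$n_contributing, 2L)
  w1 <- window_average(st, rp, halfwidth_hours = 1.5)
  expect_equal(w1$label, 0)
  expect_equal(w1$n_contributing, 1L)
  w0 <- window_average(st, rp[0, ], halfwidth_hours = 6)
  expect_true(is.na(w0$label))
  # oracle on random data
  set.seed(42)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  for (i in 1:50) {
    rp <- report_df(rep("u1", 15), format(t0 + runif(15, 0, 30) * 86400),
                    runif(15))
    st <- t0 + runif(1, 0, 30) * 86400
    hw <- runif(1, 1, 72)
    w <- window_average(st, rp, hw)
    inwin <- abs(as.numeric(difftime(rp$timestamp, st,
                                     units = "hours"))) <= hw
    expect_equal(w$label,
                 if (any(inwin)) mean(rp$value[inwin]) else NA_real_)
  }
})

test_that("aligned datasets pair each matchable snippet with a label", {
  sn <- snippet_df(c("a", "b", "c"), "u1",
                   c("2023-01-01T08:00:00", "2023-01-01T12:00:00",
                     "2023-01-02T09:00:00"), "text here")
  rp <- mk_reports(c("2023-01-01T10:00:00", "2023-01-02T10:00:00"),
                   c(1, 0))
  feats <- matrix(rnorm(6), nrow = 3,
                  dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  attr(feats, "schema") <- data.frame(name = c("f1", "f2"),
                                      family = "word_usage")
  j <- build_journeys(sn, rp)
  al <- build_aligned_dataset(j, feats, "binge_episode", mode = "nearest")
  expect_equal(nrow(al$data), 3L)
  expect_equal(al$data$label, c(1, 1, 0))
  expect_equal(nrow(al$x), 3L)
  expect_true(all(al$data$gap_hours >= 0))
  # binary labels preserved as 0/1
  expect_true(all(al$data$label %in% c(0, 1)))
  # user with no reports: all snippets excluded, with a logged count
  j2 <- build_journeys(sn, NULL)
  expect_message(
    al2 <- build_aligned_dataset(j2, feats, "binge_episode"),
    "3 snippet")
  expect_equal(nrow(al2$data), 0L)
  expect_equal(al2$n_excluded, 3L)
  # the 24-hour relevance bound excludes distant snippets
  rp_far <- mk_reports("2023-01-03T08:00:00", 1)
  j3 <- build_journeys(sn, rp_far)
  expect_message(
    al3 <- build_aligned_dataset(j3, feats, "binge_episode",
                                 max_gap_hours = 24))
  expect_equal(nrow(al3$data), 1L)  # only snippet "c" is within 24 h
})

test_that("alignment is invariant to uniform time shifts", {
  set.seed(43)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  sn <- snippet_df(paste0("s", 1:10), "u1",
                   format(t0 + sort(runif(10, 0, 20)) * 86400), "x")
  rp <- report_df(rep("u1", 8), format(t0 + runif(8, 0, 20) * 86400),
                  rbinom(8, 1, 0.4))
  feats <- matrix(0, nrow = 10, ncol = 1,
                  dimnames = list(sn$snippet_id, "f1"))
  attr(feats, "schema") <- data.frame(name = "f1", family = "word_usage")
  al <- build_aligned_dataset(build_journeys(sn, rp), feats,
                              "binge_episode", max_gap_hours = Inf)
  sn2 <- sn; sn2$timestamp <- sn$timestamp + 86400 * 100
  rp2 <- rp; rp2$timestamp <- rp$timestamp + 86400 * 100
  al2 <- build_aligned_dataset(build_journeys(sn2, rp2), feats,
                               "binge_episode", max_gap_hours = Inf)
  expect_equal(al2$data$label, al$data$label)
  expect_equal(al2$data$gap_hours, al$data$gap_hours)
})

test_that("an infinitely wide window converges to the per-user mean label", {
  set.seed(44)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  sn <- snippet_df(paste0("s", 1:5), "u1",
                   format(t0 + runif(5, 0, 10) * 86400), "x")
  rp <- report_df(rep("u1", 6), format(t0 + runif(6, 0, 10) * 86400),
                  runif(6))
  feats <- matrix(0, nrow = 5, ncol = 1,
                  dimnames = list(sn$snippet_id, "f1"))
  attr(feats, "schema") <- data.frame(name = "f1", family = "word_usage")
  al <- build_aligned_dataset(build_journeys(sn, rp), feats,
                              "binge_episode", mode = "window",
                              halfwidth_hours = 1e7)
  expect_equal(al$data$label, rep(mean(rp$value), 5))
})

test_that("row counts equal a per-snippet matchability scan", {
  set.seed(45)
  t0 <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  sn_all <- list(); rp_all <- list()
  for (u in 1:4) {
    uid <- paste0("u", u)
    n <- sample(3:8, 1)
    sn_all[[u]] <- snippet_df(paste0(uid, "_s", 1:n), uid,
                              format(t0 + runif(n, 0, 30) * 86400), "x")
    if (u < 4) {
      m <- sample(2:5, 1)
      rp_all[[u]] <- report_df(rep(uid, m),
                               format(t0 + runif(m, 0, 30) * 86400),
                               rbinom(m, 1, 0.5))
    }
  }
  sn <- do.call(rbind, sn_all)
  rp <- do.call(rbind, rp_all)
  feats <- matrix(0, nrow = nrow(sn), ncol = 1,
                  dimnames = list(sn$snippet_id, "f1"))
  attr(feats, "schema") <- data.frame(name = "f1", family = "word_usage")
  j <- build_journeys(sn, rp)
  suppressMessages(
    al <- build_aligned_dataset(j, feats, "binge_episode",
                                max_gap_hours = 24))
  # oracle: per-snippet exhaustive matchability scan
  expected <- 0L
  for (i in seq_len(nrow(sn))) {
    r <- rp[rp$user_id == sn$user_id[i], ]
    if (nrow(r) == 0) next
    gap <- min(abs(as.numeric(difftime(r$timestamp, sn$timestamp[i],
                                       units = "hours"))))
    if (gap <= 24) expected <- expected + 1L
  }
  expect_equal(nrow(al$data), expected)
  expect_equal(nrow(al$data) + al$n_excluded, nrow(sn))
})
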