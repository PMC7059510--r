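test_that("metadata features count words and characters on raw text", {
  expect_equal(unname(metadata_features("I ate.")), c(2, 6))
  expect_equal(unname(metadata_features("")), c(0, 0))
  set.seed(21)
  for (i in 1:100) {
    words <- replicate(sample(0:8, 1),
                       paste(sample(letters, sample(1:6, 1)), collapse = ""))
    txt <- paste(words, collapse = " ")
    m <- metadata_features(txt)
    expect_equal(unname(m[1]), length(words))
    expect_equal(unname(m[2]), nchar(txt))
  }
})

test_that("snippet embedding is the elementwise token-vector mean", {
  tab <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(embed_snippet("a", tab)), c(1, 2, 3),
               ignore_attr = TRUE)
  expect_equal(as.numeric(embed_snippet(c("a", "b"), tab)),
               c(5.5, 11, 16.5))
  # multiplicity weighting
  expect_equal(as.numeric(embed_snippet(c("a", "a", "b"), tab)),
               c(4, 8, 12))
  oov <- embed_snippet(c("zz", "qq"), tab)
  expect_equal(as.numeric(oov), c(0, 0, 0))
  expect_equal(attr(oov, "n_matched"), 0L)
  expect_equal(attr(oov, "n_oov"), 2L)
})

test_that("embedding files round-trip through the GloVe dialect", {
  set.seed(22)
  mat <- matrix(rnorm(12), nrow = 3,
                dimnames = list(c("alpha", "beta", "gamma"), NULL))
  path <- tempfile()
  write_embeddings(mat, path)
  back <- read_embeddings(path)
  expect_equal(back, mat, tolerance = 1e-12)
})

test_that("POS features count tags over the 44-slot inventory", {
  expect_equal(length(ptb_tagset()), 44L)
  tagger <- dictionary_tagger(c(she = "PRP", eats = "VBZ", food = "NN"))
  v <- pos_features("she eats food", tagger)
  expect_equal(unname(v[c("PRP", "VBZ", "NN")]), c(1L, 1L, 1L))
  expect_equal(sum(v), 3L)
  expect_equal(sum(pos_features("", tagger)), 0L)
  # conservation over random sentences: total tags = tagged tokens
  set.seed(23)
  voc <- c("she", "eats", "food", "runs", "fast")
  for (i in 1:50) {
    txt <- paste(sample(voc, sample(1:12, 1), TRUE), collapse = " ")
    n_tok <- length(strsplit(txt, " ")[[1]])
    expect_equal(sum(pos_features(txt, tagger)), n_tok)
  }
  # tags outside the inventory are dropped with a warning
  bad <- dictionary_tagger(c(she = "XX"), default_tag = "NN")
  expect_warning(v2 <- pos_features("she eats", bad), "inventory")
  expect_equal(sum(v2), 1L)
  # tagger failure yields zeros, pipeline continues
  boom <- function(text) stop("backend down")
  expect_warning(v3 <- pos_features("any text", boom), "failed")
  expect_equal(sum(v3), 0L)
})

test_that("LDA recovers planted topics and is seed-deterministic", {
  set.seed(24)
  vocab_a <- paste0("a", 1:12)
  vocab_b <- paste0("b", 1:12)
  mk <- function(voc) structure(
    list(tokens = sample(voc, 25, TRUE), raw_word_count = 25L,
         raw_char_count = 1L), class = "token_list")
  corpus <- c(lapply(1:20, function(i) mk(vocab_a)),
              lapply(1:20, function(i) mk(vocab_b)))
  m1 <- fit_topic_model(corpus, n_topics = 2, seed = 99, iter = 150)
  m2 <- fit_topic_model(corpus, n_topics = 2, seed = 99, iter = 150)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi, m2$phi)
  # per-document proportions are probability vectors
  expect_true(all(m1$theta >= 0))
  expect_equal(rowSums(m1$theta), rep(1, 40), tolerance = 1e-9)
  # disjoint-vocabulary documents assign >= 0.8 mass to one topic
  dominant <- apply(m1$theta, 1, max)
  expect_true(all(dominant >= 0.8))
  # the two blocks land on different topics
  top_a <- which.max(colMeans(m1$theta[1:20, ]))
  top_b <- which.max(colMeans(m1$theta[21:40, ]))
  expect_false(top_a == top_b)
  expect_error(fit_topic_model(corpus[1], n_topics = 2), "few")
})

test_that("topic features append the proportion SD and log-likelihood", {
  tp <- tiny_pipeline()
  model <- tp$pipeline$topics
  tl <- preprocess("joy food fear", tp$config)
  f <- topic_features(tl, model)
  K <- model$n_topics
  expect_length(f, K + 2)
  p <- f[1:K]
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(f["topic_sd"]), sqrt(mean((p - 1 / K)^2)))
  # degenerate distribution SD by the stated formula
  p1 <- c(1, rep(0, 7))
  expect_equal(sqrt(mean((p1 - 1 / 8)^2)), sqrt(sum((p1 - 1 / 8)^2) / 8))
  # empty snippet: uniform proportions, zero SD, zero log-likelihood
  expect_warning(f0 <- topic_features(character(), model), "uniform")
  expect_equal(unname(f0[1:K]), rep(1 / K, K))
  expect_equal(unname(f0["topic_sd"]), 0)
  expect_equal(unname(f0["topic_loglik"]), 0)
})

test_that("sentiment counts follow the fixture lexicons exactly", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("joy\tjoy\t1", "joy\tpositive\t1", "fear\tfear\t1",
               "fear\tnegative\t1"), file.path(dir, "nrc.tsv"))
  writeLines(c("joy\t3", "fear\t-2"), file.path(dir, "afinn.tsv"))
  writeLines(c("joy\tpositive", "fear\tnegative"),
             file.path(dir, "bing.tsv"))
  lex <- sentiment_lexicons(file.path(dir, "nrc.tsv"),
                            file.path(dir, "afinn.tsv"),
                            file.path(dir, "bing.tsv"))
  f <- sentiment_features("joy", lex)
  expect_length(f, 15L)
  expect_equal(unname(f["nrc_joy"]), 1)
  expect_equal(unname(f["nrc_positive"]), 1)
  expect_equal(unname(f["nrc_total"]), 1)
  expect_equal(unname(f["afinn_sum"]), 3)
  expect_equal(unname(f[c("bing_positive", "bing_negative", "bing_net")]),
               c(1, 0, 1))
  expect_equal(sum(sentiment_features(c("neutral", "words"), lex)), 0)
  expect_error(sentiment_lexicons("no/such/file.tsv",
                                  file.path(dir, "afinn.tsv"),
                                  file.path(dir, "bing.tsv")),
               "configuration")
  # brute-force per-token lookups on random snippets
  set.seed(25)
  voc <- c("joy", "fear", "plain", "other")
  for (i in 1:100) {
    tk <- sample(voc, rpois(1, 6), replace = TRUE)
    f <- sentiment_features(tk, lex)
    expect_equal(unname(f["nrc_joy"]), sum(tk == "joy"))
    expect_equal(unname(f["nrc_negative"]), sum(tk == "fear"))
    expect_equal(unname(f["nrc_total"]), sum(tk %in% c("joy", "fear")))
    expect_equal(unname(f["afinn_sum"]), 3 * sum(tk == "joy") -
                   2 * sum(tk == "fear"))
    expect_equal(unname(f["bing_net"]),
                 sum(tk == "joy") - sum(tk == "fear"))
  }
})

test_that("normalization divides the stated families and spares the rest", {
  cfg <- feature_config()
  fam <- c("metadata", "word_usage", "embedding", "pos", "topic",
           "sentiment")
  vals <- c(10, 4, 6, 2, 0.5, 8)
  out <- normalize_features(vals, fam, raw_word_count = 20, cfg)
  expect_equal(out, c(10, 0.2, 0.3, 0.1, 0.5, 0.4))
  # zero word count: divided blocks become zero, no error
  out0 <- normalize_features(vals, fam, raw_word_count = 0, cfg)
  expect_equal(out0, c(10, 0, 0, 0, 0.5, 0))
  # embedding normalization can be disabled
  cfg2 <- feature_config(normalize_embedding = FALSE)
  out2 <- normalize_features(vals, fam, raw_word_count = 20, cfg2)
  expect_equal(out2[3], 6)
})

test_that("assembled vectors follow the analytic schema length", {
  tp <- tiny_pipeline()
  pipe <- tp$pipeline
  n_expected <- 2 + nrow(pipe$vocab) + pipe$config$embedding_dim +
    length(pipe$config$tagset) + pipe$config$n_topics + 2 + 15
  expect_equal(nrow(pipe$schema), n_expected)
  mat <- featurize(tp$snippets, pipe)
  expect_equal(ncol(mat), n_expected)
  expect_equal(nrow(mat), nrow(tp$snippets))
  expect_identical(colnames(mat), pipe$schema$name)
  # snippet order does not change any snippet's vector
  perm <- rev(seq_len(nrow(tp$snippets)))
  mat2 <- featurize(tp$snippets[perm, ], pipe)
  expect_equal(mat2[rownames(mat), ], mat[, ], tolerance = 1e-12)
})

test_that("duplicating a snippet's text leaves normalized counts fixed", {
  tp <- tiny_pipeline()
  pipe <- tp$pipeline
  txt <- "joy food fear eats"
  v1 <- assemble_features(txt, pipe)
  v2 <- assemble_features(paste(txt, txt), pipe)
  wu <- pipe$schema$family == "word_usage"
  expect_equal(v2[wu], v1[wu], tolerance = 1e-12)
  # metadata doubles
  expect_equal(unname(v2["meta_word_count"]),
               2 * unname(v1["meta_word_count"]))
})

test_that("the dimensionality rule of thumb uses a strict inequality", {
  expect_false(dimensionality_guard(1001, 200))
  expect_false(dimensionality_guard(1000, 200))
  expect_true(dimensionality_guard(1000, 310))
})
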