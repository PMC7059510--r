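# shared fixtures, built in code at test time

snippet_df <- function(ids, users, times, texts,
                       classes = "intervention") {
  as_snippets(data.frame(
    snippet_id = ids, user_id = users, timestamp = times, text = texts,
    snippet_class = classes, stringsAsFactors = FALSE))
}

report_df <- function(users, times, values, measure = "binge_episode") {
  as_reports(data.frame(
    user_id = users, timestamp = times, measure_name = measure,
    value = values, stringsAsFactors = FALSE))
}

# small fitted pipeline over a hand-made corpus; every content word of the
# corpus is covered by the fixture embedding/lexicons/tagger
tiny_pipeline <- function(n_topics = 2L, dim = 4L, seed = 42L) {
  texts <- c("joy food food", "she eats food", "fear fear food eats",
             "joy joy she food", "eats fear food", "food she joy eats",
             "fear food joy", "eats eats food she")
  sn <- snippet_df(sprintf("s%02d", seq_along(texts)), "u1",
                   format(as.POSIXct("2023-01-01", tz = "UTC") +
                            3600 * seq_along(texts)),
                   texts)
  words <- c("joy", "food", "she", "eat", "fear")
  fx <- generate_fixtures(words, dim = dim, seed = seed)
  cfg <- feature_config(minocc = 0.01, maxocc = 0.95, embedding_dim = dim,
                        n_topics = n_topics, topic_iter = 60L,
                        stopwords = character())
  tagger <- dictionary_tagger(
    c(she = "PRP", eats = "VBZ", food = "NN", joy = "NN", fear = "NN"))
  pipe <- fit_feature_pipeline(
    sn, cfg, read_embeddings(fx$embeddings),
    sentiment_lexicons(fx$nrc, fx$afinn, fx$bing), tagger, seed = seed)
  list(snippets = sn, pipeline = pipe, fixtures = fx, config = cfg)
}

# brute-force oracles -------------------------------------------------------

oracle_response_rate <- function(senders) {
  n_coach <- sum(senders == "coach")
  if (n_coach == 0L) return(NA_real_)
  hits <- 0L
  for (i in seq_along(senders)) {
    if (senders[i] == "coach" && i < length(senders) &&
        senders[i + 1L] == "user") {
      hits <- hits + 1L
    }
  }
  hits / n_coach
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

oracle_word_counts <- function(tokens, terms) {
  vapply(terms, function(t) sum(tokens == t), numeric(1))
}

rand_senders <- function(n) {
  sample(c("coach", "user"), n, replace = TRUE)
}
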