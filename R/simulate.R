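#' Configuration of the synthetic journey generator
#'
#' Defines a population of simulated intervention users whose lexical
#' content is statistically coupled to a latent binary symptom process, so
#' every pipeline stage can be validated against known ground truth.
#' Per user, a day-resolution two-state Markov chain (activation
#' probability `p_activate`, deactivation `p_deactivate` per day) drives
#' both the symptom reports (the state sampled at report times) and the
#' text: each token is a designated signal term with probability
#' `signal_base_rate`, multiplied by `signal_effect` while the state is
#' active; remaining tokens come from one of several topic blocks (giving
#' the topic model real structure to find) or the background vocabulary.
#' Coach-user threads are generated with a known response probability and
#' exponential response delays. The user-level outcome follows
#' `outcome = alpha * baseline + beta * (mean signal exposure) + N(0, sigma)`.
#'
#' Defaults describe a mid-sized pilot cohort: 50 users over 84 days with
#' on average 40 intervention snippets of 30 words each (about 2000
#' snippets), daily symptom reports, symptomatic episodes lasting about a
#' week, and a coach thread of about 10 exchanges per user.
#'
#' @param n_users number of users.
#' @param snippets_per_user Poisson mean of intervention snippets.
#' @param journey_length_days journey span in days.
#' @param tokens_per_snippet Poisson mean of words per snippet.
#' @param n_background_terms,n_signal_terms,n_topic_blocks,terms_per_block
#'   vocabulary layout.
#' @param signal_base_rate per-token probability of a signal term while
#'   the latent state is inactive.
#' @param signal_effect multiplier on that rate while active; 1 = no
#'   text-symptom coupling (null model).
#' @param p_activate,p_deactivate daily Markov transition probabilities.
#' @param reports_per_day Poisson rate of symptom reports.
#' @param coach_messages_per_user coach messages per thread (mean).
#' @param response_prob probability a coach message draws a user reply.
#' @param response_delay_hours exponential mean of the reply delay.
#' @param outcome_alpha,outcome_beta,outcome_sigma outcome model
#'   coefficients and noise SD.
#' @param baseline_mean,baseline_sd distribution of the baseline severity
#'   score.
#' @param seed master seed; a fixed seed reproduces the corpus exactly.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_users = 50L, snippets_per_user = 40,
                       journey_length_days = 84, tokens_per_snippet = 30,
                       n_background_terms = 150L, n_signal_terms = 10L,
                       n_topic_blocks = 4L, terms_per_block = 15L,
                       signal_base_rate = 0.03, signal_effect = 5,
                       p_activate = 0.10, p_deactivate = 0.15,
                       reports_per_day = 1, coach_messages_per_user = 10,
                       response_prob = 0.7, response_delay_hours = 6,
                       outcome_alpha = 0.6, outcome_beta = 5,
                       outcome_sigma = 0.5,
                       baseline_mean = 3, baseline_sd = 1,
                       seed = 1L) {
  stopifnot(n_users >= 1, snippets_per_user > 0, journey_length_days > 0,
            signal_base_rate > 0, signal_base_rate * signal_effect <= 1,
            signal_effect >= 0,
            p_activate > 0, p_activate < 1, p_deactivate > 0,
            p_deactivate < 1, reports_per_day > 0,
            response_prob >= 0, response_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# stemming-invariant synthetic words: CVCVC over vowels {a,i,o,u} and
# consonants excluding s/e/y-forming endings, so the Porter pipeline is an
# identity on them
.sim_words <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "t", "v", "z")
  vow <- c("a", "i", "o", "u")
  words <- character(0)
  while (length(words) < n) {
    w <- paste0(sample(cons, n - length(words), TRUE),
                sample(vow, n - length(words), TRUE),
                sample(cons, n - length(words), TRUE),
                sample(vow, n - length(words), TRUE),
                sample(cons, n - length(words), TRUE))
    words <- unique(c(words, w))
  }
  words[seq_len(n)]
}

# one user's latent day-state trajectory
.sim_latent <- function(days, p_on, p_off) {
  s <- integer(days + 1L)
  s[1] <- rbinom(1L, 1L, p_on / (p_on + p_off))
  for (d in seq_len(days)) {
    s[d + 1L] <- if (s[d] == 1L) rbinom(1L, 1L, 1 - p_off) else
      rbinom(1L, 1L, p_on)
  }
  s
}

.state_at <- function(latent, day_frac) latent[pmin(floor(day_frac),
                                                    length(latent) - 1L) + 1L]

#' Generate a synthetic intervention corpus with ground truth
#'
#' Draws the full study described by a [sim_config()]: intervention
#' snippets whose signal-term frequency is elevated while the latent
#' symptom state is active, binary `binge_episode` reports equal to the
#' latent state at report times, baseline / follow-up severity reports
#' (`edeq_baseline`, `edeq_followup`), and coach-user message threads.
#'
#' @param config a [sim_config()].
#' @return list with `snippets` (intervention and message snippets),
#'   `reports`, `vocab` (named list of term groups), `tagger_dictionary`
#'   (token -> Penn Treebank tag), and `truth`: per-user latent
#'   trajectories, per-snippet active states and signal-token counts,
#'   per-user mean signal exposure, baselines and outcomes, and the
#'   generating coefficients.
#' @export
generate_corpus <- function(config = sim_config()) {
  cfg <- config
  if (cfg$n_users < 1L || cfg$snippets_per_user <= 0) {
    stop("degenerate config", call. = FALSE)
  }
  set.seed(cfg$seed)
  n_block_terms <- cfg$n_topic_blocks * cfg$terms_per_block
  all_words <- .sim_words(cfg$n_background_terms + cfg$n_signal_terms +
                            n_block_terms)
  background <- all_words[seq_len(cfg$n_background_terms)]
  signal <- all_words[cfg$n_background_terms + seq_len(cfg$n_signal_terms)]
  blocks <- split(all_words[cfg$n_background_terms + cfg$n_signal_terms +
                              seq_len(n_block_terms)],
                  rep(seq_len(cfg$n_topic_blocks),
                      each = cfg$terms_per_block))
  tags <- c("NN", "VB", "JJ", "RB", "PRP", "IN")
  tagger_dictionary <- stats::setNames(rep_len(tags, length(all_words)),
                                       all_words)

  origin <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  snip_rows <- list(); rep_rows <- list()
  latent_list <- list(); snip_truth <- list()
  user_truth <- list()

  for (u in seq_len(cfg$n_users)) {
    uid <- sprintf("u%03d", u)
    latent <- .sim_latent(cfg$journey_length_days, cfg$p_activate,
                          cfg$p_deactivate)
    latent_list[[uid]] <- latent

    n_sn <- max(1L, rpois(1L, cfg$snippets_per_user))
    t_days <- sort(runif(n_sn, 0, cfg$journey_length_days))
    state <- .state_at(latent, t_days)
    n_tok <- pmax(1L, rpois(n_sn, cfg$tokens_per_snippet))
    p_sig <- pmin(1, cfg$signal_base_rate *
                    ifelse(state == 1L, cfg$signal_effect, 1))
    texts <- character(n_sn); sig_count <- integer(n_sn)
    block_of <- sample.int(cfg$n_topic_blocks, n_sn, TRUE)
    for (i in seq_len(n_sn)) {
      is_sig <- runif(n_tok[i]) < p_sig[i]
      sig_count[i] <- sum(is_sig)
      toks <- character(n_tok[i])
      toks[is_sig] <- sample(signal, sig_count[i], TRUE)
      n_rest <- n_tok[i] - sig_count[i]
      if (n_rest > 0L) {
        from_block <- runif(n_rest) < 0.5
        rest <- character(n_rest)
        rest[from_block] <- sample(blocks[[block_of[i]]],
                                   sum(from_block), TRUE)
        rest[!from_block] <- sample(background, sum(!from_block), TRUE)
        toks[!is_sig] <- rest
      }
      texts[i] <- paste(toks, collapse = " ")
    }
    snip_rows[[uid]] <- data.frame(
      snippet_id = sprintf("%s_s%04d", uid, seq_len(n_sn)),
      user_id = uid,
      timestamp = format_timestamp(origin + t_days * 86400),
      text = texts, snippet_class = "intervention",
      stringsAsFactors = FALSE)
    snip_truth[[uid]] <- data.frame(
      snippet_id = sprintf("%s_s%04d", uid, seq_len(n_sn)),
      active = state, signal_tokens = sig_count, n_tokens = n_tok,
      stringsAsFactors = FALSE)

    # symptom reports: latent state sampled at report times
    n_rep <- rpois(1L, cfg$reports_per_day * cfg$journey_length_days)
    r_days <- sort(runif(max(1L, n_rep), 0, cfg$journey_length_days))
    rep_rows[[uid]] <- data.frame(
      user_id = uid,
      timestamp = format_timestamp(origin + r_days * 86400),
      measure_name = "binge_episode",
      value = .state_at(latent, r_days),
      stringsAsFactors = FALSE)

    exposure <- mean(sig_count / n_tok)
    baseline <- rnorm(1L, cfg$baseline_mean, cfg$baseline_sd)
    outcome <- cfg$outcome_alpha * baseline +
      cfg$outcome_beta * exposure + rnorm(1L, 0, cfg$outcome_sigma)
    user_truth[[uid]] <- data.frame(
      user_id = uid, exposure = exposure, baseline = baseline,
      outcome = outcome, stringsAsFactors = FALSE)
    rep_rows[[paste0(uid, "_oc")]] <- data.frame(
      user_id = uid,
      timestamp = format_timestamp(origin + c(0, cfg$journey_length_days)
                                   * 86400),
      measure_name = c("edeq_baseline", "edeq_followup"),
      value = c(baseline, outcome),
      stringsAsFactors = FALSE)
  }

  threads <- .sim_thread_rows(cfg, origin, n_per_user = NULL)
  snippets <- as_snippets(rbind(do.call(rbind, snip_rows),
                                threads$rows))
  reports <- as_reports(do.call(rbind, rep_rows))
  list(
    snippets = snippets, reports = reports,
    vocab = list(background = background, signal = signal,
                 blocks = blocks),
    tagger_dictionary = tagger_dictionary,
    truth = list(latent = latent_list,
                 snippets = do.call(rbind, snip_truth),
                 users = do.call(rbind, user_truth),
                 response_prob = cfg$response_prob,
                 outcome_alpha = cfg$outcome_alpha,
                 outcome_beta = cfg$outcome_beta,
                 outcome_sigma = cfg$outcome_sigma,
                 thread_responses = threads$n_responses,
                 thread_coach = threads$n_coach)
  )
}

# message threads as snippet rows; user replies are placed strictly before
# the next coach message so adjacency reflects the response process
.sim_thread_rows <- function(cfg, origin, n_per_user = NULL) {
  rows <- list(); n_resp <- 0L; n_coach_total <- 0L
  for (u in seq_len(cfg$n_users)) {
    uid <- sprintf("u%03d", u)
    n_coach <- if (is.null(n_per_user)) {
      max(1L, rpois(1L, cfg$coach_messages_per_user))
    } else n_per_user
    c_days <- sort(runif(n_coach, 0, cfg$journey_length_days))
    gaps_h <- c(diff(c_days), Inf) * 24
    k <- 0L
    out <- list()
    for (i in seq_len(n_coach)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        snippet_id = sprintf("%s_mc%03d", uid, i), user_id = uid,
        timestamp = format_timestamp(origin + c_days[i] * 86400),
        text = "coach check-in message",
        snippet_class = "coach_message", stringsAsFactors = FALSE)
      if (runif(1) < cfg$response_prob) {
        delay_h <- rexp(1L, 1 / cfg$response_delay_hours)
        delay_h <- min(delay_h, 0.9 * gaps_h[i], 24 * 7)
        delay_h <- max(delay_h, 1 / 60)
        k <- k + 1L
        out[[k]] <- data.frame(
          snippet_id = sprintf("%s_mu%03d", uid, i), user_id = uid,
          timestamp = format_timestamp(origin +
                                         (c_days[i] + delay_h / 24) * 86400),
          text = "user reply message",
          snippet_class = "user_message", stringsAsFactors = FALSE)
        n_resp <- n_resp + 1L
      }
    }
    n_coach_total <- n_coach_total + n_coach
    rows[[uid]] <- do.call(rbind, out)
  }
  list(rows = do.call(rbind, rows), n_responses = n_resp,
       n_coach = n_coach_total)
}

#' Generate message threads with known response statistics
#'
#' Standalone thread generator: each coach message draws a user reply with
#' the configured probability, and the reply lands strictly before the
#' next coach message, so the empirical [response_rate()] converges to
#' `response_prob` as threads grow.
#'
#' @param config a [sim_config()].
#' @param n_coach_per_user override for the (fixed) number of coach
#'   messages per thread.
#' @return named list of `message_thread` objects with attribute
#'   `n_responses` (generator-side bookkeeping).
#' @export
generate_threads <- function(config = sim_config(),
                             n_coach_per_user = NULL) {
  set.seed(config$seed)
  origin <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
  res <- .sim_thread_rows(config, origin, n_per_user = n_coach_per_user)
  sn <- as_snippets(res$rows)
  th <- extract_threads(build_journeys(sn, NULL))
  attr(th, "n_responses") <- res$n_responses
  attr(th, "n_coach") <- res$n_coach
  th
}

#' Write embedding and lexicon fixtures for a synthetic vocabulary
#'
#' Emits a GloVe-dialect embedding file (unit-norm random vectors over the
#' vocabulary) and NRC/AFINN/Bing-dialect lexicon files assigning known
#' sentiment to designated terms, so featurization runs without any
#' external download. By convention the first quarter of `positive_terms`
#' / `negative_terms` arguments' defaults mirror the generator: topic
#' block 1 terms are positive (joy/trust, AFINN +3), signal terms are
#' negative (sadness/fear, AFINN -3).
#'
#' @param vocab named list with elements `background`, `signal`, `blocks`
#'   (as returned by [generate_corpus()]), or a character vector of words
#'   (then the first half is positive, the rest negative).
#' @param dim embedding dimension.
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the embedding vectors.
#' @return list with paths `embeddings`, `nrc`, `afinn`, `bing`, and the
#'   bookkeeping `positive_terms`, `negative_terms`.
#' @export
generate_fixtures <- function(vocab, dim = 10L, dir = tempfile("fixtures"),
                              seed = 1L) {
  if (is.list(vocab)) {
    words <- unique(c(vocab$background, vocab$signal,
                      unlist(vocab$blocks, use.names = FALSE)))
    positive <- vocab$blocks[[1]]
    negative <- vocab$signal
  } else {
    words <- unique(vocab)
    half <- ceiling(length(words) / 2)
    positive <- words[seq_len(half)]
    negative <- setdiff(words, positive)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  mat <- matrix(rnorm(length(words) * dim), nrow = length(words))
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- words
  p_emb <- file.path(dir, "embeddings.txt")
  write_embeddings(mat, p_emb)

  p_nrc <- file.path(dir, "nrc.tsv")
  nrc <- rbind(
    data.frame(word = positive, category = "joy", flag = 1L),
    data.frame(word = positive, category = "positive", flag = 1L),
    data.frame(word = negative, category = "sadness", flag = 1L),
    data.frame(word = negative[seq_len(ceiling(length(negative) / 2))],
               category = "fear", flag = 1L),
    data.frame(word = negative, category = "negative", flag = 1L))
  utils::write.table(nrc, p_nrc, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)

  p_af <- file.path(dir, "afinn.tsv")
  af <- rbind(data.frame(word = positive, score = 3L),
              data.frame(word = negative, score = -3L))
  utils::write.table(af, p_af, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)

  p_bing <- file.path(dir, "bing.tsv")
  bing <- rbind(data.frame(word = positive, polarity = "positive"),
                data.frame(word = negative, polarity = "negative"))
  utils::write.table(bing, p_bing, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)

  list(embeddings = p_emb, nrc = p_nrc, afinn = p_af, bing = p_bing,
       positive_terms = positive, negative_terms = negative)
}

#' Run the full pipeline on a synthetic corpus and report the AUC
#'
#' Convenience wrapper used by validation studies: generates a corpus,
#' featurizes the intervention snippets (with fixture embeddings and
#' lexicons over the synthetic vocabulary), aligns them with the binary
#' symptom reports, fits a snippet-level classifier, and evaluates the
#' held-out AUC.
#'
#' @param config a [sim_config()].
#' @param split_mode `"within_user"` or `"across_user"`.
#' @param algorithm passed to [fit_model_a()].
#' @param feature_cfg a [feature_config()]; the default scales the
#'   embedding and topic dimensions to the synthetic vocabulary
#'   (10 embedding dimensions, 4 topics, intervention-style
#'   MINOCC = 0.005).
#' @param seed seed for split, model and topic fit.
#' @return the `model_a_report` from [evaluate_roc()], with the aligned
#'   row count in `$n_rows`.
#' @export
sim_pipeline_auc <- function(config = sim_config(),
                             split_mode = "within_user",
                             algorithm = "logistic",
                             feature_cfg = NULL, seed = 1L) {
  sim <- generate_corpus(config)
  if (is.null(feature_cfg)) {
    feature_cfg <- feature_config(minocc = 0.005, maxocc = 0.5,
                                  embedding_dim = 10L, n_topics = 4L,
                                  topic_iter = 100L)
  }
  fx <- generate_fixtures(sim$vocab, dim = feature_cfg$embedding_dim,
                          seed = seed)
  emb <- read_embeddings(fx$embeddings)
  lex <- sentiment_lexicons(fx$nrc, fx$afinn, fx$bing)
  tagger <- dictionary_tagger(sim$tagger_dictionary)
  iv <- sim$snippets[sim$snippets$snippet_class == "intervention", ,
                     drop = FALSE]
  pipe <- fit_feature_pipeline(iv, feature_cfg, emb, lex, tagger,
                               seed = seed)
  feats <- featurize(iv, pipe)
  journeys <- build_journeys(sim$snippets, sim$reports)
  aligned <- build_aligned_dataset(journeys, feats, "binge_episode",
                                   mode = "nearest", max_gap_hours = 24)
  split <- make_split(aligned, mode = split_mode, seed = seed)
  y <- aligned$data$label
  if (length(unique(y[split$train_idx])) < 2L ||
      length(unique(y[split$test_idx])) < 2L) {
    stop("degenerate split: a side has a single class", call. = FALSE)
  }
  model <- fit_model_a(aligned$x[split$train_idx, , drop = FALSE],
                       y[split$train_idx], algorithm = algorithm,
                       seed = seed)
  rep <- evaluate_roc(model, aligned$x[split$test_idx, , drop = FALSE],
                      y[split$test_idx])
  rep$n_rows <- nrow(aligned$data)
  rep
}
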