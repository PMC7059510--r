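#' Metadata features: word and character counts
#'
#' Computed on the raw snippet text: the word count is
#' whitespace-delimited, the character count includes everything
#' (punctuation and spaces).
#'
#' @param text a single character string.
#' @return named numeric vector `(meta_word_count, meta_char_count)`.
#' @export
metadata_features <- function(text) {
  text <- if (is.na(text)) "" else text
  t0 <- trimws(text)
  wc <- if (!nzchar(t0)) 0L else length(strsplit(t0, "\\s+")[[1]])
  c(meta_word_count = as.numeric(wc), meta_char_count = nchar(text))
}

#' Feature schema for a fitted pipeline configuration
#'
#' The snippet feature vector is the concatenation, in fixed family order,
#' of: metadata (2), word usage (vocabulary size), embeddings
#' (`embedding_dim`), POS tags (tag inventory size), topics
#' (`n_topics + 2`), and sentiment (15). Under the case-study message
#' configuration (79 vocabulary terms, 50 embedding dimensions, 44 tags,
#' 8 topics) this yields 200 features; the intervention configuration
#' (189 terms) yields 310.
#'
#' @param vocab_terms character vector of vocabulary terms.
#' @param config a [feature_config()].
#' @return data.frame with columns `name` and `family`.
#' @export
feature_schema <- function(vocab_terms, config = feature_config()) {
  fam <- function(names, family) data.frame(name = names, family = family,
                                            stringsAsFactors = FALSE)
  rbind(
    fam(c("meta_word_count", "meta_char_count"), "metadata"),
    fam(paste0("wu_", vocab_terms), "word_usage"),
    fam(paste0("emb_", seq_len(config$embedding_dim)), "embedding"),
    fam(paste0("pos_", config$tagset), "pos"),
    fam(c(paste0("topic_", seq_len(config$n_topics)), "topic_sd",
          "topic_loglik"), "topic"),
    fam(sentiment_feature_names(), "sentiment")
  )
}

#' Normalize feature blocks by the snippet word count
#'
#' Word-usage, embedding, POS and sentiment blocks are divided by the
#' snippet's raw (pre-preprocessing) word count, making snippets of
#' different lengths comparable; metadata and topic blocks are left
#' untouched. A zero word count sets the divided blocks to zero rather
#' than dividing. Which blocks are divided follows the `normalize_*` flags
#' of the config.
#'
#' @param values named numeric feature vector.
#' @param families character vector parallel to `values` naming each
#'   entry's family.
#' @param raw_word_count the snippet's raw word count.
#' @param config a [feature_config()].
#' @return the normalized feature vector.
#' @export
normalize_features <- function(values, families, raw_word_count,
                               config = feature_config()) {
  targets <- c("word_usage", "embedding", "pos",
               "sentiment")[c(config$normalize_word_usage,
                              config$normalize_embedding,
                              config$normalize_pos,
                              config$normalize_sentiment)]
  sel <- families %in% targets
  if (raw_word_count > 0) {
    values[sel] <- values[sel] / raw_word_count
  } else {
    values[sel] <- 0
  }
  values
}

#' Fit the featurization pipeline on a snippet corpus
#'
#' Preprocesses the texts, builds the document-frequency filtered
#' vocabulary, and fits the LDA topic model; embedding table, lexicons and
#' POS tagger are supplied pre-loaded. The returned pipeline object holds
#' everything [featurize()] needs, so the same fitted pipeline can be
#' applied to new snippets of the same corpus type.
#'
#' @param snippets snippet data.frame ([read_snippets()]).
#' @param config a [feature_config()].
#' @param embeddings embedding matrix ([read_embeddings()]).
#' @param lexicons a [sentiment_lexicons()] object.
#' @param tagger POS tagging backend ([dictionary_tagger()]).
#' @param seed seed for the topic model fit.
#' @return object of class `feature_pipeline`.
#' @export
fit_feature_pipeline <- function(snippets, config = feature_config(),
                                 embeddings, lexicons, tagger, seed = 1L) {
  if (ncol(embeddings) != config$embedding_dim) {
    stop(sprintf("embedding table has %d dimensions but config expects %d",
                 ncol(embeddings), config$embedding_dim), call. = FALSE)
  }
  corpus <- preprocess_corpus(snippets$text, config)
  vocab <- build_vocabulary(corpus, config$minocc, config$maxocc)
  topics <- fit_topic_model(corpus, n_topics = config$n_topics, seed = seed,
                            iter = config$topic_iter)
  structure(list(config = config, vocab = vocab, topics = topics,
                 embeddings = embeddings, lexicons = lexicons,
                 tagger = tagger,
                 schema = feature_schema(vocab$term, config)),
            class = "feature_pipeline")
}

#' @export
print.feature_pipeline <- function(x, ...) {
  cat(sprintf("<feature_pipeline: %d features (%d vocabulary terms)>\n",
              nrow(x$schema), nrow(x$vocab)))
  invisible(x)
}

#' Assemble the feature vector of one snippet
#'
#' Concatenates the six family blocks in fixed order (metadata, word
#' usage, embedding, POS, topic, sentiment) and applies word-count
#' normalization. See [feature_schema()] for the layout.
#'
#' @param text the snippet's raw text.
#' @param pipeline a fitted [fit_feature_pipeline()] object.
#' @param tokens optionally, the precomputed `token_list` for `text`.
#' @return named numeric vector of length `nrow(pipeline$schema)`.
#' @export
assemble_features <- function(text, pipeline, tokens = NULL) {
  cfg <- pipeline$config
  if (is.null(tokens)) tokens <- preprocess(text, cfg)
  emb <- embed_snippet(tokens, pipeline$embeddings)
  vals <- c(
    metadata_features(text),
    stats::setNames(as.numeric(word_usage_counts(tokens, pipeline$vocab)),
                    paste0("wu_", pipeline$vocab$term)),
    stats::setNames(as.numeric(emb),
                    paste0("emb_", seq_len(cfg$embedding_dim))),
    stats::setNames(as.numeric(pos_features(text, pipeline$tagger,
                                            cfg$tagset)),
                    paste0("pos_", cfg$tagset)),
    suppressWarnings(topic_features(tokens, pipeline$topics)),
    sentiment_features(tokens, pipeline$lexicons)
  )
  stopifnot(length(vals) == nrow(pipeline$schema))
  normalize_features(vals, pipeline$schema$family, tokens$raw_word_count,
                     cfg)
}

#' Featurize a snippet corpus into a feature matrix
#'
#' Applies [assemble_features()] to every snippet. Each snippet's vector
#' depends only on that snippet and the fitted pipeline, so row order is
#' immaterial. The returned matrix carries the schema and an
#' out-of-vocabulary report (snippets with no embedding-table hit) as
#' attributes.
#'
#' @param snippets snippet data.frame.
#' @param pipeline a fitted `feature_pipeline`.
#' @return numeric matrix, one row per snippet (rownames = snippet ids),
#'   with attributes `schema` (data.frame) and `n_oov_snippets`.
#' @export
featurize <- function(snippets, pipeline) {
  corpus <- preprocess_corpus(snippets$text, pipeline$config)
  n_oov <- 0L
  rows <- lapply(seq_len(nrow(snippets)), function(i) {
    assemble_features(snippets$text[i], pipeline, tokens = corpus[[i]])
  })
  for (i in seq_along(corpus)) {
    idx <- match(tolower(corpus[[i]]$tokens), rownames(pipeline$embeddings))
    if (!any(!is.na(idx))) n_oov <- n_oov + 1L
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- snippets$snippet_id
  attr(mat, "schema") <- pipeline$schema
  attr(mat, "n_oov_snippets") <- n_oov
  if (dimensionality_guard(nrow(mat), ncol(mat))) {
    message(sprintf(paste0("5 x %d features > %d snippets: consider ",
                           "generic dimensionality reduction (e.g. PCA)"),
                    ncol(mat), nrow(mat)))
  }
  mat
}

#' Rule-of-thumb dimensionality guard
#'
#' Flags corpora where five times the feature count exceeds the snippet
#' count, the situation in which generic dimensionality reduction is
#' recommended before modeling. The reduction itself is not performed.
#'
#' @param n_snippets,n_features positive integers.
#' @return TRUE iff `5 * n_features > n_snippets`.
#' @export
dimensionality_guard <- function(n_snippets, n_features) {
  stopifnot(n_snippets > 0, n_features > 0)
  5 * n_features > n_snippets
}

#' Write a feature matrix as CSV with schema header
#' @param mat matrix from [featurize()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(mat, path) {
  df <- data.frame(snippet_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
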