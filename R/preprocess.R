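#' Feature-engineering configuration
#'
#' Collects every tunable of the snippet featurization step. Defaults are
#' the message-corpus configuration of the case study this package is built
#' around: document-frequency bounds MINOCC = 0.05 and MAXOCC = 0.5,
#' 50-dimensional embeddings, 8 LDA topics, and the 44-slot Penn Treebank
#' tag inventory. For intervention-text corpora the study used
#' MINOCC = 0.005.
#'
#' @param minocc,maxocc inclusive document-frequency bounds (proportions of
#'   documents) for a term to enter the word-usage vocabulary.
#' @param embedding_dim dimension of the word-embedding table.
#' @param n_topics number of LDA topics (>= 2).
#' @param tagset POS tag inventory; defaults to [ptb_tagset()] (44 tags).
#' @param ngram_order 1 for unigrams (default), 2 to add adjacent bigrams.
#' @param stem apply Porter stemming during preprocessing.
#' @param stopwords character vector of stop words removed after
#'   lowercasing; defaults to the small English list shipped with the
#'   package.
#' @param synonyms named character vector mapping variant -> base form;
#'   mapped tokens bypass stemming so the base form is preserved verbatim.
#' @param normalize_word_usage,normalize_embedding,normalize_pos,normalize_sentiment
#'   divide the family's block by the snippet's raw word count
#'   (all default TRUE, the study's convention; the embedding block is
#'   already an average, so its normalization can be switched off).
#' @param topic_iter Gibbs sweeps when fitting the topic model.
#' @return object of class `feature_config` (a list).
#' @export
feature_config <- function(minocc = 0.05, maxocc = 0.5,
                           embedding_dim = 50L, n_topics = 8L,
                           tagset = ptb_tagset(), ngram_order = 1L,
                           stem = TRUE, stopwords = default_stopwords(),
                           synonyms = character(),
                           normalize_word_usage = TRUE,
                           normalize_embedding = TRUE,
                           normalize_pos = TRUE,
                           normalize_sentiment = TRUE,
                           topic_iter = 200L) {
  stopifnot(minocc >= 0, maxocc <= 1, minocc < maxocc,
            embedding_dim > 0, n_topics >= 2, length(tagset) > 0,
            ngram_order %in% 1:2)
  structure(list(
    minocc = minocc, maxocc = maxocc,
    embedding_dim = as.integer(embedding_dim),
    n_topics = as.integer(n_topics),
    tagset = tagset, ngram_order = as.integer(ngram_order),
    stem = stem, stopwords = stopwords, synonyms = synonyms,
    normalize_word_usage = normalize_word_usage,
    normalize_embedding = normalize_embedding,
    normalize_pos = normalize_pos,
    normalize_sentiment = normalize_sentiment,
    topic_iter = as.integer(topic_iter)
  ), class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat(sprintf(paste0("<feature_config: minocc=%g maxocc=%g dim=%d topics=%d",
                     " tags=%d ngram=%d>\n"),
              x$minocc, x$maxocc, x$embedding_dim, x$n_topics,
              length(x$tagset), x$ngram_order))
  invisible(x)
}

#' Default English stop-word list
#'
#' @return character vector of common English function words (shipped as
#'   `inst/extdata/stopwords_en.txt`).
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "dhitext")
  if (!nzchar(path)) return(character())
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Read a stop-word list (one word per line)
#' @param path file path.
#' @return character vector.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  trimws(x[nzchar(trimws(x))])
}

#' Read a synonym map (variant<TAB>base, one pair per line)
#' @param path file path.
#' @return named character vector, names are variants.
#' @export
read_synonyms <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) stop("synonym file: malformed line(s) ",
                        paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

# lowercase alphabetic tokenization (apostrophes kept inside words)
tokenize_raw <- function(text) {
  m <- gregexpr("[a-z]+(?:'[a-z]+)*", tolower(text), perl = TRUE)
  regmatches(tolower(text), m)
}

#' Preprocess one text snippet into a token list
#'
#' Tokenizes (lowercase alphabetic tokens), removes stop words, applies the
#' synonym map and Porter stemming, and records the raw word and character
#' counts of the original text (before any removal). Tokens found in the
#' synonym map are replaced by their base form verbatim (not stemmed);
#' all other tokens are stemmed when `config$stem` is TRUE. With
#' `ngram_order = 2`, adjacent-token bigrams (joined with `_`) are appended
#' after the unigram pipeline.
#'
#' @param text a single character string.
#' @param config [feature_config()].
#' @return object of class `token_list`: list with `tokens`,
#'   `raw_word_count`, `raw_char_count`.
#' @export
preprocess <- function(text, config = feature_config()) {
  preprocess_corpus(text, config)[[1]]
}

#' Preprocess a corpus of snippets
#'
#' Vectorized [preprocess()]; stemming is memoized over the corpus's unique
#' tokens.
#'
#' @param texts character vector.
#' @inheritParams preprocess
#' @return list of `token_list` objects, one per element of `texts`.
#' @export
preprocess_corpus <- function(texts, config = feature_config()) {
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  raw_wc <- vapply(texts, function(t) {
    t <- trimws(t)
    if (!nzchar(t)) 0L else length(strsplit(t, "\\s+")[[1]])
  }, integer(1), USE.NAMES = FALSE)
  raw_cc <- nchar(texts)

  toks <- tokenize_raw(texts)
  stop_set <- config$stopwords
  syn <- config$synonyms
  all_tokens <- unlist(toks, use.names = FALSE)
  uq <- unique(all_tokens)
  mapped <- uq
  if (length(syn)) {
    hit <- uq %in% names(syn)
    mapped[hit] <- unname(syn[uq[hit]])
    if (config$stem) mapped[!hit] <- porter_stem(uq[!hit])
  } else if (config$stem) {
    mapped <- porter_stem(uq)
  }
  lut <- stats::setNames(mapped, uq)

  out <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    tk <- toks[[i]]
    if (length(stop_set)) tk <- tk[!tk %in% stop_set]
    tk <- unname(lut[tk])
    if (config$ngram_order == 2L && length(tk) >= 2L) {
      bigrams <- paste(tk[-length(tk)], tk[-1], sep = "_")
      tk <- c(tk, bigrams)
    }
    out[[i]] <- structure(list(tokens = tk,
                               raw_word_count = raw_wc[i],
                               raw_char_count = raw_cc[i]),
                          class = "token_list")
  }
  out
}

#' Build a document-frequency filtered vocabulary
#'
#' Document frequency of a term is the fraction of corpus documents
#' containing it at least once (computed on preprocessed tokens, so
#' filtering operates on the same token space as counting). Terms are
#' retained iff `minocc <= doc_freq <= maxocc`, both bounds inclusive, and
#' sorted lexicographically (C locale) for a deterministic schema.
#'
#' @param corpus list of `token_list` objects ([preprocess_corpus()]).
#' @param minocc,maxocc inclusive document-frequency bounds.
#' @return object of class `dhi_vocabulary`: data.frame with columns
#'   `term`, `doc_freq`; attributes `minocc`, `maxocc`, `n_docs`.
#' @export
build_vocabulary <- function(corpus, minocc = 0.05, maxocc = 0.5) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  if (!(minocc < maxocc)) {
    stop("configuration error: minocc must be < maxocc", call. = FALSE)
  }
  n_docs <- length(corpus)
  per_doc <- lapply(corpus, function(tl) unique(tl$tokens))
  df_tab <- table(unlist(per_doc, use.names = FALSE))
  doc_freq <- as.numeric(df_tab) / n_docs
  term <- names(df_tab)
  keep <- doc_freq >= minocc & doc_freq <= maxocc
  term <- term[keep]; doc_freq <- doc_freq[keep]
  o <- order(term, method = "radix")
  out <- data.frame(term = term[o], doc_freq = doc_freq[o],
                    stringsAsFactors = FALSE)
  attr(out, "minocc") <- minocc
  attr(out, "maxocc") <- maxocc
  attr(out, "n_docs") <- n_docs
  class(out) <- c("dhi_vocabulary", "data.frame")
  out
}

#' Write / read a vocabulary as a two-column TSV (term, doc_freq)
#' @param vocab a `dhi_vocabulary`.
#' @param path file path.
#' @return `path` invisibly (write); a `dhi_vocabulary` (read; bounds are
#'   restored from header comments).
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# minocc=%.17g maxocc=%.17g n_docs=%d",
                     attr(vocab, "minocc"), attr(vocab, "maxocc"),
                     attr(vocab, "n_docs")), con)
  utils::write.table(vocab, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[0-9.eE+-]+", hdr))[[1]]
  out <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  attr(out, "minocc") <- as.numeric(meta[1])
  attr(out, "maxocc") <- as.numeric(meta[2])
  attr(out, "n_docs") <- as.integer(as.numeric(meta[3]))
  class(out) <- c("dhi_vocabulary", "data.frame")
  out
}

#' Count vocabulary terms in a token list
#'
#' @param tokens a `token_list` (or bare character vector of tokens).
#' @param vocab a `dhi_vocabulary`.
#' @return named integer vector of length `nrow(vocab)`; entry i is the
#'   number of occurrences of term i; out-of-vocabulary tokens contribute
#'   nothing.
#' @export
word_usage_counts <- function(tokens, vocab) {
  tk <- if (inherits(tokens, "token_list")) tokens$tokens else tokens
  idx <- match(tk, vocab$term)
  counts <- tabulate(idx[!is.na(idx)], nbins = nrow(vocab))
  stats::setNames(as.integer(counts), vocab$term)
}

#' Distinct-term count per snippet (vocabulary richness diagnostic)
#'
#' Not part of the assembled feature schema; offered as a per-snippet
#' diagnostic.
#'
#' @param corpus list of `token_list` objects.
#' @return integer vector of distinct-token counts.
#' @export
vocabulary_richness <- function(corpus) {
  vapply(corpus, function(tl) length(unique(tl$tokens)), integer(1))
}
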