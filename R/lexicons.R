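.nrc_categories <- c("anger", "anticipation", "disgust", "fear", "joy",
                     "sadness", "surprise", "trust", "positive", "negative")

#' Load the three sentiment lexicons
#'
#' Reads the lexicon set used for the 15-dimensional sentiment feature
#' block. Dialects:
#' \itemize{
#'   \item NRC: `word<TAB>category<TAB>0/1` (category one of the 8 emotions
#'     anger, anticipation, disgust, fear, joy, sadness, surprise, trust,
#'     plus positive and negative; rows flagged 0 are ignored; the flag
#'     column may be omitted).
#'   \item AFINN: `word<TAB>integer` with scores in -5..+5.
#'   \item Bing: `word<TAB>polarity` with polarity `positive` or
#'     `negative`.
#' }
#'
#' @param nrc,afinn,bing file paths; all three are required.
#' @return object of class `sentiment_lexicons`.
#' @export
sentiment_lexicons <- function(nrc, afinn, bing) {
  for (p in c(nrc, afinn, bing)) {
    if (!file.exists(p)) {
      stop("configuration error: lexicon file not found: ", p, call. = FALSE)
    }
  }
  read_tsv2 <- function(path, n_min) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) < n_min)) {
      stop("malformed lexicon file: ", path, call. = FALSE)
    }
    parts
  }
  nrc_rows <- read_tsv2(nrc, 2L)
  nrc_df <- data.frame(
    word = tolower(vapply(nrc_rows, `[`, character(1), 1L)),
    category = vapply(nrc_rows, `[`, character(1), 2L),
    flag = vapply(nrc_rows, function(p)
      if (length(p) >= 3L) as.integer(p[3]) else 1L, integer(1)),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(nrc_df$category), .nrc_categories)
  if (length(bad)) {
    stop("NRC lexicon: unknown category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nrc_df <- nrc_df[nrc_df$flag == 1L, c("word", "category")]

  af_rows <- read_tsv2(afinn, 2L)
  afinn_vec <- stats::setNames(
    as.numeric(vapply(af_rows, `[`, character(1), 2L)),
    tolower(vapply(af_rows, `[`, character(1), 1L)))

  bg_rows <- read_tsv2(bing, 2L)
  bing_vec <- stats::setNames(
    vapply(bg_rows, `[`, character(1), 2L),
    tolower(vapply(bg_rows, `[`, character(1), 1L)))
  if (!all(bing_vec %in% c("positive", "negative"))) {
    stop("Bing lexicon: polarity must be positive/negative", call. = FALSE)
  }
  structure(list(nrc = nrc_df, afinn = afinn_vec, bing = bing_vec,
                 nrc_by_cat = split(nrc_df$word, nrc_df$category)),
            class = "sentiment_lexicons")
}

#' Names of the 15 sentiment features
#' @return character vector: 11 NRC (8 emotions, positive, negative, total
#'   matched), 1 AFINN (score sum), 3 Bing (positive, negative, net).
#' @export
sentiment_feature_names <- function() {
  c(paste0("nrc_", .nrc_categories), "nrc_total",
    "afinn_sum", "bing_positive", "bing_negative", "bing_net")
}

#' Sentiment lexicon features for one snippet
#'
#' Counts lexicon hits over the snippet's tokens (with multiplicity). The
#' NRC block contributes one count per emotion/polarity category plus the
#' number of tokens matched by at least one NRC category; the AFINN block
#' contributes the sum of integer scores of matched tokens; the Bing block
#' contributes positive count, negative count, and their difference.
#'
#' @param tokens a `token_list` or character vector of tokens.
#' @param lexicons a [sentiment_lexicons()] object.
#' @return named numeric vector of length 15
#'   (see [sentiment_feature_names()]).
#' @export
sentiment_features <- function(tokens, lexicons) {
  tk <- if (inherits(tokens, "token_list")) tokens$tokens else tokens
  out <- stats::setNames(numeric(15L), sentiment_feature_names())
  if (length(tk)) {
    nrc <- lexicons$nrc
    by_cat <- lexicons$nrc_by_cat
    if (is.null(by_cat)) by_cat <- split(nrc$word, nrc$category)
    for (cat in .nrc_categories) {
      out[paste0("nrc_", cat)] <- sum(tk %in% by_cat[[cat]])
    }
    out["nrc_total"] <- sum(tk %in% nrc$word)
    af <- lexicons$afinn[tk]
    out["afinn_sum"] <- sum(af, na.rm = TRUE)
    bg <- lexicons$bing[tk]
    out["bing_positive"] <- sum(bg == "positive", na.rm = TRUE)
    out["bing_negative"] <- sum(bg == "negative", na.rm = TRUE)
    out["bing_net"] <- out["bing_positive"] - out["bing_negative"]
  }
  out
}
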