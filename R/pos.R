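#' The Penn Treebank tag inventory (44 slots)
#'
#' The 36 word-level Penn Treebank part-of-speech tags plus 8
#' punctuation/symbol tags, shipped as `inst/extdata/ptb_tags.txt`. This
#' 44-slot inventory fixes the size of the POS feature block.
#'
#' @return character vector of 44 tag labels.
#' @export
ptb_tagset <- function() {
  path <- system.file("extdata", "ptb_tags.txt", package = "dhitext")
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Deterministic dictionary-based POS tagger
#'
#' A tagging backend for [pos_features()]: splits text into lowercase
#' alphabetic tokens and assigns each the tag listed for it in
#' `dictionary`, falling back to `default_tag`. Being a pure lookup it is
#' fully reproducible, which makes it the reference backend for tests and
#' synthetic corpora; any function mapping a character string to a vector
#' of tags can be plugged in instead (e.g. a wrapper around an external
#' statistical tagger).
#'
#' @param dictionary named character vector: token -> tag.
#' @param default_tag tag for tokens absent from the dictionary.
#' @return a function `(text) -> character vector of tags`.
#' @export
dictionary_tagger <- function(dictionary, default_tag = "NN") {
  force(dictionary); force(default_tag)
  function(text) {
    tk <- tokenize_raw(text)[[1]]
    if (!length(tk)) return(character())
    tags <- unname(dictionary[tk])
    tags[is.na(tags)] <- default_tag
    tags
  }
}

#' Read a tagger dictionary (token<TAB>tag, one pair per line)
#' @param path file path.
#' @return named character vector suitable for [dictionary_tagger()].
#' @export
read_tagger_dictionary <- function(path) {
  read_synonyms(path)
}

#' Part-of-speech tag count features
#'
#' Runs the tagging backend on the raw snippet text and counts tags over
#' the fixed inventory. Tags outside the inventory are dropped with a
#' warning; a tagger failure yields a zero row with a warning so the
#' pipeline continues.
#'
#' @param text a single character string.
#' @param tagger tagging backend, e.g. [dictionary_tagger()].
#' @param tagset tag inventory; defaults to [ptb_tagset()].
#' @return named integer vector of length `length(tagset)`.
#' @export
pos_features <- function(text, tagger, tagset = ptb_tagset()) {
  zero <- stats::setNames(integer(length(tagset)), tagset)
  tags <- tryCatch(tagger(text), error = function(e) {
    warning("POS tagger failed on a snippet (", conditionMessage(e),
            "); emitting zeros", call. = FALSE)
    character()
  })
  if (!length(tags)) return(zero)
  idx <- match(tags, tagset)
  if (anyNA(idx)) {
    warning("dropping tag(s) outside the inventory: ",
            paste(unique(tags[is.na(idx)]), collapse = ", "), call. = FALSE)
    idx <- idx[!is.na(idx)]
  }
  counts <- tabulate(idx, nbins = length(tagset))
  stats::setNames(as.integer(counts), tagset)
}
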