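#' Read a word-embedding table in the GloVe text dialect
#'
#' One word per line followed by its vector: space-separated, no header.
#' Lookup is case-normalized (words are lowercased; on duplicates the first
#' entry wins).
#'
#' @param path file path.
#' @return numeric matrix, one row per word (rownames), one column per
#'   dimension.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  dims <- vapply(parts, length, integer(1)) - 1L
  if (!length(parts)) stop("empty embedding file", call. = FALSE)
  if (length(unique(dims)) != 1L) {
    stop("embedding file: inconsistent vector lengths", call. = FALSE)
  }
  words <- tolower(vapply(parts, `[`, character(1), 1L))
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims[1])))
  keep <- !duplicated(words)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- words[keep]
  mat
}

#' Write an embedding table in the GloVe text dialect
#' @param mat numeric matrix with word rownames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(mat, path) {
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format(mat[i, ], scientific = FALSE,
                                     trim = TRUE, digits = 15)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Embed a snippet as the elementwise mean of its word vectors
#'
#' Each in-vocabulary token contributes its embedding row (duplicates
#' weighted by multiplicity); the snippet representation is the elementwise
#' mean. With no in-vocabulary token the zero vector is returned and the
#' `n_matched` attribute is 0, letting callers track the out-of-vocabulary
#' rate.
#'
#' @param tokens a `token_list` or character vector of tokens.
#' @param table embedding matrix from [read_embeddings()].
#' @return numeric vector of length `ncol(table)` with attributes
#'   `n_matched` and `n_oov`.
#' @export
embed_snippet <- function(tokens, table) {
  tk <- if (inherits(tokens, "token_list")) tokens$tokens else tokens
  idx <- match(tolower(tk), rownames(table))
  hit <- idx[!is.na(idx)]
  out <- if (length(hit)) {
    colMeans(table[hit, , drop = FALSE])
  } else {
    numeric(ncol(table))
  }
  attr(out, "n_matched") <- length(hit)
  attr(out, "n_oov") <- length(tk) - length(hit)
  out
}
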