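#' Porter stemming algorithm
#'
#' Reduces English words to a common base form using the classic Porter
#' (1980) suffix-stripping algorithm: five ordered rule steps driven by the
#' consonant--vowel "measure" of the stem. Words of one or two letters are
#' returned unchanged, as the algorithm prescribes.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("eating", "caresses", "ponies", "relational"))
#' @export
porter_stem <- function(words) {
  if (!is.character(words)) stop("`words` must be a character vector")
  uq <- unique(words)
  stems <- vapply(uq, porter_stem_one, character(1), USE.NAMES = FALSE)
  stems[match(words, uq)]
}

# consonant/vowel pattern of a word: TRUE where consonant.
# 'y' is a consonant at position 1 or after a vowel.
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    cons[i] <- if (ch %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (ch == "y") {
      if (i == 1L) TRUE else !cons[i - 1L]
    } else TRUE
  }
  cons
}

# measure m = number of vowel->consonant transitions in [C](VC)^m[V]
.porter_m <- function(stem) {
  if (nchar(stem) == 0L) return(0L)
  cons <- .porter_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  rle_v <- rle(cons)$values
  if (length(rle_v) < 2L) return(0L)
  sum(!rle_v[-length(rle_v)] & rle_v[-1])
}

.porter_has_vowel <- function(stem) {
  nchar(stem) > 0L && any(!.porter_cons(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.porter_dbl_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- .porter_cons(strsplit(word, "", fixed = TRUE)[[1]])
  cons[n]
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  cons <- .porter_cons(strsplit(word, "", fixed = TRUE)[[1]])
  if (!(cons[n - 2L] && !cons[n - 1L] && cons[n])) return(FALSE)
  !(substr(word, n, n) %in% c("w", "x", "y"))
}

.ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n >= k && substr(word, n - k + 1L, n) == suffix
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

porter_stem_one <- function(word) {
  if (is.na(word) || nchar(word) <= 2L) return(word)
  w <- word

  # step 1a
  if (.ends(w, "sses")) w <- .chop(w, 2L)
  else if (.ends(w, "ies")) w <- paste0(.chop(w, 3L), "i")
  else if (.ends(w, "ss")) w <- w
  else if (.ends(w, "s")) w <- .chop(w, 1L)

  # step 1b
  step1b_fix <- FALSE
  if (.ends(w, "eed")) {
    if (.porter_m(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (.ends(w, "ed") && .porter_has_vowel(.chop(w, 2L))) {
    w <- .chop(w, 2L); step1b_fix <- TRUE
  } else if (.ends(w, "ing") && .porter_has_vowel(.chop(w, 3L))) {
    w <- .chop(w, 3L); step1b_fix <- TRUE
  }
  if (step1b_fix) {
    if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_dbl_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, 1L)
    } else if (.porter_m(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c
  if (.ends(w, "y") && .porter_has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # steps 2-4: longest matching suffix only, then test the m condition
  apply_rules <- function(w, rules, min_m) {
    sfx <- names(rules)
    sfx <- sfx[order(-nchar(sfx))]
    for (s in sfx) {
      if (.ends(w, s)) {
        stem <- .chop(w, nchar(s))
        if (.porter_m(stem) > min_m) w <- paste0(stem, rules[[s]])
        return(w)
      }
    }
    w
  }

  w <- apply_rules(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"), 0L)

  w <- apply_rules(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""), 0L)

  # step 4
  sfx4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  sfx4 <- sfx4[order(-nchar(sfx4))]
  for (s in sfx4) {
    if (.ends(w, s)) {
      stem <- .chop(w, nchar(s))
      ok <- .porter_m(stem) > 1L
      if (s == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # step 5a
  if (.ends(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (.porter_m(w) > 1L && .porter_dbl_cons(w) &&
      .ends(w, "l")) {
    w <- .chop(w, 1L)
  }
  w
}
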