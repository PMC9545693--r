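# Porter (1980) suffix-stripping stemmer. Implemented here because the
# advice-annotation pipeline needs word roots for tf-idf and no stemmer is
# otherwise available to the package; follows the original five-step
# algorithm, matching the longest listed suffix within each step.

#' Porter stemmer
#'
#' Reduces English words to their Porter word roots, the token form used
#' throughout the advice-annotation pipeline (e.g. `monitoring` ->
#' `monitor`, `dosing` -> `dose`). Input is lower-cased before stemming;
#' words shorter than three characters are returned unchanged (after
#' lower-casing), as in the original algorithm.
#'
#' @param words Character vector.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("monitoring", "adjusted", "caresses"))
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem1, character(1), USE.NAMES = FALSE)
}

# consonant/vowel mask: TRUE where letter i is a consonant
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- !(chars %in% c("a", "e", "i", "o", "u"))
  if (n == 0) return(logical(0))
  for (i in seq_len(n)) {
    if (chars[i] == "y") {
      cons[i] <- if (i == 1) TRUE else !cons[i - 1]
    }
  }
  cons
}

# measure m of a stem: number of VC sequences
.porter_m <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  cons <- .porter_cons(chars)
  if (length(cons) == 0) return(0L)
  runs <- rle(cons)$values
  # count vowel-run -> consonant-run transitions
  m <- 0L
  for (i in seq_along(runs)[-1]) if (runs[i] && !runs[i - 1]) m <- m + 1L
  m
}

.porter_has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  any(!.porter_cons(chars))
}

# ends with double consonant
.porter_doublec <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- .porter_cons(strsplit(word, "")[[1]])
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.porter_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  chars <- strsplit(stem, "")[[1]]
  cons <- .porter_cons(chars)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(chars[n] %in% c("w", "x", "y"))
}

.ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substr(word, n - s + 1, n) == suffix
}

.chop <- function(word, suffix) substr(word, 1, nchar(word) - nchar(suffix))

# apply the first (longest) matching rule from a list of c(suffix, repl)
# pairs, subject to a measure condition on the stem; returns word unchanged
# if nothing applies
.porter_rules <- function(word, rules, min_m = 1L) {
  for (r in rules) {
    if (.ends(word, r[1])) {
      stem <- .chop(word, r[1])
      if (.porter_m(stem) >= min_m) {
        return(paste0(stem, r[2]))
      }
      return(word)
    }
  }
  word
}

porter_stem1 <- function(word) {
  if (nchar(word) < 3) return(word)

  # step 1a
  if (.ends(word, "sses")) {
    word <- .chop(word, "es")
  } else if (.ends(word, "ies")) {
    word <- paste0(.chop(word, "ies"), "i")
  } else if (!.ends(word, "ss") && .ends(word, "s")) {
    word <- .chop(word, "s")
  }

  # step 1b
  fired <- FALSE
  if (.ends(word, "eed")) {
    stem <- .chop(word, "eed")
    if (.porter_m(stem) > 0) word <- .chop(word, "d")
  } else if (.ends(word, "ed") && .porter_has_vowel(.chop(word, "ed"))) {
    word <- .chop(word, "ed"); fired <- TRUE
  } else if (.ends(word, "ing") && .porter_has_vowel(.chop(word, "ing"))) {
    word <- .chop(word, "ing"); fired <- TRUE
  }
  if (fired) {
    if (.ends(word, "at") || .ends(word, "bl") || .ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_doublec(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- substr(word, 1, nchar(word) - 1)
    } else if (.porter_m(word) == 1 && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c
  if (.ends(word, "y") && .porter_has_vowel(.chop(word, "y"))) {
    word <- paste0(.chop(word, "y"), "i")
  }

  # step 2 (m > 0)
  word <- .porter_rules(word, list(
    c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
    c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
    c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
    c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
    c("iviti", "ive"), c("enci", "ence"), c("anci", "ance"),
    c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("ator", "ate"), c("eli", "e")
  ))

  # step 3 (m > 0)
  word <- .porter_rules(word, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"),
    c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", "")
  ))

  # step 4 (m > 1); "ion" only after s or t
  step4 <- list(
    c("ement", ""), c("ance", ""), c("ence", ""), c("able", ""),
    c("ible", ""), c("ment", ""), c("ant", ""), c("ent", ""),
    c("ism", ""), c("ate", ""), c("iti", ""), c("ous", ""),
    c("ive", ""), c("ize", ""), c("ion", ""), c("al", ""),
    c("er", ""), c("ic", ""), c("ou", "")
  )
  for (r in step4) {
    if (.ends(word, r[1])) {
      stem <- .chop(word, r[1])
      ok <- .porter_m(stem) > 1
      if (r[1] == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) word <- stem
      break
    }
  }

  # step 5a
  if (.ends(word, "e")) {
    stem <- .chop(word, "e")
    m <- .porter_m(stem)
    if (m > 1 || (m == 1 && !.porter_cvc(stem))) word <- stem
  }

  # step 5b
  if (.porter_m(word) > 1 && .porter_doublec(word) &&
      .ends(word, "l")) {
    word <- substr(word, 1, nchar(word) - 1)
  }

  word
}
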