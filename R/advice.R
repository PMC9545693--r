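# Pre-processing of clinical-management texts and tf-idf sentence encoding.

#' The nine clinical-management advice categories
#'
#' Closed vocabulary of advice labels attached to DDI management texts.
#'
#' @return Character vector of the nine category identifiers.
#' @export
advice_categories <- function() {
  c("avoid", "use_with_caution", "space_dosing_times", "wash_out",
    "monitor", "adjust_dose", "modify_administration", "use_alternative",
    "discontinue")
}

#' Blind drug names in a text
#'
#' Lower-cases the text and replaces every occurrence of a lexicon name with
#' a common token, so classifiers cannot key on specific drugs. Multi-word
#' names are matched longest-first at word boundaries, so e.g. a three-word
#' vaccine name is replaced as a whole before any of its constituent words
#' could match a shorter lexicon entry.
#'
#' @param text Character vector.
#' @param drug_lexicon Character vector of drug names (case-insensitive).
#' @param token Replacement token (default `"DRUG"`).
#' @return Character vector of blinded, lower-cased texts (the token keeps
#'   its case).
#' @export
blind_text <- function(text, drug_lexicon, token = "DRUG") {
  out <- tolower(text)
  lex <- tolower(drug_lexicon)
  lex <- lex[order(-nchar(lex))]
  for (name in lex) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", name), "\\b")
    out <- gsub(pat, token, out)
  }
  out
}

#' Split a text into sentences
#'
#' Punctuation-boundary splitter: sentences end at `.`, `!` or `?` followed
#' by whitespace (or end of text). Deliberately simple; see the package
#' vignette for the trade-offs.
#'
#' @param text Character scalar.
#' @return Character vector of trimmed sentences, in order.
#' @export
split_sentences <- function(text) {
  s <- unlist(strsplit(text, "(?<=[.!?])\\s+", perl = TRUE))
  s <- trimws(s)
  s[nzchar(s)]
}

tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  toks[nzchar(toks)]
}

#' Pre-process a management text into blinded, stemmed sentences
#'
#' Full pre-processing chain for advice classification: lower-casing, drug
#' name blinding ([blind_text()]), sentence splitting, tokenisation on
#' non-alphanumeric boundaries (no stop-word removal) and Porter stemming.
#'
#' @param text Character scalar, the free text of one record.
#' @param drug_lexicon Character vector of drug names; must be non-empty
#'   when `blind = TRUE`.
#' @param blind Whether to blind drug names (default TRUE).
#' @return Tibble with one row per sentence: `sentence_index`, `raw_text`,
#'   `blinded_text`, `token_roots` (list column of stems).
#' @export
#' @examples
#' preprocess("Avoid concurrent use of Warfarin.", "warfarin")
preprocess <- function(text, drug_lexicon = character(), blind = TRUE) {
  stopifnot(length(text) == 1)
  if (blind && length(drug_lexicon) == 0) {
    stopf("ddi_empty_lexicon", "drug name blinding requested with an empty lexicon")
  }
  blinded <- if (blind) blind_text(text, drug_lexicon) else tolower(text)
  sents <- split_sentences(blinded)
  tibble::tibble(
    sentence_index = seq_along(sents),
    raw_text = split_sentences(text)[seq_along(sents)],
    blinded_text = sents,
    token_roots = purrr::map(sents, ~ porter_stem(tokenize(.x)))
  )
}

#' Pre-process a sentence corpus table
#'
#' Applies blinding, tokenisation and stemming to an already sentence-level
#' corpus (one row per sentence, as consumed from the corpus CSV).
#'
#' @param corpus Tibble with columns `sentence_id`, `text` (and optionally
#'   `record_id`, `dir`, carried through).
#' @param drug_lexicon Character vector of drug names.
#' @param blind Whether to blind drug names.
#' @return The corpus tibble with added `blinded_text` and `token_roots`
#'   columns.
#' @export
preprocess_corpus <- function(corpus, drug_lexicon = character(), blind = TRUE) {
  stopifnot(all(c("sentence_id", "text") %in% names(corpus)))
  if (blind && length(drug_lexicon) == 0) {
    stopf("ddi_empty_lexicon", "drug name blinding requested with an empty lexicon")
  }
  corpus <- tibble::as_tibble(corpus)
  corpus$blinded_text <- if (blind) blind_text(corpus$text, drug_lexicon) else tolower(corpus$text)
  corpus$token_roots <- purrr::map(corpus$blinded_text, ~ porter_stem(tokenize(.x)))
  corpus
}

#' Fit a tf-idf model over a sentence corpus
#'
#' Records the corpus size `N`, the per-root sentence ("document")
#' frequencies `df(w)` (number of sentences containing the root at least
#' once) and the vocabulary.
#'
#' @param token_lists List of character vectors of token roots, one per
#'   sentence (e.g. the `token_roots` column from [preprocess_corpus()]).
#' @return A `tfidf_model`: list with `N`, `df` (named integer), `vocab`.
#' @export
tfidf_fit <- function(token_lists) {
  if (length(token_lists) == 0) {
    stopf("ddi_empty_corpus", "cannot fit tf-idf on an empty corpus")
  }
  df_tab <- table(unlist(purrr::map(token_lists, unique)))
  vocab <- sort(names(df_tab), method = "radix")
  structure(
    list(
      N = length(token_lists),
      df = stats::setNames(as.integer(df_tab[vocab]), vocab),
      vocab = vocab
    ),
    class = "tfidf_model"
  )
}

#' tf-idf weight vector of one sentence
#'
#' Weighs every vocabulary root `w` in sentence `s` as
#' `tfidf(w, s) = tf(w, s) * log(N / (df(w) + 1))`, where `tf(w, s)` is the
#' relative frequency of `w` among the sentence's tokens, `N` the corpus
#' sentence count and `df(w)` the number of corpus sentences containing `w`.
#' The logarithm is natural (configurable via `log_base`). Out-of-vocabulary
#' roots are ignored. Note the `df + 1` damping makes corpus-universal words
#' carry a small negative weight.
#'
#' @param model A fitted `tfidf_model`.
#' @param tokens Character vector of a sentence's token roots (non-empty).
#' @param log_base Base of the logarithm (default `exp(1)`).
#' @return Named numeric vector over the model vocabulary.
#' @export
tfidf_transform <- function(model, tokens, log_base = exp(1)) {
  stopifnot(inherits(model, "tfidf_model"))
  if (length(tokens) == 0) {
    stopf("ddi_empty_sentence", "cannot encode a sentence with no tokens")
  }
  w <- stats::setNames(numeric(length(model$vocab)), model$vocab)
  known <- tokens[tokens %in% model$vocab]
  if (length(known) > 0) {
    tf <- table(known) / length(tokens)
    idf <- log(model$N / (model$df[names(tf)] + 1), base = log_base)
    w[names(tf)] <- as.numeric(tf) * idf
  }
  w
}

#' tf-idf design matrix of a corpus
#'
#' @param model A fitted `tfidf_model`.
#' @param token_lists List of token-root vectors.
#' @param log_base Base of the logarithm (default natural).
#' @return Numeric matrix, one row per sentence, columns = vocabulary.
#' @export
tfidf_matrix <- function(model, token_lists, log_base = exp(1)) {
  m <- do.call(rbind, purrr::map(token_lists,
                                 ~ tfidf_transform(model, .x, log_base = log_base)))
  rownames(m) <- names(token_lists)
  m
}
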