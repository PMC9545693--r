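# Shared fixtures and independent oracles, all built in code.

toy_scheme <- function() {
  severity_scheme("toy", c("High", "Mid", "Low"), critical = "High")
}

# A random raw table over a small drug universe, with swapped pair orders,
# case jitter and occasional unmapped / non-drug names.
random_raw_table <- function(n_rows, n_drugs = 8, p_bad = 0.1) {
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  bad <- c("mystery compound", "grapefruit juice")
  pool <- c(drugs, if (p_bad > 0) bad)
  w <- c(rep((1 - p_bad) / n_drugs, n_drugs), if (p_bad > 0) rep(p_bad / 2, 2))
  d1 <- sample(pool, n_rows, replace = TRUE, prob = w)
  d2 <- sample(pool, n_rows, replace = TRUE, prob = w)
  jitter_case <- function(x) ifelse(runif(length(x)) < 0.3, toupper(x), x)
  tibble::tibble(
    dir = "toy",
    drug_1 = jitter_case(d1),
    drug_2 = jitter_case(d2),
    severity = sample(c("High", "Mid", "Low", NA), n_rows, replace = TRUE),
    evidence = NA_character_,
    advice_text = NA_character_
  )
}

toy_mapping <- function(n_drugs = 8) {
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  dplyr::bind_rows(
    identity_mapping(c(drugs, toupper(drugs))),
    tibble::tibble(raw_name = c("mystery compound", "MYSTERY COMPOUND"),
                   status = "UNMAPPED", concept_name = NA),
    tibble::tibble(raw_name = c("grapefruit juice", "GRAPEFRUIT JUICE"),
                   status = "NON_DRUG", concept_name = NA)
  ) |>
    dplyr::mutate(concept_name = ifelse(status == "DRUG",
                                        tolower(concept_name), concept_name))
}

# Brute-force merge oracle: plain loops, no shared code with normalize_table.
oracle_merge <- function(raw, mapping, scheme) {
  status <- function(nm) {
    i <- match(nm, mapping$raw_name)
    if (is.na(i)) "UNMAPPED" else mapping$status[i]
  }
  concept <- function(nm) mapping$concept_name[match(nm, mapping$raw_name)]
  out <- list()
  for (i in seq_len(nrow(raw))) {
    s1 <- status(raw$drug_1[i]); s2 <- status(raw$drug_2[i])
    if (s1 != "DRUG" || s2 != "DRUG") next
    a <- concept(raw$drug_1[i]); b <- concept(raw$drug_2[i])
    if (tolower(a) == tolower(b)) next
    key <- paste(sort(c(a, b), method = "radix"), collapse = " || ")
    r <- if (is.na(raw$severity[i])) integer() else match(raw$severity[i], scheme$levels)
    out[[key]] <- sort(unique(c(out[[key]], r)))
  }
  out
}

# Brute-force 7-region counts from three key vectors.
oracle_venn <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  reg <- integer(7)
  for (p in u) {
    ina <- p %in% a; inb <- p %in% b; inc <- p %in% c_
    k <- if (ina && !inb && !inc) 1 else if (!ina && inb && !inc) 2 else
      if (!ina && !inb && inc) 3 else if (ina && inb && !inc) 4 else
      if (ina && !inb && inc) 5 else if (!ina && inb && inc) 6 else 7
    reg[k] <- reg[k] + 1L
  }
  reg
}

random_key_sets <- function(n_universe = 40, p = c(0.4, 0.4, 0.4)) {
  u <- sprintf("p%03d", seq_len(n_universe))
  list(
    a = u[runif(n_universe) < p[1]],
    b = u[runif(n_universe) < p[2]],
    c = u[runif(n_universe) < p[3]]
  )
}

# Build a dir_table directly from a key -> (severity label, evidence) layout,
# bypassing ingestion, for concordance unit tests.
make_dir_table <- function(dir_id, pairs, severity = NULL, evidence = NULL,
                           scheme = default_severity_schemes()[[dir_id]]) {
  ab <- strsplit(pairs, " \\|\\| ")
  rec <- tibble::tibble(
    ingredient_a = vapply(ab, `[`, "", 1),
    ingredient_b = vapply(ab, `[`, "", 2),
    pair = pairs,
    severity = if (is.null(severity)) NA_integer_ else match(severity, scheme$levels),
    severity_set = lapply(seq_along(pairs), function(i) integer()),
    evidence = evidence %||% NA_character_,
    advice_texts = lapply(seq_along(pairs), function(i) character()),
    provenance = as.list(seq_along(pairs))
  )
  rec$severity_label <- ifelse(is.na(rec$severity), NA, scheme$levels[rec$severity])
  ddiconcord:::new_dir_table(dir_id, rec,
                             exclusions = c(unmapped = 0, non_drug = 0, self_pair = 0),
                             n_input = length(pairs))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent literal tf-idf evaluation (used as the formula oracle).
oracle_tfidf <- function(token_lists, sentence_tokens) {
  N <- length(token_lists)
  vocab <- sort(unique(unlist(token_lists)), method = "radix")
  sapply(vocab, function(w) {
    df <- sum(vapply(token_lists, function(s) w %in% s, logical(1)))
    tf <- sum(sentence_tokens == w) / length(sentence_tokens)
    tf * log(N / (df + 1))
  })
}
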