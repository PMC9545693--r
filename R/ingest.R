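# Ingestion of raw DIR tables: name normalisation, drug-class expansion,
# canonicalisation of unordered pairs, and duplicate merging.

#' Canonicalise an interacting drug pair
#'
#' Interacting pairs are unordered: (D1, D2) and (D2, D1) refer to the same
#' DDI. The canonical form sorts the two identifiers under a fixed
#' case-insensitive byte-wise collation (locale-independent), so every
#' representation of the same pair is identical. Self-pairs are rejected:
#' an ingredient cannot interact with itself at this level of description.
#'
#' @param name_a,name_b Ingredient identifiers (non-empty strings).
#' @return Character vector of length 2, `c(ingredient_a, ingredient_b)` with
#'   `ingredient_a` ordered before `ingredient_b`.
#' @export
#' @examples
#' canonicalize_pair("warfarin", "aspirin")
canonicalize_pair <- function(name_a, name_b) {
  stopifnot(length(name_a) == 1, length(name_b) == 1,
            nzchar(name_a), nzchar(name_b))
  if (tolower(name_a) == tolower(name_b)) {
    stopf("ddi_self_pair", "self-pair rejected: %s", name_a)
  }
  v <- c(name_a, name_b)
  v[order(tolower(v), v, method = "radix")]
}

# Vectorised canonical ordering over parallel name vectors. Returns a list
# with columns a, b (canonically ordered) and logical `self` marking rows
# whose two members coincide (case-insensitively).
canonical_order <- function(x, y) {
  lx <- tolower(x)
  ly <- tolower(y)
  lev <- sort(unique(c(lx, ly)), method = "radix")
  swap <- match(lx, lev) > match(ly, lev)
  list(
    a = ifelse(swap, y, x),
    b = ifelse(swap, x, y),
    self = lx == ly
  )
}

pair_key <- function(a, b) paste(a, b, sep = " || ")

#' Expand drug-class rows into ingredient-level rows
#'
#' Some resources state DDIs at the drug-class level (e.g. "beta blockers"
#' with verapamil). Each class-level row is replaced by one row per class
#' member (a Cartesian product if both sides are classes), inheriting the
#' row's severity, evidence and advice fields. Names are recognised as
#' classes by membership in the class mapping; all other rows pass through
#' unchanged. A class that maps to no members raises a warning and the row
#' is dropped.
#'
#' @param records Tibble of raw DDI rows with at least columns `drug_1`,
#'   `drug_2` (other columns are carried along).
#' @param classes Class mapping as returned by [read_class_mapping()]: a
#'   named list, class name -> character vector of member names.
#' @return Tibble of the same shape with class rows expanded.
#' @export
expand_classes <- function(records, classes) {
  stopifnot(is.data.frame(records), all(c("drug_1", "drug_2") %in% names(records)))
  if (length(classes) == 0 || nrow(records) == 0) {
    return(tibble::as_tibble(records))
  }
  members <- function(name) {
    if (name %in% names(classes)) classes[[name]] else name
  }
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    m1 <- members(row$drug_1)
    m2 <- members(row$drug_2)
    if (length(m1) == 0 || length(m2) == 0) {
      warnf("class row %s - %s expands to no members; dropped",
            row$drug_1, row$drug_2)
      return(records[0, ])
    }
    grid <- expand.grid(drug_1 = m1, drug_2 = m2,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    expanded <- row[rep(1, nrow(grid)), ]
    expanded$drug_1 <- grid$drug_1
    expanded$drug_2 <- grid$drug_2
    expanded
  })
  dplyr::bind_rows(out)
}

#' Normalise, canonicalise and merge a raw DIR table
#'
#' Applies the full cleaning sequence of one resource's extracted DDI table:
#' raw names are mapped to normalised ingredient concepts (salt and ester
#' variants collapse onto one ingredient); rows involving an unmapped name
#' or a non-drug interactant (herbs, foods, beverages, tobacco, lab tests)
#' are dropped and counted; pairs are canonicalised so swapped duplicates
#' coincide; rows whose two names normalise to the same ingredient are
#' dropped as self-pairs; and duplicate rows per canonical pair are merged,
#' accumulating all observed severity ranks (resolved to the most severe by
#' [resolve_severity()]), keeping the strongest evidence label, and
#' concatenating advice texts in input order.
#'
#' @param records Tibble of raw rows (`drug_1`, `drug_2`, optional
#'   `severity`, `evidence`, `advice_text`, `description`), already
#'   class-expanded (see [expand_classes()]).
#' @param mapping Name mapping as returned by [read_name_mapping()]; raw
#'   names absent from the mapping are treated as UNMAPPED.
#' @param scheme [severity_scheme()] for the resource; unknown severity
#'   labels are an error (the vocabularies are closed).
#' @param evidence_levels Optional character vector of evidence labels,
#'   strongest first, used to resolve conflicting evidence on merge.
#' @param dir_id Resource identifier stored on the result; defaults to the
#'   scheme's.
#' @return A `dir_table` object: list with `dir_id`; `records`, a tibble with
#'   one row per canonical pair (`ingredient_a`, `ingredient_b`, `pair`,
#'   `severity` rank, `severity_set` list-column, `severity_label`,
#'   `evidence`, `advice_texts` list-column, `provenance` list-column of
#'   input row indices); `ingredient_set`; `exclusions` (counts of rows
#'   dropped as unmapped / non-drug / self-pair); and `n_input`.
#' @export
normalize_table <- function(records, mapping, scheme,
                            evidence_levels = NULL, dir_id = NULL) {
  stopifnot(is.data.frame(records), inherits(scheme, "severity_scheme"))
  dir_id <- dir_id %||% scheme$dir_id
  records <- tibble::as_tibble(records)
  for (col in c("severity", "evidence", "advice_text")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  n_input <- nrow(records)

  if (n_input == 0) {
    return(new_dir_table(dir_id, empty_records(),
                         exclusions = c(unmapped = 0L, non_drug = 0L, self_pair = 0L),
                         n_input = 0L))
  }

  stopifnot(all(nzchar(records$drug_1)), all(nzchar(records$drug_2)))

  m1 <- lookup_mapping(records$drug_1, mapping)
  m2 <- lookup_mapping(records$drug_2, mapping)

  unmapped <- m1$status == "UNMAPPED" | m2$status == "UNMAPPED"
  non_drug <- !unmapped & (m1$status == "NON_DRUG" | m2$status == "NON_DRUG")
  keep <- !unmapped & !non_drug

  ord <- canonical_order(m1$concept[keep], m2$concept[keep])
  kept <- records[keep, ]
  self <- ord$self
  n_self <- sum(self)

  # severity labels validated against the closed vocabulary even on rows that
  # are later dropped as self-pairs: a bad label is a data error regardless
  sev_rank <- severity_rank(kept$severity, scheme)

  surv <- tibble::tibble(
    ingredient_a = ord$a[!self],
    ingredient_b = ord$b[!self],
    severity_rank = sev_rank[!self],
    evidence = kept$evidence[!self],
    advice_text = kept$advice_text[!self],
    row_id = which(keep)[!self]
  )
  surv$pair <- pair_key(surv$ingredient_a, surv$ingredient_b)

  merged <- merge_pairs(surv, scheme, evidence_levels)
  new_dir_table(
    dir_id, merged,
    exclusions = c(unmapped = sum(unmapped), non_drug = sum(non_drug),
                   self_pair = n_self),
    n_input = n_input
  )
}

merge_pairs <- function(surv, scheme, evidence_levels) {
  if (nrow(surv) == 0) return(empty_records())
  surv <- surv[order(match(surv$pair, sort(unique(surv$pair), method = "radix")),
                     surv$row_id), ]
  grp <- split(seq_len(nrow(surv)), factor(surv$pair, levels = unique(surv$pair)))
  rows <- purrr::map(grp, function(idx) {
    g <- surv[idx, ]
    sev_set <- sort(unique(g$severity_rank[!is.na(g$severity_rank)]))
    ev <- g$evidence[!is.na(g$evidence)]
    ev_res <- if (length(ev) == 0) {
      NA_character_
    } else if (is.null(evidence_levels)) {
      ev[[1]]
    } else {
      ev[order(match(ev, evidence_levels))][[1]]
    }
    adv <- g$advice_text[!is.na(g$advice_text) & nzchar(g$advice_text)]
    tibble::tibble(
      ingredient_a = g$ingredient_a[[1]],
      ingredient_b = g$ingredient_b[[1]],
      pair = g$pair[[1]],
      severity = if (length(sev_set)) resolve_severity(sev_set, scheme) else NA_integer_,
      severity_set = list(sev_set),
      evidence = ev_res,
      advice_texts = list(adv),
      provenance = list(g$row_id)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$severity_label <- ifelse(is.na(out$severity), NA_character_,
                               scheme$levels[out$severity])
  out[order(match(out$pair, sort(out$pair, method = "radix"))), ]
}

empty_records <- function() {
  tibble::tibble(
    ingredient_a = character(), ingredient_b = character(), pair = character(),
    severity = integer(), severity_set = list(), evidence = character(),
    advice_texts = list(), provenance = list(), severity_label = character()
  )
}

new_dir_table <- function(dir_id, records, exclusions, n_input) {
  structure(
    list(
      dir_id = dir_id,
      records = records,
      ingredient_set = sort(unique(c(records$ingredient_a, records$ingredient_b)),
                            method = "radix"),
      exclusions = as.integer(exclusions) |> stats::setNames(names(exclusions)),
      n_input = as.integer(n_input)
    ),
    class = "dir_table"
  )
}

#' @export
print.dir_table <- function(x, ...) {
  cat(sprintf("<dir_table %s> %d pairs, %d ingredients (from %d raw rows; dropped: %s)\n",
              x$dir_id, nrow(x$records), length(x$ingredient_set), x$n_input,
              paste(names(x$exclusions), x$exclusions, sep = "=", collapse = ", ")))
  invisible(x)
}

lookup_mapping <- function(names_raw, mapping) {
  i <- match(names_raw, mapping$raw_name)
  status <- ifelse(is.na(i), "UNMAPPED", mapping$status[i])
  concept <- ifelse(is.na(i), NA_character_, mapping$concept_name[i])
  concept[status != "DRUG"] <- NA_character_
  list(status = status, concept = concept)
}

#' Resolve multiple severity ratings to the one kept for analysis
#'
#' Where one DDI carries several severity ratings (class-level mapping or
#' context-dependent ratings), the highest severity is kept. Because levels
#' are ranked in displayed order with 1 the most severe, this is the minimum
#' rank.
#'
#' @param severity_set Non-empty integer vector of severity ranks.
#' @param scheme The [severity_scheme()] the ranks refer to.
#' @return Single integer rank, the most severe in the set.
#' @export
#' @examples
#' resolve_severity(c(2L, 4L), default_severity_schemes()$bnf)
resolve_severity <- function(severity_set, scheme) {
  stopifnot(inherits(scheme, "severity_scheme"))
  if (length(severity_set) == 0) {
    stopf("ddi_empty_severity_set", "cannot resolve an empty severity set")
  }
  if (!all(severity_set %in% seq_along(scheme$levels))) {
    stopf("ddi_unknown_severity", "severity rank outside scheme %s", scheme$dir_id)
  }
  as.integer(min(severity_set))
}

# ---- readers / writers -----------------------------------------------------

#' Read a raw DIR table from CSV
#'
#' Expected columns: `dir`, `drug_1`, `drug_2`, and optionally `severity`,
#' `evidence`, `advice_text`, `description`.
#'
#' @param path CSV file path.
#' @return Tibble of raw rows.
#' @export
read_ddi_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read a drug-name normalisation mapping
#'
#' Three-column CSV `raw_name, status, concept_name` where `status` is one of
#' `DRUG`, `UNMAPPED`, `NON_DRUG`. Raw names not present in the table are
#' treated as UNMAPPED by [normalize_table()] (the lookup is total).
#'
#' @param path CSV file path.
#' @return Tibble with columns `raw_name`, `status`, `concept_name`.
#' @export
read_name_mapping <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  stopifnot(all(c("raw_name", "status") %in% names(m)))
  if (!"concept_name" %in% names(m)) m$concept_name <- NA_character_
  bad <- !m$status %in% c("DRUG", "UNMAPPED", "NON_DRUG")
  if (any(bad)) stopf("ddi_bad_mapping", "unknown mapping status: %s",
                      paste(unique(m$status[bad]), collapse = ", "))
  if (any(m$status == "DRUG" & (is.na(m$concept_name) | !nzchar(m$concept_name)))) {
    stopf("ddi_bad_mapping", "DRUG rows must carry a concept_name")
  }
  m
}

#' Build an identity name mapping
#'
#' Convenience for already-normalised inputs: maps every supplied name to
#' itself as a drug concept.
#'
#' @param names Character vector of ingredient names.
#' @return Mapping tibble as from [read_name_mapping()].
#' @export
identity_mapping <- function(names) {
  tibble::tibble(raw_name = names, status = "DRUG", concept_name = names)
}

#' Read a drug-class membership table
#'
#' Two-column CSV `class_name, member_name`.
#'
#' @param path CSV file path.
#' @param mapping Optional name mapping; members that do not resolve to a
#'   drug concept are dropped with a warning.
#' @return Named list: class name -> character vector of member raw names.
#' @export
read_class_mapping <- function(path, mapping = NULL) {
  cl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  stopifnot(all(c("class_name", "member_name") %in% names(cl)))
  out <- split(cl$member_name, cl$class_name)
  if (!is.null(mapping)) {
    out <- purrr::imap(out, function(members, class) {
      ok <- lookup_mapping(members, mapping)$status == "DRUG"
      if (any(!ok)) {
        warnf("class %s: dropping %d unresolvable member(s)", class, sum(!ok))
      }
      members[ok]
    })
  }
  out
}

#' Serialise a normalised DIR table
#'
#' Writes the per-pair records as CSV (advice texts joined with `" | "`,
#' severity sets with `";"`) and an exclusion report as a JSON sidecar
#' (`<path>.exclusions.json`) with the counts of rows dropped as unmapped,
#' non-drug and self-pair.
#'
#' @param x A `dir_table`.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_dir_table <- function(x, path) {
  stopifnot(inherits(x, "dir_table"))
  rec <- x$records
  flat <- tibble::tibble(
    dir = x$dir_id,
    ingredient_a = rec$ingredient_a,
    ingredient_b = rec$ingredient_b,
    severity = rec$severity_label,
    severity_set = purrr::map_chr(rec$severity_set, paste, collapse = ";"),
    evidence = rec$evidence,
    advice_text = purrr::map_chr(rec$advice_texts, paste, collapse = " | "),
    n_source_rows = purrr::map_int(rec$provenance, length)
  )
  readr::write_csv(flat, path, progress = FALSE)
  jsonlite::write_json(
    list(dir = x$dir_id, n_input = x$n_input, n_pairs = nrow(rec),
         dropped = as.list(x$exclusions)),
    paste0(path, ".exclusions.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(x)
}
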