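# End-to-end orchestration: ingest -> concordance -> (optional) advice
# annotation -> report bundle.

#' Run the full concordance pipeline
#'
#' Executes the complete analysis over three raw resource tables: reads and
#' validates the inputs, expands class-level rows for the configured
#' resource, normalises and merges each table, computes the listing
#' statistics (full and ingredient-restricted Venn partitions, pairwise
#' coverage rates and Jaccard indices), severity cross-tabulations, the
#' evidence cross-tabulation, the critical-severity overlap and the
#' three-way intersection list, and - when an advice section is configured -
#' fits the per-category advice classifiers and annotates the corpus.
#'
#' @param config Named list or path to a YAML file with fields:
#'   `dir_tables` (named list of CSV paths, one per resource),
#'   `mapping` (name-mapping CSV path), optional `classes` (class CSV path)
#'   and `class_dir` (resource to expand, default `"thesaurus"`), optional
#'   `advice` (list with `corpus`, `labels`, `lexicon` paths and optional
#'   `min_ppv`, `cost`), optional `out_dir` (outputs written as CSV/JSON
#'   when set), optional `seed`.
#' @return A report bundle: list with `tables` (the `dir_table`s),
#'   `table3` (per-resource name/ingredient/DDI counts), `venn`,
#'   `venn_restricted`, `pairwise` (coverage/Jaccard tibble), `severity_tabs`,
#'   `severity_summary` (per-resource level counts and percentages),
#'   `evidence_tab` (or NULL), `critical`, `intersection`, and `advice`
#'   (classifier report, annotations and per-record labels, or NULL).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stopf("ddi_config_error", "config file not found: %s", config)
    }
    config <- yaml::read_yaml(config)
  }
  for (f in c("dir_tables", "mapping")) {
    if (is.null(config[[f]])) stopf("ddi_config_error", "config lacks '%s'", f)
  }
  paths <- c(unlist(config$dir_tables), config$mapping, config$classes,
             config$advice$corpus, config$advice$labels, config$advice$lexicon)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stopf("ddi_config_error", "input file(s) not found: %s",
          paste(missing, collapse = ", "))
  }

  schemes <- default_severity_schemes()
  evidence <- default_evidence_schemes()
  mapping <- read_name_mapping(config$mapping)
  classes <- if (!is.null(config$classes)) {
    read_class_mapping(config$classes, mapping)
  } else list()
  class_dir <- config$class_dir %||% "thesaurus"

  tables <- purrr::imap(config$dir_tables, function(path, d) {
    raw <- read_ddi_table(path)
    if (d == class_dir && length(classes)) raw <- expand_classes(raw, classes)
    normalize_table(raw, mapping, schemes[[d]],
                    evidence_levels = evidence[[d]], dir_id = d)
  })
  ids <- names(tables)
  stopifnot(length(tables) == 3)

  table3 <- tibble::tibble(
    dir = ids,
    initial_names = purrr::map_int(config$dir_tables, function(p) {
      raw <- read_ddi_table(p)
      length(unique(c(raw$drug_1, raw$drug_2)))
    })[ids],
    normalised_ingredients = purrr::map_int(tables, ~ length(.x$ingredient_set)),
    ddi_count = purrr::map_int(tables, ~ nrow(.x$records)),
    raw_rows = purrr::map_int(tables, "n_input"),
    dropped_unmapped = purrr::map_int(tables, ~ .x$exclusions[["unmapped"]]),
    dropped_non_drug = purrr::map_int(tables, ~ .x$exclusions[["non_drug"]]),
    dropped_self_pair = purrr::map_int(tables, ~ .x$exclusions[["self_pair"]])
  )

  vp <- venn_partition(tables[[1]], tables[[2]], tables[[3]])
  vp_restricted <- ingredient_restricted_partition(tables)

  combos <- utils::combn(ids, 2, simplify = FALSE)
  pairwise <- purrr::map(combos, function(cb) {
    A <- tables[[cb[1]]]; B <- tables[[cb[2]]]
    tibble::tibble(
      dir_a = cb[1], dir_b = cb[2],
      shared = sum(pair_keys(A) %in% pair_keys(B)),
      coverage_of_a_pct = coverage_rate(A, B),
      coverage_of_b_pct = coverage_rate(B, A),
      jaccard = jaccard(A, B)
    )
  }) |> dplyr::bind_rows()

  severity_summary <- purrr::map(tables, function(tb) {
    sch <- schemes[[tb$dir_id]]
    counts <- table(factor(tb$records$severity_label, levels = sch$levels))
    tibble::tibble(
      dir = tb$dir_id, severity = sch$levels, rank = seq_along(sch$levels),
      n = as.integer(counts),
      pct = if (nrow(tb$records) > 0) 100 * as.integer(counts) / nrow(tb$records)
            else NA_real_
    )
  }) |> dplyr::bind_rows()

  severity_tabs <- purrr::map(tables, function(tb) {
    severity_crosstab(tb, tables[setdiff(ids, tb$dir_id)], schemes)
  })

  evidence_tab <- NULL
  if (all(c("bnf", "micromedex") %in% ids)) {
    evidence_tab <- evidence_crosstab(tables$bnf, tables$micromedex, evidence)
  }

  critical <- critical_overlap(tables, schemes)
  intersection <- build_intersection_list(tables)

  advice <- NULL
  if (!is.null(config$advice) && !is.null(config$advice$corpus)) {
    advice <- run_advice_stage(config$advice)
  }

  bundle <- list(
    tables = tables, table3 = table3, venn = vp,
    venn_restricted = vp_restricted, pairwise = pairwise,
    severity_summary = severity_summary, severity_tabs = severity_tabs,
    evidence_tab = evidence_tab, critical = critical,
    intersection = intersection, advice = advice
  )
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

run_advice_stage <- function(cfg) {
  corpus <- readr::read_csv(cfg$corpus, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  labels <- readr::read_csv(cfg$labels, col_types = readr::cols(
    sentence_id = readr::col_character(), category = readr::col_character(),
    label = readr::col_integer()), progress = FALSE)
  lexicon <- readLines(cfg$lexicon)
  min_ppv <- cfg$min_ppv %||% 0.80
  cost <- cfg$cost %||% 1000

  prepped <- preprocess_corpus(corpus, lexicon)
  nonempty <- lengths(prepped$token_roots) > 0
  prepped <- prepped[nonempty, ]
  model <- tfidf_fit(prepped$token_roots)
  x <- tfidf_matrix(model, stats::setNames(prepped$token_roots,
                                           prepped$sentence_id))

  labelled_ids <- unique(labels$sentence_id)
  train_idx <- prepped$sentence_id %in% labelled_ids
  fit <- fit_advice_classifiers(
    x[train_idx, , drop = FALSE], labels,
    sentence_ids = prepped$sentence_id[train_idx],
    min_ppv = min_ppv, cost = cost
  )
  ann <- NULL
  per_record <- NULL
  if (any(purrr::map_chr(fit$classifiers, "status") == "ACTIVE")) {
    ann <- annotate_corpus(fit$classifiers, x, prepped$sentence_id)
    if ("record_id" %in% names(prepped)) {
      per_record <- aggregate_advice(
        ann, prepped[, c("sentence_id", "record_id")]
      )
    }
  }
  list(tfidf = model, classifiers = fit$classifiers, report = fit$report,
       annotations = ann, per_record = per_record)
}

write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_csv(bundle$table3, p("table_counts.csv"), progress = FALSE)
  readr::write_csv(summary(bundle$venn), p("venn_partition.csv"), progress = FALSE)
  readr::write_csv(summary(bundle$venn_restricted),
                   p("venn_partition_ingredient_restricted.csv"), progress = FALSE)
  readr::write_csv(bundle$pairwise, p("pairwise_overlap.csv"), progress = FALSE)
  readr::write_csv(bundle$severity_summary, p("severity_summary.csv"),
                   progress = FALSE)
  for (d in names(bundle$severity_tabs)) {
    readr::write_csv(bundle$severity_tabs[[d]],
                     p(sprintf("severity_crosstab_%s.csv", d)), progress = FALSE)
  }
  if (!is.null(bundle$evidence_tab)) {
    readr::write_csv(bundle$evidence_tab, p("evidence_crosstab.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(critical_sizes = as.list(bundle$critical$critical_sizes),
         pairwise = bundle$critical$pairwise,
         triple_joint = bundle$critical$triple_joint,
         intersection_size = bundle$critical$intersection_size,
         intersection_critical = bundle$critical$intersection_critical),
    p("critical_overlap.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  inter_flat <- bundle$intersection
  for (col in grep("_advice$", names(inter_flat), value = TRUE)) {
    inter_flat[[col]] <- purrr::map_chr(inter_flat[[col]],
                                        ~ paste(.x, collapse = " | "))
  }
  readr::write_csv(inter_flat, p("intersection_list.csv"), progress = FALSE)
  if (!is.null(bundle$advice)) {
    readr::write_csv(bundle$advice$report, p("classifier_report.csv"),
                     progress = FALSE)
    if (!is.null(bundle$advice$annotations)) {
      readr::write_csv(bundle$advice$annotations, p("advice_annotations.csv"),
                       progress = FALSE)
    }
    if (!is.null(bundle$advice$per_record)) {
      flat <- bundle$advice$per_record
      flat$categories <- purrr::map_chr(flat$categories, paste, collapse = ";")
      readr::write_csv(flat, p("advice_per_record.csv"), progress = FALSE)
    }
  }
  invisible(out_dir)
}
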