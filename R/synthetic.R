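# Synthetic three-resource DDI datasets with fully known ground truth.
# Emulates the observable structure of compendium extracts - overlap
# structure, salt-name variants, class-level rows, rating distributions,
# templated advice sentences - not real pharmacology.

#' Simulation configuration for a synthetic three-DIR dataset
#'
#' Defaults describe a desk-scale study: the seven-region overlap structure
#' is the published three-compendium Venn scaled down by a factor of 1000,
#' and the severity/evidence distributions are the published per-resource
#' rating proportions. Rates the literature does not pin down (salt-variant
#' injection, class-level rows, advice noise) use fixed realistic defaults;
#' see the package vignette.
#'
#' @param seed Master seed; every random artifact draws from its own
#'   sub-stream derived from it, so adding one artifact never perturbs the
#'   others.
#' @param n_ingredients Number of synthetic ingredients (`drug0001`...).
#' @param venn_region_sizes Seven non-negative integers: pairs unique to A,
#'   B, C, then shared by exactly AB, AC, BC, then by all three (A = bnf,
#'   B = thesaurus, C = micromedex). Their sum must not exceed
#'   `choose(n_ingredients, 2)`.
#' @param salt_variant_rate Fraction of raw rows emitted twice under two
#'   salt-name variants that collapse under normalisation.
#' @param class_row_rate Fraction of eligible Thesaurus-style row groups
#'   collapsed into a single drug-class row.
#' @param severity_distributions Named list (per dir) of named probability
#'   vectors over that dir's severity labels.
#' @param evidence_distributions Named list (per dir, or absent) of named
#'   probability vectors over evidence labels; the reserved name `none`
#'   yields an unrated row.
#' @param advice_templates Named list: category -> character vector of
#'   sentence templates containing a `{drug}` placeholder.
#' @param advice_noise_rate Fraction of filler (no-advice) sentences in the
#'   advice corpus.
#' @param multi_label_rate Fraction of advice texts carrying two categories.
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(seed = 20200901,
                       n_ingredients = 60,
                       venn_region_sizes = c(29, 19, 46, 8, 7, 5, 7),
                       salt_variant_rate = 0.1,
                       class_row_rate = 0.1,
                       severity_distributions = default_severity_distributions(),
                       evidence_distributions = default_evidence_distributions(),
                       advice_templates = default_advice_templates(),
                       advice_noise_rate = 0.2,
                       multi_label_rate = 0.25) {
  stopifnot(length(venn_region_sizes) == 7, all(venn_region_sizes >= 0))
  if (sum(venn_region_sizes) > choose(n_ingredients, 2)) {
    stopf("ddi_infeasible_config",
          "requested %d pairs but only %d are possible with %d ingredients",
          sum(venn_region_sizes), choose(n_ingredients, 2), n_ingredients)
  }
  for (r in c(salt_variant_rate, class_row_rate, advice_noise_rate, multi_label_rate)) {
    stopifnot(r >= 0, r <= 1)
  }
  schemes <- default_severity_schemes()
  for (d in names(severity_distributions)) {
    p <- severity_distributions[[d]]
    stopifnot(abs(sum(p) - 1) < 1e-8, all(names(p) %in% schemes[[d]]$levels))
  }
  for (d in names(evidence_distributions)) {
    p <- evidence_distributions[[d]]
    stopifnot(abs(sum(p) - 1) < 1e-8)
  }
  structure(
    list(seed = seed, n_ingredients = n_ingredients,
         venn_region_sizes = as.integer(venn_region_sizes),
         salt_variant_rate = salt_variant_rate, class_row_rate = class_row_rate,
         severity_distributions = severity_distributions,
         evidence_distributions = evidence_distributions,
         advice_templates = advice_templates,
         advice_noise_rate = advice_noise_rate,
         multi_label_rate = multi_label_rate),
    class = "sim_config"
  )
}

#' Published per-resource severity proportions used as simulation defaults
#' @return Named list of named probability vectors.
#' @export
default_severity_distributions <- function() {
  list(
    bnf = c(Severe = 0.2456, Moderate = 0.0946, Mild = 0.0051, Unknown = 0.6547),
    thesaurus = c("Contraindicated" = 0.0775, "Not recommended" = 0.3360,
                  "Precautions for use" = 0.2154, "Take into consideration" = 0.3711),
    micromedex = c(Contraindicated = 0.0876, Major = 0.6373,
                   Moderate = 0.2428, Minor = 0.0323)
  )
}

#' Published evidence-rating proportions used as simulation defaults
#'
#' The `none` entry for the BNF-style resource reflects that it rates only
#' about a third of its DDIs; the Thesaurus-style resource has no evidence
#' field at all.
#' @return Named list of named probability vectors.
#' @export
default_evidence_distributions <- function() {
  list(
    bnf = c(Study = 0.1189, Anecdotal = 0.0178, Theoretical = 0.1699, none = 0.6934),
    micromedex = c(Established = 0.0873, Theoretical = 0.7091, Probable = 0.2036)
  )
}

#' Default advice sentence templates
#'
#' Each category has a few template sentences with a `{drug}` placeholder
#' and a characteristic vocabulary, so that a keyword-based oracle (and a
#' trained classifier) can recover the labels.
#' @return Named list: category -> character vector of templates.
#' @export
default_advice_templates <- function() {
  list(
    avoid = c(
      "avoid concurrent use of {drug}.",
      "concomitant administration with {drug} should be avoided.",
      "avoid combining this treatment with {drug}."
    ),
    use_with_caution = c(
      "use {drug} with caution during combined therapy.",
      "caution is advised when {drug} is co-prescribed.",
      "exercise caution if {drug} must be given."
    ),
    space_dosing_times = c(
      "space the dosing times of {drug} by at least four hours.",
      "separate administration times from {drug} by several hours.",
      "stagger the dosing schedule of {drug} and the interacting agent."
    ),
    wash_out = c(
      "allow a wash out period after stopping {drug}.",
      "a washout interval of two weeks is required before starting {drug}.",
      "observe a wash out phase between the two treatments of {drug}."
    ),
    monitor = c(
      "monitor plasma concentrations of {drug} closely.",
      "monitor the patient for toxicity while on {drug}.",
      "clinical and laboratory monitoring of {drug} therapy is recommended."
    ),
    adjust_dose = c(
      "adjust the dose of {drug} as clinically indicated.",
      "a dose reduction of {drug} may be necessary.",
      "dosage adjustment of {drug} should be considered."
    ),
    modify_administration = c(
      "modify the administration route of {drug} if possible.",
      "administer {drug} by an alternative route of administration.",
      "change the method of administration of {drug}."
    ),
    use_alternative = c(
      "consider an alternative agent to {drug}.",
      "an alternative to {drug} is preferred.",
      "switch to an alternative therapy instead of {drug}."
    ),
    discontinue = c(
      "discontinue {drug} if the reaction develops.",
      "treatment with {drug} should be discontinued.",
      "stop {drug} promptly when symptoms occur."
    )
  )
}

.filler_sentences <- c(
  "refer to the product literature for further details.",
  "the clinical relevance of this finding is unclear.",
  "no specific recommendation can be made at this time.",
  "the interaction has been reported in the literature.",
  "limited data are available for this combination."
)

dir_ids <- function() c("bnf", "thesaurus", "micromedex")

ingredient_names <- function(n) sprintf("drug%04d", seq_len(n))

#' Generate the canonical-pair universe of a synthetic study
#'
#' Draws `sum(venn_region_sizes)` distinct unordered ingredient pairs and
#' assigns them to the seven exclusive Venn regions exactly as configured.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List: `sets` (named list of canonical pair-key vectors per dir),
#'   `pairs` (tibble `ingredient_a`, `ingredient_b`, `pair`, `region`), and
#'   `truth` (a `venn_partition` of the configured region sizes).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ing <- ingredient_names(config$n_ingredients)
  total <- sum(config$venn_region_sizes)
  regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  pairs <- with_stream(config$seed, "universe", {
    all_pairs <- t(utils::combn(ing, 2))
    idx <- sample.int(nrow(all_pairs), total)
    chosen <- all_pairs[idx, , drop = FALSE]
    tibble::tibble(
      ingredient_a = chosen[, 1], ingredient_b = chosen[, 2],
      pair = pair_key(chosen[, 1], chosen[, 2]),
      region = rep(regions, times = config$venn_region_sizes)
    )
  })
  membership <- list(
    bnf = c("A", "AB", "AC", "ABC"),
    thesaurus = c("B", "AB", "BC", "ABC"),
    micromedex = c("C", "AC", "BC", "ABC")
  )
  sets <- purrr::map(membership, ~ pairs$pair[pairs$region %in% .x])
  truth <- new_venn_partition(config$venn_region_sizes, dir_ids(),
                              sizes = purrr::map_int(sets, length))
  list(sets = sets, pairs = pairs, truth = truth)
}

#' Emit raw DIR tables (plus mappings) from a generated universe
#'
#' Produces, per resource, the raw rows a scraper would have produced:
#' severity and evidence labels drawn from the configured distributions,
#' advice texts built from the category templates (ground-truth labels
#' recorded), randomly swapped pair order, salt-name variant duplicate rows
#' (e.g. `<drug> tartrate` / `<drug> succinate`, both mapping back to the
#' base ingredient), and - for the Thesaurus-style resource - groups of
#' rows sharing a partner collapsed into drug-class rows with a class
#' membership table. Deterministic given the config seed.
#'
#' @param universe Result of [generate_universe()].
#' @param config The same [sim_config()].
#' @return List: `tables` (named list of raw-row tibbles with columns
#'   `dir`, `drug_1`, `drug_2`, `severity`, `evidence`, `advice_text`),
#'   `mapping` (name-mapping tibble), `classes` (named list of class
#'   members), and `truth` (list with per-dir severity/evidence/advice
#'   ground-truth tibbles and the universe truth).
#' @export
emit_raw_tables <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  schemes <- default_severity_schemes()
  truth_rating <- list()
  tables <- list()

  for (d in dir_ids()) {
    p <- universe$pairs[universe$pairs$pair %in% universe$sets[[d]], ]
    n <- nrow(p)
    sev_dist <- config$severity_distributions[[d]]
    ev_dist <- config$evidence_distributions[[d]]

    sev <- with_stream(config$seed, paste0("severity/", d), {
      if (n > 0) sample(names(sev_dist), n, replace = TRUE, prob = sev_dist)
      else character()
    })
    ev <- if (is.null(ev_dist)) {
      rep(NA_character_, n)
    } else {
      with_stream(config$seed, paste0("evidence/", d), {
        e <- if (n > 0) sample(names(ev_dist), n, replace = TRUE, prob = ev_dist)
        else character()
        ifelse(e == "none", NA_character_, e)
      })
    }

    adv <- with_stream(config$seed, paste0("advice/", d), {
      make_advice_texts(n, p$ingredient_a, config)
    })

    truth_rating[[d]] <- tibble::tibble(
      pair = p$pair, severity = sev, evidence = ev,
      advice_categories = adv$labels
    )

    tab <- tibble::tibble(
      dir = d, drug_1 = p$ingredient_a, drug_2 = p$ingredient_b,
      severity = sev, evidence = ev, advice_text = adv$texts,
      pair = p$pair
    )
    tables[[d]] <- tab
  }

  # class-level rows (Thesaurus-style resource only)
  classes <- list()
  if (config$class_row_rate > 0 && nrow(tables$thesaurus) > 0) {
    res <- with_stream(config$seed, "classes", {
      collapse_class_rows(tables$thesaurus, config$class_row_rate)
    })
    tables$thesaurus <- res$table
    classes <- res$classes
    # class members inherit the class row's single severity rating and its
    # advice text (and thus the anchor row's true advice labels)
    i <- match(res$overridden$pair, truth_rating$thesaurus$pair)
    j <- match(res$overridden$anchor_pair, truth_rating$thesaurus$pair)
    truth_rating$thesaurus$severity[i] <- res$overridden$severity
    truth_rating$thesaurus$advice_categories[i] <-
      truth_rating$thesaurus$advice_categories[j]
  }

  # salt-name variant duplicate rows + mapping table
  base_names <- ingredient_names(config$n_ingredients)
  variant_map <- character()
  for (d in dir_ids()) {
    tab <- tables[[d]]
    if (nrow(tab) == 0 || config$salt_variant_rate == 0) next
    res <- with_stream(config$seed, paste0("salts/", d), {
      inject_salt_variants(tab, config$salt_variant_rate)
    })
    tables[[d]] <- res$table
    variant_map <- c(variant_map, res$variants)
  }

  # random order swap to exercise canonicalisation
  for (d in dir_ids()) {
    tab <- tables[[d]]
    if (nrow(tab) == 0) next
    tables[[d]] <- with_stream(config$seed, paste0("swap/", d), {
      swap <- stats::runif(nrow(tab)) < 0.5
      tmp <- tab$drug_1[swap]
      tab$drug_1[swap] <- tab$drug_2[swap]
      tab$drug_2[swap] <- tmp
      tab
    })
  }

  variant_map <- variant_map[!duplicated(names(variant_map))]
  mapping <- dplyr::bind_rows(
    identity_mapping(base_names),
    tibble::tibble(raw_name = names(variant_map), status = "DRUG",
                   concept_name = unname(variant_map))
  )

  tables <- purrr::map(tables, ~ dplyr::select(.x, -dplyr::any_of("pair")))
  list(
    tables = tables, mapping = mapping, classes = classes,
    truth = list(venn = universe$truth, pairs = universe$pairs,
                 ratings = truth_rating)
  )
}

# build advice texts for n records; returns texts + list of true label sets
make_advice_texts <- function(n, drug_names, config) {
  if (n == 0) return(list(texts = character(), labels = list()))
  cats <- names(config$advice_templates)
  texts <- character(n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    k <- 1 + (stats::runif(1) < config$multi_label_rate)
    chosen <- sample(cats, k)
    sents <- vapply(chosen, function(cat) {
      tpl <- sample(config$advice_templates[[cat]], 1)
      sub("{drug}", drug_names[i], tpl, fixed = TRUE)
    }, character(1))
    if (stats::runif(1) < config$advice_noise_rate) {
      sents <- c(sents, sample(.filler_sentences, 1))
    }
    texts[i] <- paste(sents, collapse = " ")
    labels[[i]] <- sort(chosen)
  }
  list(texts = texts, labels = labels)
}

# collapse eligible groups of thesaurus rows into class-level rows
collapse_class_rows <- function(tab, rate) {
  groups <- split(seq_len(nrow(tab)), tab$drug_1)
  groups <- groups[lengths(groups) >= 2]
  classes <- list()
  overridden <- tibble::tibble(pair = character(), severity = character(),
                               advice_text = character(), anchor_pair = character())
  drop <- integer()
  add <- list()
  ci <- 0L
  for (g in groups) {
    if (stats::runif(1) >= rate) next
    ci <- ci + 1L
    cname <- sprintf("class%03d", ci)
    members <- tab$drug_2[g]
    classes[[cname]] <- members
    anchor <- tab$drug_1[g[1]]
    sev <- tab$severity[g[1]]
    adv <- tab$advice_text[g[1]]
    add[[ci]] <- tibble::tibble(
      dir = tab$dir[g[1]], drug_1 = anchor, drug_2 = cname,
      severity = sev, evidence = NA_character_, advice_text = adv,
      pair = NA_character_
    )
    overridden <- dplyr::bind_rows(
      overridden,
      tibble::tibble(pair = tab$pair[g], severity = sev,
                     advice_text = adv, anchor_pair = tab$pair[g[1]])
    )
    drop <- c(drop, g)
  }
  if (length(drop)) {
    tab <- dplyr::bind_rows(tab[-drop, ], dplyr::bind_rows(add))
  }
  list(table = tab, classes = classes, overridden = overridden)
}

# duplicate a fraction of rows under two salt-name variants of drug_1
inject_salt_variants <- function(tab, rate) {
  pick <- which(stats::runif(nrow(tab)) < rate &
                  grepl("^drug[0-9]+$", tab$drug_1))
  variants <- character()
  if (length(pick)) {
    dup <- tab[pick, ]
    v1 <- paste(tab$drug_1[pick], "tartrate")
    v2 <- paste(dup$drug_1, "succinate")
    variants <- stats::setNames(c(tab$drug_1[pick], dup$drug_1), c(v1, v2))
    tab$drug_1[pick] <- v1
    dup$drug_1 <- v2
    tab <- dplyr::bind_rows(tab, dup)
  }
  list(table = tab, variants = variants)
}

#' Emit a labelled advice-sentence corpus
#'
#' Generates template-based advice sentences with known multi-label ground
#' truth: each non-noise sentence realises one category template (two joined
#' with "and" for multi-label sentences); a configured fraction are filler
#' sentences with an empty label set. Drug placeholders are filled with
#' synthetic ingredient names so that blinding is exercised. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()]; every category must have at least one
#'   template.
#' @param n_sentences Corpus size (default 400).
#' @return List: `corpus` tibble (`sentence_id`, `record_id`, `dir`,
#'   `text`), `labels` long tibble (`sentence_id`, `category`, `label`), and
#'   `lexicon` (the drug names used).
#' @export
emit_advice_corpus <- function(config, n_sentences = 400) {
  stopifnot(inherits(config, "sim_config"))
  cats <- advice_categories()
  missing <- setdiff(cats, names(config$advice_templates))
  if (length(missing)) {
    stopf("ddi_missing_template", "no template for categories: %s",
          paste(missing, collapse = ", "))
  }
  ing <- ingredient_names(config$n_ingredients)
  with_stream(config$seed, "advice_corpus", {
    ids <- sprintf("s%05d", seq_len(n_sentences))
    texts <- character(n_sentences)
    lab <- matrix(FALSE, n_sentences, length(cats), dimnames = list(ids, cats))
    for (i in seq_len(n_sentences)) {
      if (stats::runif(1) < config$advice_noise_rate) {
        texts[i] <- sample(.filler_sentences, 1)
        next
      }
      k <- 1 + (stats::runif(1) < config$multi_label_rate)
      chosen <- sample(cats, k)
      clauses <- vapply(chosen, function(cat) {
        tpl <- sample(config$advice_templates[[cat]], 1)
        sub("{drug}", sample(ing, 1), tpl, fixed = TRUE)
      }, character(1))
      clauses <- sub("\\.$", "", clauses)
      texts[i] <- paste0(paste(clauses, collapse = " and "), ".")
      lab[i, chosen] <- TRUE
    }
    labels <- tibble::tibble(
      sentence_id = rep(ids, each = length(cats)),
      category = rep(cats, times = n_sentences),
      label = as.integer(t(lab))
    )
    list(
      corpus = tibble::tibble(
        sentence_id = ids,
        record_id = sprintf("r%05d", seq_len(n_sentences)),
        dir = "micromedex", text = texts
      ),
      labels = labels,
      lexicon = ing
    )
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Materialises the generator's outputs in the CSV dialects the ingestion
#' and annotation modules consume: three raw DIR tables, the name mapping,
#' the class table, the advice corpus and labels, the drug lexicon, and the
#' ground truth as JSON.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_sentences Advice corpus size.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_dataset <- function(config, dir, n_sentences = 400) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  uni <- generate_universe(config)
  raw <- emit_raw_tables(uni, config)
  adv <- emit_advice_corpus(config, n_sentences)
  paths <- list()
  for (d in names(raw$tables)) {
    paths[[paste0("table_", d)]] <- file.path(dir, paste0(d, "_raw.csv"))
    readr::write_csv(raw$tables[[d]], paths[[paste0("table_", d)]], na = "",
                     progress = FALSE)
  }
  paths$mapping <- file.path(dir, "name_mapping.csv")
  readr::write_csv(raw$mapping, paths$mapping, progress = FALSE)
  paths$classes <- file.path(dir, "class_mapping.csv")
  cl <- tibble::tibble(
    class_name = rep(names(raw$classes), lengths(raw$classes)),
    member_name = unlist(raw$classes) %||% character()
  )
  readr::write_csv(cl, paths$classes, progress = FALSE)
  paths$corpus <- file.path(dir, "advice_corpus.csv")
  readr::write_csv(adv$corpus, paths$corpus, progress = FALSE)
  paths$labels <- file.path(dir, "advice_labels.csv")
  readr::write_csv(adv$labels, paths$labels, progress = FALSE)
  paths$lexicon <- file.path(dir, "drug_lexicon.txt")
  writeLines(adv$lexicon, paths$lexicon)
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(
      venn_regions = as.list(stats::setNames(as.integer(raw$truth$venn),
                                             names(raw$truth$venn))),
      ratings = purrr::map(raw$truth$ratings, function(t) {
        t$advice_categories <- purrr::map(t$advice_categories, ~ .x %||% character())
        t
      })
    ),
    paths$truth, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
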