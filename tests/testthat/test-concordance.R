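test_that("Venn partition handles degenerate and published-count cases", {
  full <- venn_partition("p", "p", "p")
  expect_equal(as.integer(full), c(0, 0, 0, 0, 0, 0, 1))
  disjoint <- venn_partition("p1", "p2", "p3")
  expect_equal(as.integer(disjoint), c(1, 1, 1, 0, 0, 0, 0))
  empty <- venn_partition(character(), character(), character())
  expect_equal(sum(empty), 0)

  # inclusion-exclusion on the published three-compendium counts
  vp <- venn_from_counts(sizes = c(51481, 38037, 65446),
                         pairwise = c(14576, 14433, 11574), triple = 6970)
  expect_equal(as.integer(vp), c(29442, 18857, 46409, 7606, 7463, 4604, 6970))
  expect_equal(sum(vp), 121351)
  expect_error(venn_from_counts(c(10, 10, 10), c(11, 0, 0), 0),
               class = "ddi_infeasible_counts")
})

test_that("Venn partition equals a brute-force region count on random fixtures", {
  withr::with_seed(71, {
    for (rep in 1:20) {
      s <- random_key_sets(sample(10:60, 1), runif(3, 0.2, 0.8))
      vp <- venn_partition(s$a, s$b, s$c)
      expect_equal(as.integer(vp), oracle_venn(s$a, s$b, s$c))
      # inclusion-exclusion identity on the same fixture
      expect_equal(
        sum(vp),
        length(unique(s$a)) + length(unique(s$b)) + length(unique(s$c)) -
          sum(unique(s$a) %in% s$b) - sum(unique(s$a) %in% s$c) -
          sum(unique(s$b) %in% s$c) + sum(unique(s$a) %in% s$b & unique(s$a) %in% s$c)
      )
      # statistics are invariant under reordering of the inputs' rows
      expect_equal(as.integer(venn_partition(sample(s$a), rev(s$b), sample(s$c))),
                   as.integer(vp))
    }
  })
})

test_that("coverage rate and Jaccard match worked examples and their identity", {
  expect_equal(round_half_up(coverage_from_counts(6970, 51481)), 13.54)
  expect_equal(coverage_rate(c("p1", "p2"), c("p1", "p2")), 100)
  expect_equal(round_half_up(coverage_rate(c("p1", "p2", "p3"), "p2")), 33.33)
  expect_error(coverage_rate(character(), "p1"), class = "ddi_empty_reference")

  expect_equal(jaccard(c("p1", "p2"), c("p1", "p2")), 1.0)
  expect_equal(jaccard("p1", "p2"), 0.0)
  expect_equal(jaccard_from_counts(51481, 38037, 14576), 14576 / 74942)
  expect_error(jaccard(character(), character()), class = "ddi_empty_reference")

  withr::with_seed(72, {
    for (rep in 1:10) {
      s <- random_key_sets(30)
      if (length(s$a) == 0) next
      u <- length(unique(c(s$a, s$b)))
      expect_equal(coverage_rate(s$a, s$b),
                   100 * jaccard(s$a, s$b) * u / length(unique(s$a)))
    }
  })
})

test_that("severity cross-tab counts shared pairs per level with a Not-found column", {
  sch <- default_severity_schemes()
  row_tab <- make_dir_table("bnf", c("a || b", "a || c", "b || c"),
                            severity = c("Severe", "Severe", "Moderate"))
  other <- make_dir_table("micromedex", c("a || b", "b || c"),
                          severity = c("Major", "Contraindicated"))
  ct <- severity_crosstab(row_tab, list(other), sch)
  cell <- function(rl, cl) ct$n[ct$row_level == rl & ct$col_level == cl]
  expect_equal(cell("Severe", "Major"), 1L)
  expect_equal(cell("Severe", "Not found"), 1L)
  expect_equal(cell("Moderate", "Contraindicated"), 1L)
  # row totals reproduce the row resource's per-level counts
  totals <- tapply(ct$n, ct$row_level, sum)
  expect_equal(as.integer(totals[c("Severe", "Moderate")]), c(2L, 1L))
  # row percentages sum to 100 within populated rows
  pct <- tapply(ct$row_pct, ct$row_level, sum)
  expect_equal(as.numeric(pct[c("Severe", "Moderate")]), c(100, 100))

  # against an empty comparison resource everything lands in Not found
  none <- make_dir_table("micromedex", character())
  ct0 <- severity_crosstab(row_tab, list(none), sch)
  expect_equal(sum(ct0$n[ct0$col_level != "Not found"]), 0L)
  expect_equal(sum(ct0$n), 3L)
})

test_that("severity cross-tab equals a per-pair brute-force tally on random fixtures", {
  sch <- default_severity_schemes()
  withr::with_seed(73, {
    for (rep in 1:10) {
      keys <- sprintf("x%02d || y%02d", 1:40, 41:80)
      rk <- sample(keys, 40)
      ok <- sample(keys, 25)
      row_tab <- make_dir_table("bnf", rk,
                                severity = sample(sch$bnf$levels, 40, TRUE))
      other <- make_dir_table("thesaurus", ok,
                              severity = sample(sch$thesaurus$levels, 25, TRUE))
      ct <- severity_crosstab(row_tab, list(other), sch)
      for (i in seq_len(nrow(ct))) {
        expected <- 0L
        for (j in seq_along(rk)) {
          if (row_tab$records$severity_label[j] != ct$row_level[i]) next
          pos <- match(rk[j], ok)
          lab <- if (is.na(pos)) "Not found" else other$records$severity_label[pos]
          if (lab == ct$col_level[i]) expected <- expected + 1L
        }
        expect_equal(ct$n[i], expected)
      }
    }
  })
})

test_that("evidence cross-tab buckets unrated rows, reports both coverages and margins", {
  ev <- default_evidence_schemes()
  p <- make_dir_table("bnf", c("a || b", "a || c", "b || d"),
                      evidence = c("Study", NA, "Anecdotal"))
  t_ <- make_dir_table("micromedex", c("a || b", "a || c", "c || d"),
                       evidence = c("Theoretical", "Established", "Probable"))
  ct <- evidence_crosstab(p, t_, ev)
  one <- ct[ct$row_level == "Study" & ct$col_level == "Theoretical", ]
  expect_equal(one$n, 1L)
  expect_equal(one$row_cov_pct, 100)
  expect_equal(one$col_cov_pct, 100)
  expect_equal(ct$n[ct$row_level == "none" & ct$col_level == "Established"], 1L)
  expect_equal(ct$n[ct$row_level == "Anecdotal" & ct$col_level == "Not found"], 1L)
  expect_equal(ct$n[ct$row_level == "Not found" & ct$col_level == "Probable"], 1L)

  # disjoint resources: everything sits in the Not-found margins
  d1 <- make_dir_table("bnf", "a || b", evidence = "Study")
  d2 <- make_dir_table("micromedex", "c || d", evidence = "Probable")
  ct0 <- evidence_crosstab(d1, d2, ev)
  expect_equal(sum(ct0$n[ct0$row_level != "Not found" & ct0$col_level != "Not found"]), 0L)

  # a shared record without evidence in the fully-rated resource is an error
  t_bad <- make_dir_table("micromedex", "a || b", evidence = NA_character_)
  expect_error(evidence_crosstab(d1, t_bad, ev), class = "ddi_missing_evidence")
})

test_that("critical overlap counts joint-critical pairs and is monotone in the critical set", {
  sch <- default_severity_schemes()
  A <- make_dir_table("bnf", c("a || b", "a || c", "b || c", "c || d"),
                      severity = c("Severe", "Severe", "Moderate", "Severe"))
  B <- make_dir_table("thesaurus", c("a || b", "b || c", "c || d"),
                      severity = c("Contraindicated", "Not recommended", "Precautions for use"))
  C <- make_dir_table("micromedex", c("a || b", "a || c", "b || c"),
                      severity = c("Major", "Minor", "Contraindicated"))
  rep_ <- critical_overlap(list(A, B, C), sch)
  expect_equal(unname(rep_$critical_sizes), c(3L, 2L, 2L))
  pw <- rep_$pairwise
  expect_equal(pw$joint[pw$dir_a == "bnf" & pw$dir_b == "thesaurus"], 1L)  # a||b
  expect_equal(pw$joint[pw$dir_a == "bnf" & pw$dir_b == "micromedex"], 1L)
  # thesaurus and micromedex both rate a||b and b||c critical
  expect_equal(pw$joint[pw$dir_a == "thesaurus" & pw$dir_b == "micromedex"], 2L)
  expect_equal(rep_$triple_joint, 1L)
  expect_equal(rep_$intersection_size, 2L)  # a||b, b||c
  expect_true(all(pw$joint <= rep_$critical_sizes[pw$dir_a]))
  expect_true(all(pw$joint <= rep_$critical_sizes[pw$dir_b]))

  # shrinking a critical set never increases joint counts
  sch2 <- sch
  sch2$thesaurus <- severity_scheme("thesaurus", sch$thesaurus$levels,
                                    critical = "Contraindicated")
  rep2 <- critical_overlap(list(A, B, C), sch2)
  expect_true(all(rep2$pairwise$joint <= rep_$pairwise$joint))
  expect_lte(rep2$triple_joint, rep_$triple_joint)

  # no critical pairs anywhere -> all zeros
  A0 <- make_dir_table("bnf", "a || b", severity = "Mild")
  B0 <- make_dir_table("thesaurus", "a || b", severity = "Take into consideration")
  C0 <- make_dir_table("micromedex", "a || b", severity = "Minor")
  rep0 <- critical_overlap(list(A0, B0, C0), sch)
  expect_true(all(rep0$pairwise$joint == 0))
  expect_equal(rep0$triple_joint, 0L)
})

test_that("ingredient-restricted partition filters to the common ingredient subset", {
  # identical ingredient universes: restriction changes nothing
  A <- make_dir_table("bnf", c("a || b", "a || c"), severity = c("Severe", "Mild"))
  B <- make_dir_table("thesaurus", c("a || b", "b || c"),
                      severity = c("Contraindicated", "Precautions for use"))
  C <- make_dir_table("micromedex", c("a || c", "b || c"),
                      severity = c("Major", "Minor"))
  expect_equal(as.integer(ingredient_restricted_partition(list(A, B, C))),
               as.integer(venn_partition(A, B, C)))

  # a pair with an ingredient unique to one resource is excluded, and pairs
  # involving ingredients outside the three-way ingredient intersection drop
  A2 <- make_dir_table("bnf", c("a || b", "a || z"), severity = c("Severe", "Mild"))
  vp <- ingredient_restricted_partition(list(A2, B, C))
  # common ingredients are {a, b}; only "a || b" (in bnf and thesaurus) survives
  expect_equal(as.integer(vp), c(0, 0, 0, 1, 0, 0, 0))

  # random fixture vs filter-then-oracle enumeration
  withr::with_seed(74, {
    ing <- letters[1:8]
    mk <- function(d) {
      prs <- t(utils::combn(ing[runif(8) < 0.8], 2))
      keys <- unique(apply(prs, 1, function(r)
        paste(sort(r, method = "radix"), collapse = " || ")))
      make_dir_table(d, keys,
                     severity = sample(default_severity_schemes()[[d]]$levels,
                                       length(keys), TRUE))
    }
    tabs <- list(mk("bnf"), mk("thesaurus"), mk("micromedex"))
    common <- Reduce(intersect, lapply(tabs, function(t) t$ingredient_set))
    filt <- lapply(tabs, function(t) {
      r <- t$records
      r$pair[r$ingredient_a %in% common & r$ingredient_b %in% common]
    })
    expect_equal(as.integer(ingredient_restricted_partition(tabs)),
                 oracle_venn(filt[[1]], filt[[2]], filt[[3]]))
  })
})

test_that("the intersection list carries the ABC region with all three payloads", {
  A <- make_dir_table("bnf", c("a || b", "a || c"), severity = c("Severe", "Mild"),
                      evidence = c("Study", NA))
  B <- make_dir_table("thesaurus", c("a || b", "b || c"),
                      severity = c("Contraindicated", "Precautions for use"))
  C <- make_dir_table("micromedex", c("a || b", "b || c"),
                      severity = c("Major", "Minor"),
                      evidence = c("Established", "Probable"))
  il <- build_intersection_list(list(A, B, C))
  expect_equal(nrow(il), 1)
  expect_equal(il$pair, "a || b")
  expect_equal(il$bnf_severity, "Severe")
  expect_equal(il$thesaurus_severity, "Contraindicated")
  expect_equal(il$micromedex_evidence, "Established")

  disjoint <- build_intersection_list(list(
    make_dir_table("bnf", "a || b"), make_dir_table("thesaurus", "c || d"),
    make_dir_table("micromedex", "e || f")
  ))
  expect_equal(nrow(disjoint), 0)

  # 7-region structure: the list size equals the ABC region count
  cfg <- sim_config(venn_region_sizes = c(3, 3, 3, 2, 2, 2, 5), n_ingredients = 20)
  uni <- generate_universe(cfg)
  tabs <- purrr::imap(uni$sets, ~ make_dir_table(.y, .x))
  expect_equal(nrow(build_intersection_list(unname(tabs))), 5)
})
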