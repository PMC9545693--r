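# Listing / severity / evidence agreement statistics between DIR tables.

# Accept a dir_table or a plain character vector of pair keys.
pair_keys <- function(x) {
  if (inherits(x, "dir_table")) x$records$pair else as.character(x)
}

#' Exclusive Venn partition of three DDI sets
#'
#' Counts the seven mutually exclusive regions of three sets of canonical
#' pairs: present in exactly one resource, in exactly one of the three
#' pairwise overlaps, or in all three.
#'
#' @param A,B,C `dir_table` objects or character vectors of canonical pair
#'   keys. Empty sets are allowed.
#' @param labels Labels for the three sets (defaults to dir ids or
#'   `c("A","B","C")`).
#' @return A `venn_partition`: named integer vector with components
#'   `A_only`, `B_only`, `C_only`, `AB_only`, `AC_only`, `BC_only`, `ABC`
#'   (names use `labels`), with attributes `labels` and `sizes` (the input
#'   set sizes).
#' @export
venn_partition <- function(A, B, C, labels = NULL) {
  if (is.null(labels)) {
    labels <- c(
      if (inherits(A, "dir_table")) A$dir_id else "A",
      if (inherits(B, "dir_table")) B$dir_id else "B",
      if (inherits(C, "dir_table")) C$dir_id else "C"
    )
  }
  a <- unique(pair_keys(A)); b <- unique(pair_keys(B)); c_ <- unique(pair_keys(C))
  u <- unique(c(a, b, c_))
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c_
  counts <- c(
    sum(in_a & !in_b & !in_c),
    sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c),
    sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c),
    sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c)
  )
  new_venn_partition(counts, labels,
                     sizes = c(length(a), length(b), length(c_)))
}

new_venn_partition <- function(counts, labels, sizes) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 7, all(counts >= 0))
  names(counts) <- c(
    paste0(labels, "_only"),
    paste0(labels[1], "_", labels[2], "_only"),
    paste0(labels[1], "_", labels[3], "_only"),
    paste0(labels[2], "_", labels[3], "_only"),
    paste(labels, collapse = "_")
  )
  structure(counts, labels = labels,
            sizes = stats::setNames(as.integer(sizes), labels),
            class = "venn_partition")
}

#' Reconstruct an exclusive Venn partition from printed set counts
#'
#' Published comparisons usually print the three set sizes, the three
#' pairwise intersection counts (inclusive of the triple region) and the
#' triple intersection. Inclusion-exclusion turns these into the seven
#' exclusive region counts.
#'
#' @param sizes Numeric length 3: |A|, |B|, |C|.
#' @param pairwise Numeric length 3: |A intersect B|, |A intersect C|,
#'   |B intersect C| (each including the triple region).
#' @param triple |A intersect B intersect C|.
#' @param labels Set labels.
#' @return A `venn_partition`.
#' @export
venn_from_counts <- function(sizes, pairwise, triple, labels = c("A", "B", "C")) {
  stopifnot(length(sizes) == 3, length(pairwise) == 3, length(triple) == 1)
  ab <- pairwise[1] - triple
  ac <- pairwise[2] - triple
  bc <- pairwise[3] - triple
  only <- c(
    sizes[1] - pairwise[1] - pairwise[2] + triple,
    sizes[2] - pairwise[1] - pairwise[3] + triple,
    sizes[3] - pairwise[2] - pairwise[3] + triple
  )
  counts <- c(only, ab, ac, bc, triple)
  if (any(counts < 0)) {
    stopf("ddi_infeasible_counts", "printed counts imply a negative region")
  }
  new_venn_partition(counts, labels, sizes)
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> total", sum(x), "\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Summarise a Venn partition
#'
#' @param object A `venn_partition`.
#' @param ... Unused.
#' @return Tibble with one row per region (`region`, `n`) plus derived rows:
#'   total union size, single-resource total, exactly-two total, and the
#'   pairwise intersections in both exclusive and inclusive (of the triple
#'   region) forms, clearly labelled.
#' @export
summary.venn_partition <- function(object, ...) {
  lab <- attr(object, "labels")
  x <- as.integer(object)
  tibble::tibble(
    region = c(names(object), "union_total", "single_resource_total",
               "exactly_two_total",
               paste0(lab[1], "_", lab[2], "_inclusive"),
               paste0(lab[1], "_", lab[3], "_inclusive"),
               paste0(lab[2], "_", lab[3], "_inclusive")),
    n = c(x, sum(x), sum(x[1:3]), sum(x[4:6]),
          x[4] + x[7], x[5] + x[7], x[6] + x[7])
  )
}

#' Coverage rate of one set by another
#'
#' The percentage of set A's members that also occur in B,
#' `100 * |A intersect B| / |A|`. Directional: `coverage_rate(A, B)` reads
#' "how much of A is covered by B". Full precision is returned; round with
#' [round_half_up()] for presentation.
#'
#' @param A,B `dir_table`s or character vectors of pair keys.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' coverage_rate(c("p1", "p2", "p3"), "p2")
coverage_rate <- function(A, B) {
  a <- unique(pair_keys(A))
  if (length(a) == 0) {
    stopf("ddi_empty_reference", "coverage rate undefined for an empty reference set")
  }
  coverage_from_counts(sum(a %in% unique(pair_keys(B))), length(a))
}

#' Coverage rate from printed counts
#'
#' @param n_shared Intersection count |A intersect B|.
#' @param n_ref Reference set size |A|.
#' @return Percentage `100 * n_shared / n_ref`, full precision.
#' @export
coverage_from_counts <- function(n_shared, n_ref) {
  if (any(n_ref == 0)) {
    stopf("ddi_empty_reference", "coverage rate undefined for an empty reference set")
  }
  100 * n_shared / n_ref
}

#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; symmetric similarity in `[0, 1]`.
#'
#' @param A,B `dir_table`s or character vectors of pair keys.
#' @return Jaccard index.
#' @export
jaccard <- function(A, B) {
  a <- unique(pair_keys(A)); b <- unique(pair_keys(B))
  if (length(a) == 0 && length(b) == 0) {
    stopf("ddi_empty_reference", "Jaccard index undefined when both sets are empty")
  }
  jaccard_from_counts(length(a), length(b), sum(a %in% b))
}

#' Jaccard index from printed counts
#'
#' @param n_a,n_b Set sizes.
#' @param n_ab Intersection size.
#' @return `n_ab / (n_a + n_b - n_ab)`.
#' @export
jaccard_from_counts <- function(n_a, n_b, n_ab) {
  if (any(n_a + n_b - n_ab == 0)) {
    stopf("ddi_empty_reference", "Jaccard index undefined when both sets are empty")
  }
  n_ab / (n_a + n_b - n_ab)
}

#' Severity cross-tabulation of one DIR against the others
#'
#' For each severity level of the row resource, counts how the same pairs
#' are rated by each comparison resource, with an explicit *Not found*
#' column for pairs absent from that resource, and row percentages (share of
#' the row level's total).
#'
#' @param row_dir `dir_table` under consideration (severity-resolved).
#' @param other_dirs List of comparison `dir_table`s.
#' @param schemes Named list of [severity_scheme()]s covering all involved
#'   resources.
#' @return A tibble of class `rating_crosstab`, long format: `row_dir`,
#'   `row_level`, `col_dir`, `col_level` (a severity label or `"Not found"`),
#'   `n`, `row_pct`.
#' @export
severity_crosstab <- function(row_dir, other_dirs, schemes = default_severity_schemes()) {
  stopifnot(inherits(row_dir, "dir_table"))
  row_scheme <- schemes[[row_dir$dir_id]]
  rows <- row_dir$records[!is.na(row_dir$records$severity), ]
  out <- purrr::map(other_dirs, function(other) {
    col_scheme <- schemes[[other$dir_id]]
    col_levels <- c(col_scheme$levels, "Not found")
    i <- match(rows$pair, other$records$pair)
    col_lab <- ifelse(is.na(i), "Not found",
                      other$records$severity_label[i])
    tab <- table(
      factor(row_scheme$levels[rows$severity], levels = row_scheme$levels),
      factor(col_lab, levels = col_levels)
    )
    long <- tibble::as_tibble(tab, .name_repair = "minimal")
    names(long) <- c("row_level", "col_level", "n")
    long$col_dir <- other$dir_id
    row_totals <- as.numeric(rowSums(tab))[match(long$row_level, row_scheme$levels)]
    long$row_pct <- ifelse(row_totals == 0, NA_real_, 100 * long$n / row_totals)
    long
  })
  res <- dplyr::bind_rows(out)
  res <- tibble::tibble(
    row_dir = row_dir$dir_id,
    row_level = res$row_level, col_dir = res$col_dir,
    col_level = res$col_level, n = as.integer(res$n), row_pct = res$row_pct
  )
  class(res) <- c("rating_crosstab", class(res))
  res
}

#' Evidence cross-tabulation between two DIRs
#'
#' Compares evidence (substantiation) ratings between a resource that rates
#' only some of its DDIs (unrated records form an explicit `"none"` level)
#' and one that rates all of them. For every evidence-level pair the shared
#' count and both directional coverage rates are reported; *Not found*
#' margins count pairs of each level absent from the other resource.
#'
#' @param dir_partial `dir_table` with possibly missing evidence.
#' @param dir_total `dir_table` whose every shared record must carry
#'   evidence; a missing one raises a `ddi_missing_evidence` error.
#' @param evidence_levels Named list of evidence vocabularies (strongest
#'   first) keyed by dir id; defaults to [default_evidence_schemes()].
#' @return Tibble of class `rating_crosstab`: `row_dir`, `row_level`
#'   (including `"none"`), `col_dir`, `col_level` (including `"Not found"`),
#'   `n`, `row_cov_pct` (share of the row level), `col_cov_pct` (share of
#'   the column level; NA for the Not-found column), plus reversed-margin
#'   rows (`row_level == "Not found"`) for pairs of `dir_total` absent from
#'   `dir_partial`.
#' @export
evidence_crosstab <- function(dir_partial, dir_total,
                              evidence_levels = default_evidence_schemes()) {
  stopifnot(inherits(dir_partial, "dir_table"), inherits(dir_total, "dir_table"))
  lev_p <- c(evidence_levels[[dir_partial$dir_id]], "none")
  lev_t <- evidence_levels[[dir_total$dir_id]]

  p <- dir_partial$records
  t_ <- dir_total$records
  shared_in_t <- t_$pair %in% p$pair
  if (any(is.na(t_$evidence[shared_in_t]))) {
    stopf("ddi_missing_evidence",
          "%s must carry an evidence rating on every shared record",
          dir_total$dir_id)
  }
  row_lab <- factor(ifelse(is.na(p$evidence), "none", p$evidence), levels = lev_p)
  i <- match(p$pair, t_$pair)
  col_lab <- factor(ifelse(is.na(i), "Not found", t_$evidence[i]),
                    levels = c(lev_t, "Not found"))
  tab <- table(row_lab, col_lab)
  row_totals <- table(row_lab)
  col_totals <- table(factor(t_$evidence, levels = lev_t))

  long <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(long) <- c("row_level", "col_level", "n")
  rt <- as.numeric(row_totals[long$row_level])
  ct_ <- as.numeric(col_totals)[match(long$col_level, lev_t)]
  long$row_cov_pct <- ifelse(rt == 0, NA_real_, 100 * long$n / rt)
  long$col_cov_pct <- ifelse(is.na(ct_) | ct_ == 0, NA_real_, 100 * long$n / ct_)

  # reversed margin: dir_total pairs missing from dir_partial, per level
  missing_t <- table(factor(t_$evidence[!t_$pair %in% p$pair], levels = lev_t))
  rev_rows <- tibble::tibble(
    row_level = "Not found",
    col_level = lev_t,
    n = as.integer(missing_t),
    row_cov_pct = NA_real_,
    col_cov_pct = ifelse(as.numeric(col_totals) == 0, NA_real_,
                         100 * as.numeric(missing_t) / as.numeric(col_totals))
  )
  res <- dplyr::bind_rows(long, rev_rows)
  res <- tibble::tibble(
    row_dir = dir_partial$dir_id, row_level = res$row_level,
    col_dir = dir_total$dir_id, col_level = res$col_level,
    n = as.integer(res$n), row_cov_pct = res$row_cov_pct,
    col_cov_pct = res$col_cov_pct
  )
  class(res) <- c("rating_crosstab", class(res))
  res
}

#' Critical severity overlap between three DIRs
#'
#' A pair is *critical* in a resource when its resolved severity rank falls
#' in that resource's configured critical set. Joint-critical counts require
#' the pair to be listed AND rated critical in both (or all three)
#' resources. Coverages are expressed against each resource's full critical
#' set size; the per-resource critical share of the three-way DDI
#' intersection is also reported.
#'
#' @param tables Named list of three `dir_table`s.
#' @param schemes Named list of [severity_scheme()]s.
#' @return A `critical_overlap` object: list with `critical_sizes` (named),
#'   `pairwise` tibble (`dir_a`, `dir_b`, `joint`, `cov_a_pct`, `cov_b_pct`),
#'   `triple_joint`, `intersection_size`, and `intersection_critical` tibble
#'   (`dir`, `n_critical`, `share_pct`).
#' @export
critical_overlap <- function(tables, schemes = default_severity_schemes()) {
  stopifnot(length(tables) == 3)
  ids <- purrr::map_chr(tables, "dir_id")
  names(tables) <- ids
  crit <- purrr::map(tables, function(tb) {
    cr <- critical_ranks(schemes[[tb$dir_id]])
    tb$records$pair[!is.na(tb$records$severity) & tb$records$severity %in% cr]
  })
  sizes <- purrr::map_int(crit, length)
  combos <- utils::combn(ids, 2, simplify = FALSE)
  pairwise <- purrr::map(combos, function(cb) {
    joint <- sum(crit[[cb[1]]] %in% crit[[cb[2]]])
    tibble::tibble(
      dir_a = cb[1], dir_b = cb[2], joint = joint,
      cov_a_pct = if (sizes[[cb[1]]] > 0) 100 * joint / sizes[[cb[1]]] else NA_real_,
      cov_b_pct = if (sizes[[cb[2]]] > 0) 100 * joint / sizes[[cb[2]]] else NA_real_
    )
  }) |> dplyr::bind_rows()
  triple_joint <- sum(crit[[1]] %in% crit[[2]] & crit[[1]] %in% crit[[3]])
  inter <- Reduce(intersect, purrr::map(tables, pair_keys))
  inter_crit <- tibble::tibble(
    dir = ids,
    n_critical = purrr::map_int(crit, ~ sum(.x %in% inter))[ids],
    share_pct = if (length(inter) > 0) {
      100 * purrr::map_int(crit, ~ sum(.x %in% inter))[ids] / length(inter)
    } else NA_real_
  )
  structure(
    list(critical_sizes = sizes, pairwise = pairwise,
         triple_joint = triple_joint, intersection_size = length(inter),
         intersection_critical = inter_crit),
    class = "critical_overlap"
  )
}

#' @export
print.critical_overlap <- function(x, ...) {
  cat("<critical_overlap> critical sizes:",
      paste(names(x$critical_sizes), x$critical_sizes, sep = "=", collapse = ", "),
      "\n")
  print(x$pairwise)
  cat("jointly critical in all three:", x$triple_joint,
      "| three-way DDI intersection:", x$intersection_size, "\n")
  invisible(x)
}

#' Venn partition restricted to the common-ingredient subset
#'
#' Filters each resource's table to pairs whose BOTH members belong to the
#' three-way ingredient intersection, then partitions the filtered sets.
#' This controls for differences in which drugs a resource covers at all.
#'
#' @param tables Named list of three `dir_table`s.
#' @return A `venn_partition` over the filtered pair sets.
#' @export
ingredient_restricted_partition <- function(tables) {
  stopifnot(length(tables) == 3)
  common <- Reduce(intersect, purrr::map(tables, "ingredient_set"))
  keys <- purrr::map(tables, function(tb) {
    r <- tb$records
    r$pair[r$ingredient_a %in% common & r$ingredient_b %in% common]
  })
  venn_partition(keys[[1]], keys[[2]], keys[[3]],
                 labels = purrr::map_chr(tables, "dir_id"))
}

#' Three-way DDI intersection list with per-resource payloads
#'
#' The canonical pairs present in all three resources, with each resource's
#' severity, evidence and advice texts attached - the working set for
#' severity/evidence/advice agreement analyses.
#'
#' @param tables Named list of three `dir_table`s.
#' @return Tibble with `pair`, `ingredient_a`, `ingredient_b`, and per
#'   resource `<dir>_severity`, `<dir>_evidence`, `<dir>_advice` (list
#'   column).
#' @export
build_intersection_list <- function(tables) {
  stopifnot(length(tables) == 3)
  ids <- purrr::map_chr(tables, "dir_id")
  common <- Reduce(intersect, purrr::map(tables, pair_keys))
  common <- sort(common, method = "radix")
  first <- tables[[1]]$records
  i0 <- match(common, first$pair)
  out <- tibble::tibble(
    pair = common,
    ingredient_a = first$ingredient_a[i0],
    ingredient_b = first$ingredient_b[i0]
  )
  for (k in seq_along(tables)) {
    r <- tables[[k]]$records
    i <- match(common, r$pair)
    out[[paste0(ids[k], "_severity")]] <- r$severity_label[i]
    out[[paste0(ids[k], "_evidence")]] <- r$evidence[i]
    out[[paste0(ids[k], "_advice")]] <- r$advice_texts[i]
  }
  out
}
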