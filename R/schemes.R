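#' Severity rating scheme of a drug information resource
#'
#' Each drug information resource (DIR) grades its drug-drug interactions
#' (DDIs) on an ordered categorical severity scale. Levels are given in the
#' order the resource displays them, most severe first, so rank 1 is the most
#' severe level and "keeping the highest rating" means keeping the minimum
#' rank. A subset of the top levels is flagged *critical* (e.g. BNF "Severe";
#' Micromedex "Contraindicated" and "Major").
#'
#' @param dir_id Identifier of the resource (e.g. `"bnf"`).
#' @param levels Character vector of severity labels, most severe first.
#' @param critical Character vector, subset of `levels`, flagged critical.
#' @return An object of class `severity_scheme` with fields `dir_id`,
#'   `levels` (rank order) and `critical`.
#' @export
severity_scheme <- function(dir_id, levels, critical) {
  stopifnot(is.character(levels), length(levels) >= 1, !anyDuplicated(levels))
  if (length(critical) == 0 || !all(critical %in% levels)) {
    stopf("ddi_bad_scheme", "critical set must be a non-empty subset of the levels")
  }
  structure(
    list(dir_id = dir_id, levels = levels, critical = critical),
    class = "severity_scheme"
  )
}

#' @export
print.severity_scheme <- function(x, ...) {
  cat("<severity_scheme ", x$dir_id, ">\n", sep = "")
  flag <- ifelse(x$levels %in% x$critical, " [critical]", "")
  cat(sprintf("  %d - %s%s", seq_along(x$levels), x$levels, flag), sep = "\n")
  invisible(x)
}

#' Default severity schemes for the three compendia
#'
#' Severity vocabularies of the British National Formulary (BNF), the French
#' ANSM interaction Thesaurus, and Micromedex, in each source's displayed
#' order (most severe first), with the conventional critical sets: BNF
#' *Severe*; Thesaurus *Contraindicated* and *Not recommended*; Micromedex
#' *Contraindicated* and *Major*. BNF *Unknown* ranks last because the source
#' displays it last, although it denotes an unpredicted outcome rather than
#' the mildest one.
#'
#' @return Named list of [severity_scheme()] objects
#'   (`bnf`, `thesaurus`, `micromedex`).
#' @export
default_severity_schemes <- function() {
  list(
    bnf = severity_scheme(
      "bnf",
      c("Severe", "Moderate", "Mild", "Unknown"),
      critical = "Severe"
    ),
    thesaurus = severity_scheme(
      "thesaurus",
      c("Contraindicated", "Not recommended", "Precautions for use",
        "Take into consideration"),
      critical = c("Contraindicated", "Not recommended")
    ),
    micromedex = severity_scheme(
      "micromedex",
      c("Contraindicated", "Major", "Moderate", "Minor"),
      critical = c("Contraindicated", "Major")
    )
  )
}

#' Default evidence-rating vocabularies
#'
#' Evidence (substantiation) scales of the two resources that carry one,
#' strongest documentation first. Thesaurus has no evidence field. The order
#' is used when duplicate rows for one canonical pair carry different
#' evidence labels: the strongest is kept.
#'
#' @return Named list of character vectors, strongest level first.
#' @export
default_evidence_schemes <- function() {
  list(
    bnf = c("Study", "Anecdotal", "Theoretical"),
    micromedex = c("Established", "Theoretical", "Probable")
  )
}

#' Convert severity labels to ranks under a scheme
#'
#' @param labels Character vector of severity labels (NA allowed).
#' @param scheme A [severity_scheme()].
#' @return Integer ranks (1 = most severe); NA maps to NA.
#' @export
severity_rank <- function(labels, scheme) {
  stopifnot(inherits(scheme, "severity_scheme"))
  r <- match(labels, scheme$levels)
  bad <- !is.na(labels) & is.na(r)
  if (any(bad)) {
    stopf(
      "ddi_unknown_severity",
      "severity label(s) not in the %s scheme: %s",
      scheme$dir_id, paste(unique(labels[bad]), collapse = ", ")
    )
  }
  r
}

# ranks (integers) flagged critical under a scheme
critical_ranks <- function(scheme) match(scheme$critical, scheme$levels)
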