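# Per-category advice classifiers: class-weighted linear SVM, leave-one-out
# scores, ROC operating points and PPV-constrained threshold selection.

#' Train a class-weighted linear SVM for one advice category
#'
#' Fits a soft-margin linear support vector machine on tf-idf sentence
#' vectors for one binary category. Class imbalance is handled by
#' inverse-class-frequency weighting: the total misclassification budget
#' `cost` is split equally between the two classes and spread over each
#' class's sentences (per-class weight `cost / (2 * n_class)`), which makes
#' the fitted decision function invariant under duplication of the data
#' set.
#'
#' @param x Numeric matrix, one row per sentence (tf-idf vectors).
#' @param y Logical vector, TRUE for sentences in the category.
#' @param category Category identifier stored on the result.
#' @param cost Total per-class misclassification budget (default 1000, an
#'   approximately unit per-sentence cost at corpus sizes of a few hundred
#'   sentences).
#' @return An `advice_classifier` with the linear decision function
#'   (`w`, `b`, scores oriented so positives score high), class counts, and
#'   `status = "UNTHRESHOLDED"`.
#' @export
train_classifier <- function(x, y, category = "category", cost = 1000) {
  stopifnot(is.matrix(x), nrow(x) == length(y), is.logical(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stopf("ddi_degenerate_training",
          "category %s: training set must contain both classes (pos=%d, neg=%d)",
          category, n_pos, n_neg)
  }
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("pos", "neg"))
  wts <- c(pos = cost / (2 * n_pos), neg = cost / (2 * n_neg))
  fit <- e1071::svm(x, yf, kernel = "linear", scale = FALSE,
                    cost = 1, class.weights = wts)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the decision function so that positive sentences score high:
  # libsvm's sign convention depends on the order classes are first seen
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  if (!startsWith(colnames(dv)[1], "pos")) {
    w <- -w; b <- -b
  }
  structure(
    list(category = category, w = w, b = b, feature_names = colnames(x),
         cost = cost, n_pos = n_pos, n_neg = n_neg,
         status = "UNTHRESHOLDED", threshold = NA_real_,
         ppv = NA_real_, sensitivity = NA_real_),
    class = "advice_classifier"
  )
}

#' @export
print.advice_classifier <- function(x, ...) {
  cat(sprintf("<advice_classifier %s> status=%s", x$category, x$status))
  if (x$status == "ACTIVE") {
    cat(sprintf(" threshold=%.4g (LOO PPV %.3f, sensitivity %.3f)",
                x$threshold, x$ppv, x$sensitivity))
  }
  cat(sprintf("  [trained on %d pos / %d neg]\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Decision scores of a classifier on sentence vectors
#'
#' @param clf An `advice_classifier`.
#' @param x Numeric matrix of tf-idf vectors (columns in training order).
#' @return Numeric vector of decision values (positive = category side).
#' @export
decision_scores <- function(clf, x) {
  stopifnot(inherits(clf, "advice_classifier"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(x %*% clf$w + clf$b)
}

#' Leave-one-out cross-validated decision scores
#'
#' Scores each sentence with a classifier trained on all other sentences.
#' Folds whose training subset loses a class entirely are degenerate: their
#' score is NA and a warning is raised. If the labels are constant, every
#' fold is degenerate and an empty score vector is returned.
#'
#' @param x Numeric matrix of tf-idf vectors.
#' @param y Logical label vector.
#' @param cost Passed to [train_classifier()].
#' @return Numeric vector of length `nrow(x)` (NA for degenerate folds), or
#'   `numeric(0)` when no fold is trainable.
#' @export
loocv_scores <- function(x, y, cost = 1000) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  n <- nrow(x)
  if (n < 3) stopf("ddi_too_small", "leave-one-out needs at least 3 sentences")
  if (sum(y) == 0 || sum(!y) == 0) {
    return(numeric(0))
  }
  scores <- rep(NA_real_, n)
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (sum(yi) == 0 || sum(!yi) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    clf <- train_classifier(x[-i, , drop = FALSE], yi, cost = cost)
    scores[i] <- decision_scores(clf, x[i, , drop = FALSE])
  }
  if (n_degenerate > 0) {
    warnf("%d leave-one-out fold(s) skipped as degenerate", n_degenerate)
  }
  scores
}

#' ROC operating points from decision scores
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores plus -Inf/+Inf sentinels; a sentence is predicted positive when
#' its score is at or above the threshold. Points are listed by strictly
#' decreasing threshold, so sensitivity is non-decreasing along the list.
#' PPV is NA where nothing is predicted positive.
#'
#' @param scores Numeric decision scores (NA entries dropped with their
#'   labels).
#' @param labels Logical vector aligned with `scores`.
#' @return Tibble: `threshold`, `tp`, `fp`, `ppv`, `sensitivity`.
#' @export
roc_points <- function(scores, labels) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) == 0) {
    stopf("ddi_no_positives", "ROC analysis needs at least one positive")
  }
  u <- sort(unique(scores))
  thr <- c(Inf, rev(if (length(u) > 1) (u[-1] + u[-length(u)]) / 2), -Inf)
  pts <- purrr::map(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    tibble::tibble(
      threshold = t, tp = tp, fp = fp,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      sensitivity = tp / sum(labels)
    )
  })
  dplyr::bind_rows(pts)
}

#' Select the operating threshold under a PPV constraint
#'
#' Among ROC operating points with estimated PPV at or above `min_ppv`,
#' selects the one with maximum sensitivity (ties broken by higher PPV,
#' then higher threshold). When no point qualifies the classifier is
#' rejected - rejection is a first-class outcome for categories the model
#' cannot annotate reliably.
#'
#' @param scores Leave-one-out decision scores.
#' @param labels Logical labels aligned with `scores`.
#' @param min_ppv Minimum acceptable PPV (default 0.80).
#' @return List: `status` (`"ACTIVE"` or `"REJECTED"`), `threshold`, `ppv`,
#'   `sensitivity` (NA when rejected), and `roc` (the full operating-point
#'   table).
#' @export
roc_and_select_threshold <- function(scores, labels, min_ppv = 0.80) {
  roc <- roc_points(scores, labels)
  ok <- !is.na(roc$ppv) & roc$ppv >= min_ppv
  if (!any(ok)) {
    return(list(status = "REJECTED", threshold = NA_real_, ppv = NA_real_,
                sensitivity = NA_real_, roc = roc))
  }
  cand <- roc[ok, ]
  cand <- cand[order(-cand$sensitivity, -cand$ppv, -cand$threshold), ]
  best <- cand[1, ]
  list(status = "ACTIVE", threshold = best$threshold, ppv = best$ppv,
       sensitivity = best$sensitivity, roc = roc)
}

#' Fit, evaluate and threshold classifiers for every advice category
#'
#' For each category: trains the class-weighted linear SVM on the full
#' labelled corpus, computes leave-one-out decision scores, and selects the
#' maximum-sensitivity threshold whose leave-one-out PPV meets `min_ppv`.
#' Categories with a single class, or no qualifying operating point, end
#' REJECTED.
#'
#' @param x tf-idf matrix of the labelled corpus.
#' @param labels Long tibble `sentence_id`, `category`, `label` (0/1), or a
#'   logical matrix with category columns aligned to the rows of `x`.
#' @param sentence_ids Sentence ids aligned with the rows of `x` (needed
#'   when `labels` is long).
#' @param categories Categories to fit (default all nine).
#' @param min_ppv PPV constraint (default 0.80).
#' @param cost Passed to [train_classifier()].
#' @return List with `classifiers` (named list of `advice_classifier`s,
#'   thresholded or REJECTED) and `report`, a tibble of per-category status,
#'   threshold and leave-one-out PPV/sensitivity.
#' @export
fit_advice_classifiers <- function(x, labels, sentence_ids = rownames(x),
                                   categories = advice_categories(),
                                   min_ppv = 0.80, cost = 1000) {
  ymat <- label_matrix(labels, sentence_ids, categories)
  classifiers <- list()
  report <- list()
  for (cat in categories) {
    y <- ymat[, cat]
    if (sum(y) == 0 || sum(!y) == 0) {
      clf <- structure(
        list(category = cat, w = NULL, b = NA_real_, feature_names = colnames(x),
             cost = cost, n_pos = sum(y), n_neg = sum(!y),
             status = "REJECTED", threshold = NA_real_,
             ppv = NA_real_, sensitivity = NA_real_),
        class = "advice_classifier"
      )
      sel <- list(status = "REJECTED", threshold = NA_real_,
                  ppv = NA_real_, sensitivity = NA_real_)
    } else {
      clf <- train_classifier(x, y, category = cat, cost = cost)
      loo <- loocv_scores(x, y, cost = cost)
      sel <- roc_and_select_threshold(loo, y, min_ppv = min_ppv)
      clf$status <- sel$status
      clf$threshold <- sel$threshold
      clf$ppv <- sel$ppv
      clf$sensitivity <- sel$sensitivity
    }
    classifiers[[cat]] <- clf
    report[[cat]] <- tibble::tibble(
      category = cat, status = sel$status, n_pos = sum(y),
      threshold = sel$threshold, loo_ppv = sel$ppv,
      loo_sensitivity = sel$sensitivity
    )
  }
  list(classifiers = classifiers, report = dplyr::bind_rows(report))
}

label_matrix <- function(labels, sentence_ids, categories) {
  if (is.matrix(labels) || (is.data.frame(labels) && !"category" %in% names(labels))) {
    m <- as.matrix(labels)
    storage.mode(m) <- "logical"
    stopifnot(all(categories %in% colnames(m)))
    return(m[, categories, drop = FALSE])
  }
  stopifnot(all(c("sentence_id", "category", "label") %in% names(labels)),
            !is.null(sentence_ids))
  m <- matrix(FALSE, nrow = length(sentence_ids), ncol = length(categories),
              dimnames = list(sentence_ids, categories))
  pos <- labels[labels$label %in% c(1, TRUE, "1"), ]
  pos <- pos[pos$sentence_id %in% sentence_ids & pos$category %in% categories, ]
  m[cbind(match(pos$sentence_id, sentence_ids), match(pos$category, categories))] <- TRUE
  m
}

#' Annotate a corpus with all active classifiers
#'
#' Applies every ACTIVE classifier independently to each sentence; a
#' sentence with no positive decision carries no advice label.
#'
#' @param classifiers Named list of `advice_classifier`s (REJECTED ones are
#'   skipped); at least one must be ACTIVE.
#' @param x tf-idf matrix of the corpus to annotate.
#' @param sentence_ids Ids aligned with the rows of `x`.
#' @return Long tibble `sentence_id`, `category`, `score`, `decision`
#'   (logical), with attribute `no_advice`: the sentence ids that received
#'   no label.
#' @export
annotate_corpus <- function(classifiers, x, sentence_ids = rownames(x)) {
  active <- purrr::keep(classifiers, ~ .x$status == "ACTIVE")
  if (length(active) == 0) {
    stopf("ddi_no_active_classifiers", "no ACTIVE classifier to annotate with")
  }
  if (is.null(sentence_ids)) sentence_ids <- as.character(seq_len(nrow(x)))
  out <- purrr::map(active, function(clf) {
    s <- decision_scores(clf, x)
    tibble::tibble(sentence_id = sentence_ids, category = clf$category,
                   score = s, decision = s >= clf$threshold)
  })
  ann <- dplyr::bind_rows(out)
  labelled <- unique(ann$sentence_id[ann$decision])
  attr(ann, "no_advice") <- setdiff(sentence_ids, labelled)
  ann
}

#' Aggregate sentence-level annotations to DDI records
#'
#' A record's advice label set is the union of its sentences' label sets.
#'
#' @param annotations Long tibble from [annotate_corpus()] (or manual labels
#'   with a logical `decision` column).
#' @param sentence_records Tibble `sentence_id`, `record_id` mapping
#'   sentences to DDI records.
#' @return Tibble `record_id`, `categories` (list column of sorted category
#'   sets; empty character vector for records with no advice).
#' @export
aggregate_advice <- function(annotations, sentence_records) {
  stopifnot(all(c("sentence_id", "record_id") %in% names(sentence_records)))
  pos <- annotations[annotations$decision, c("sentence_id", "category")]
  joined <- dplyr::inner_join(sentence_records, pos, by = "sentence_id")
  per_rec <- split(joined$category, joined$record_id)
  tibble::tibble(
    record_id = unique(sentence_records$record_id),
    categories = purrr::map(unique(sentence_records$record_id),
                            ~ sort(unique(per_rec[[.x]] %||% character())))
  )
}

#' Validate automatic annotations against a manually labelled hold-out
#'
#' Per-category positive predictive value `TP / (TP + FP)`, sensitivity
#' `TP / (TP + FN)` and their harmonic mean F1, comparing automatic
#' decisions with manual labels on the same sentences. Metrics whose
#' denominator is empty are reported as NA (not applicable), never as 0.
#'
#' @param auto Long tibble `sentence_id`, `category`, `decision` (logical or
#'   0/1) - the automatic labels.
#' @param manual Long tibble `sentence_id`, `category`, `label` (0/1) - the
#'   manual labels over the same sentence ids.
#' @param categories Categories to evaluate (default: those present in
#'   `auto`).
#' @return Tibble `category`, `tp`, `fp`, `fn`, `ppv`, `sensitivity`, `f1`.
#' @export
validate_holdout <- function(auto, manual, categories = NULL) {
  ids <- sort(unique(manual$sentence_id))
  if (!setequal(unique(auto$sentence_id), ids)) {
    stopf("ddi_id_mismatch",
          "automatic and manual annotations cover different sentence ids")
  }
  categories <- categories %||% sort(unique(auto$category))
  rows <- purrr::map(categories, function(cat) {
    a <- auto[auto$category == cat, ]
    m <- manual[manual$category == cat, ]
    auto_pos <- a$sentence_id[as.logical(a$decision)]
    man_pos <- m$sentence_id[m$label %in% c(1, TRUE, "1")]
    tp <- length(intersect(auto_pos, man_pos))
    fp <- length(setdiff(auto_pos, man_pos))
    fn <- length(setdiff(man_pos, auto_pos))
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0) {
      2 * ppv * sens / (ppv + sens)
    } else NA_real_
    tibble::tibble(category = cat, tp = tp, fp = fp, fn = fn,
                   ppv = ppv, sensitivity = sens, f1 = f1)
  })
  dplyr::bind_rows(rows)
}
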