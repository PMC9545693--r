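# small deterministic 2-D fixtures keep the SVM geometry inspectable

sep_fixture <- function() {
  x <- rbind(c(2, 2), c(3, 2.5), c(-2, -2), c(-3, -1))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = c(TRUE, TRUE, FALSE, FALSE))
}

# weighted soft-margin objective used by the independent optimiser oracle
svm_objective <- function(par, x, y, cost) {
  w <- par[1:2]; b <- par[3]
  ys <- ifelse(y, 1, -1)
  ci <- ifelse(y, cost / (2 * sum(y)), cost / (2 * sum(!y)))
  margins <- 1 - ys * (x %*% w + b)
  0.5 * sum(w^2) + sum(ci * pmax(margins, 0))
}

test_that("a separable toy set is classified with zero training error", {
  f <- sep_fixture()
  clf <- train_classifier(f$x, f$y, "avoid")
  s <- decision_scores(clf, f$x)
  expect_true(all(s[f$y] > 0))
  expect_true(all(s[!f$y] < 0))
  expect_error(train_classifier(f$x, rep(TRUE, 4)),
               class = "ddi_degenerate_training")
})

test_that("the class weighting makes training invariant under dataset duplication", {
  withr::with_seed(81, {
    x <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
    y <- x[, 1] + 0.3 * rnorm(20) > 0.2   # imbalanced, not separable
    clf1 <- train_classifier(x, y)
    clf2 <- train_classifier(rbind(x, x), c(y, y))
    # identical up to the iterative solver's convergence tolerance
    expect_equal(clf2$w, clf1$w, tolerance = 5e-3)
    expect_equal(clf2$b, clf1$b, tolerance = 5e-3)
  })
})

test_that("the fitted decision boundary matches an independent optimiser", {
  withr::with_seed(82, {
    x <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
    y <- x[, 1] - x[, 2] + 0.5 * rnorm(30) > 0
    clf <- train_classifier(x, y, cost = 20)
    fitted_obj <- svm_objective(c(clf$w, clf$b), x, y, cost = 20)

    # convex objective: polish from several starts with a derivative-free
    # optimiser and keep the best solution found
    best <- Inf; best_par <- NULL
    for (start in list(c(0, 0, 0), c(1, -1, 0), c(clf$w, clf$b) + 0.5)) {
      o <- stats::optim(start, svm_objective, x = x, y = y, cost = 20,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
      if (o$value < best) { best <- o$value; best_par <- o$par }
    }
    # both optimisers reach the same optimum of the same objective ...
    expect_equal(fitted_obj, best, tolerance = 1e-3)
    # ... and describe the same boundary
    expect_equal(clf$w / sqrt(sum(clf$w^2)),
                 best_par[1:2] / sqrt(sum(best_par[1:2]^2)), tolerance = 0.02)
    expect_equal(sign(decision_scores(clf, x)),
                 sign(as.numeric(x %*% best_par[1:2] + best_par[3])))
  })
})

test_that("leave-one-out scores equal explicit retraining and are order-invariant", {
  f <- sep_fixture()
  x3 <- rbind(f$x, c(0.5, 0))
  y3 <- c(f$y, TRUE)
  s <- loocv_scores(x3, y3)
  expect_length(s, 5)
  for (i in seq_len(5)) {
    clf_i <- train_classifier(x3[-i, , drop = FALSE], y3[-i])
    expect_equal(s[i], decision_scores(clf_i, x3[i, , drop = FALSE]))
  }

  # permuting sentence order permutes, but does not change, the scores
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(loocv_scores(x3[perm, ], y3[perm]), s[perm], tolerance = 2e-3)

  # constant labels: every fold is degenerate -> empty score list
  expect_length(loocv_scores(x3, rep(TRUE, 5)), 0)
  # a single positive: its own fold is degenerate and flagged
  expect_warning(s1 <- loocv_scores(f$x, c(TRUE, FALSE, FALSE, FALSE)),
                 "degenerate")
  expect_true(is.na(s1[1]))
})

test_that("threshold selection maximises sensitivity under the PPV floor", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c(TRUE, TRUE, FALSE, TRUE)
  sel <- roc_and_select_threshold(scores, labels, min_ppv = 0.8)
  expect_equal(sel$status, "ACTIVE")
  expect_equal(sel$ppv, 1.0)
  expect_equal(sel$sensitivity, 2 / 3)
  expect_gt(sel$threshold, 0.7)
  expect_lt(sel$threshold, 0.8)

  # perfectly separated scores
  sep <- roc_and_select_threshold(c(2, 1.5, -1, -2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$status, "ACTIVE")
  expect_equal(sep$ppv, 1.0)
  expect_equal(sep$sensitivity, 1.0)

  # positives all below negatives: nothing qualifies at 0.8
  inv <- roc_and_select_threshold(c(1, 0.9, 0.2, 0.1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(inv$status, "REJECTED")
  expect_true(is.na(inv$threshold))
  expect_error(roc_and_select_threshold(1:3, rep(FALSE, 3)),
               class = "ddi_no_positives")
})

test_that("the ROC operating-point list is threshold-sorted with monotone sensitivity", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      n <- sample(5:30, 1)
      scores <- rnorm(n)
      labels <- runif(n) < 0.4
      if (!any(labels)) labels[1] <- TRUE
      roc <- roc_points(scores, labels)
      expect_true(all(diff(roc$threshold) < 0))
      expect_true(all(diff(roc$sensitivity) >= 0))

      # raising the PPV floor never raises the achievable sensitivity
      sens_at <- vapply(c(0, 0.5, 0.8, 0.95), function(p) {
        sel <- roc_and_select_threshold(scores, labels, min_ppv = p)
        if (sel$status == "ACTIVE") sel$sensitivity else -1
      }, numeric(1))
      expect_true(all(diff(sens_at) <= 0))
      expect_equal(sens_at[1], 1.0)  # a floor of zero always admits recall 1
    }
  })
})

test_that("annotation applies active classifiers independently and flags no-advice", {
  f <- sep_fixture()
  clf_a <- train_classifier(f$x, f$y, "monitor")
  clf_a$status <- "ACTIVE"; clf_a$threshold <- 0
  clf_b <- train_classifier(f$x, !f$y, "avoid")
  clf_b$status <- "ACTIVE"; clf_b$threshold <- 0
  rej <- clf_a; rej$category <- "wash_out"; rej$status <- "REJECTED"

  ann <- annotate_corpus(list(clf_a, clf_b, rej), f$x,
                         sentence_ids = paste0("s", 1:4))
  expect_setequal(unique(ann$category), c("monitor", "avoid"))
  expect_equal(sum(ann$decision[ann$category == "monitor"]), 2)
  expect_length(attr(ann, "no_advice"), 0)

  # per-classifier manual thresholding oracle
  for (clf in list(clf_a, clf_b)) {
    s <- decision_scores(clf, f$x)
    expect_equal(ann$decision[ann$category == clf$category], s >= clf$threshold)
  }
  expect_error(annotate_corpus(list(rej), f$x), class = "ddi_no_active_classifiers")
})

test_that("record-level advice is the union of its sentences' labels", {
  ann <- tibble::tibble(
    sentence_id = c("s1", "s1", "s2", "s3"),
    category = c("monitor", "adjust_dose", "avoid", "monitor"),
    score = 1, decision = c(TRUE, TRUE, TRUE, FALSE)
  )
  map <- tibble::tibble(sentence_id = c("s1", "s2", "s3"),
                        record_id = c("r1", "r1", "r2"))
  agg <- aggregate_advice(ann, map)
  expect_equal(agg$categories[[which(agg$record_id == "r1")]],
               c("adjust_dose", "avoid", "monitor"))
  expect_equal(agg$categories[[which(agg$record_id == "r2")]], character())
})

test_that("hold-out validation computes PPV, sensitivity and F1 with NA for empty margins", {
  ids <- sprintf("s%02d", 1:12)
  manual <- tidyr::expand_grid(sentence_id = ids,
                               category = c("monitor", "avoid", "wash_out"))
  manual$label <- 0L
  manual$label[manual$category == "monitor" & manual$sentence_id %in% ids[1:10]] <- 1L
  auto <- manual
  names(auto)[3] <- "decision"
  auto$decision <- FALSE
  auto$decision[auto$category == "monitor" & auto$sentence_id %in% ids[c(1:8, 11, 12)]] <- TRUE

  rep_ <- validate_holdout(auto, manual)
  mon <- rep_[rep_$category == "monitor", ]
  expect_equal(c(mon$tp, mon$fp, mon$fn), c(8, 2, 2))
  expect_equal(mon$ppv, 0.8)
  expect_equal(mon$sensitivity, 0.8)
  expect_equal(mon$f1, 0.8)
  # never predicted, never true: all three not-applicable, not zero
  wo <- rep_[rep_$category == "wash_out", ]
  expect_true(is.na(wo$ppv) && is.na(wo$sensitivity) && is.na(wo$f1))

  # perfect agreement
  perfect <- validate_holdout(
    transform(manual, decision = label == 1L), manual)
  expect_equal(perfect$ppv[perfect$category == "monitor"], 1.0)
  expect_equal(perfect$f1[perfect$category == "monitor"], 1.0)

  expect_error(validate_holdout(auto[auto$sentence_id != "s01", ], manual),
               class = "ddi_id_mismatch")
})
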