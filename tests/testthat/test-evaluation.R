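test_that("confusion metrics use the standard denominators", {
  m <- classification_metrics(list(TP = 30, FN = 10, TN = 50, FP = 10))
  expect_equal(unname(m), c(0.8, 0.75, 50 / 60), tolerance = 1e-12)
  expect_equal(unname(classification_metrics(list(TP = 5, FN = 0, TN = 7, FP = 0))),
               c(1, 1, 1))
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1)),
               "denominator")

  # accuracy is the prevalence-weighted mean of sensitivity and specificity
  set.seed(3)
  for (k in 1:20) {
    cm <- as.list(stats::setNames(sample(1:50, 4), c("TP", "TN", "FP", "FN")))
    m <- classification_metrics(cm)
    npos <- cm$TP + cm$FN; nneg <- cm$TN + cm$FP
    expect_equal(unname(m["acc"]),
                 unname((npos * m["sen"] + nneg * m["spe"]) / (npos + nneg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the pairwise-comparison oracle and is rank invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  expect_error(roc_auc(runif(4), rep(0, 4)), "both classes")
  set.seed(5)
  for (k in 1:10) {
    scores <- round(runif(50), 1)           # plenty of ties
    labels <- rbinom(50, 1, 0.4)
    if (length(unique(labels)) < 2) next
    a <- roc_auc(scores, labels)
    expect_equal(a, auc_pairwise_oracle(scores, labels), tolerance = 1e-12)
    # strictly increasing transform leaves the AUC unchanged
    expect_equal(roc_auc(exp(3 * scores), labels), a, tolerance = 1e-12)
  }
  # independent cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- runif(200); labels <- rbinom(200, 1, 0.3)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(7)
  scores <- runif(300)
  aucs <- replicate(1000, roc_auc(scores, sample(rep(0:1, c(200, 100)))))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the mean metric is the plain average of the three rates", {
  expect_equal(mean_metric(1, 1, 1), 1)
  expect_equal(mean_metric(0.77, 0.73, 0.77), 2.27 / 3, tolerance = 1e-12)
  expect_equal(round(100 * mean_metric(0.77, 0.73, 0.77)), 76)
  expect_error(mean_metric(1.2, 0.5, 0.5))
})

test_that("post-processing rewrites isolated seconds in one pass", {
  expect_equal(postprocess_labels(c(0, 1, 0)), c(0, 0, 0))
  expect_equal(postprocess_labels(c(1, 0, 1)), c(1, 1, 1))
  expect_equal(postprocess_labels(c(0, 1, 1, 0)), c(0, 1, 1, 0))
  # one simultaneous pass on the *input*: each interior position is judged
  # against the original neighbours, so alternations invert rather than
  # collapse to one class (iterating to a fixpoint would erase them)
  expect_equal(postprocess_labels(c(0, 1, 0, 1, 0)), c(0, 0, 1, 0, 0))
  expect_equal(postprocess_labels(c(1, 0, 1, 0, 1)), c(1, 1, 0, 1, 1))
  # endpoints never change; length preserved; non-singletons untouched
  set.seed(8)
  for (k in 1:25) {
    x <- rbinom(30, 1, 0.4)
    y <- postprocess_labels(x)
    expect_length(y, 30)
    expect_equal(y[c(1, 30)], x[c(1, 30)])
    i <- 2:29
    untouched <- !(x[i - 1] == x[i + 1] & x[i] != x[i - 1])
    expect_equal(y[i][untouched], x[i][untouched])
  }
})

test_that("Hamming diversity matches its oracle and invariances", {
  expect_equal(hamming_diversity(list(rep(1L, 15), rep(1L, 15))), 0)
  expect_equal(hamming_diversity(list(rep(0L, 15), rep(1L, 15))), 1)
  expect_error(hamming_diversity(list(rep(0L, 15), rep(1L, 10))), "length")
  set.seed(10)
  for (k in 1:10) {
    pop <- replicate(5, sample(0:1, 15, replace = TRUE), simplify = FALSE)
    d <- hamming_diversity(pop)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, diversity_oracle(pop), tolerance = 1e-12)
    expect_equal(hamming_diversity(sample(pop)), d, tolerance = 1e-12)
    expect_equal(hamming_diversity(lapply(pop, function(g) 1L - g)), d,
                 tolerance = 1e-12)
  }
})

test_that("TFCV folds partition subjects and chance data scores ~0.5", {
  cohort <- generate_cohort(cap_sim_params(n_subjects = 4, duration_s = 120,
                                           prevalence = 0.2, seed = 31))
  # null cohort: labels shuffled independently of the signal
  set.seed(31)
  null_cohort <- lapply(cohort, function(r) { r$labels <- sample(r$labels); r })
  cfg <- cap_config(hidden = 4, time_steps = 2)
  pm <- tfcv_fitness(cfg, null_cohort, cap_control(epochs = 2, seed = 1))
  expect_gt(pm, 0.3); expect_lt(pm, 0.7)

  # the subject-independence guard trips on overlapping folds
  w <- make_windows(preprocess_recording(cohort[[1]]), 2)
  expect_error(capfuse:::assert_disjoint_subjects(w, w), "subject-independence")
})

test_that("LOO runs one cycle per subject and reports the summary layout", {
  cohort <- generate_cohort(cap_sim_params(n_subjects = 4, duration_s = 120,
                                           prevalence = 0.2, seed = 33))
  res <- loo_evaluate(cap_config(hidden = 4, time_steps = 2), cohort,
                      cap_control(epochs = 3, seed = 1))
  expect_s3_class(res, "cap_loo")
  expect_equal(nrow(res$per_subject), 4)
  expect_setequal(res$per_subject$subject,
                  vapply(cohort, function(r) r$subject_id, ""))
  expect_setequal(res$summary$metric, c("acc", "sen", "spe", "auc"))
  expect_true(all(c("mean", "sd", "min", "max") %in% names(res$summary)))
  expect_true(all(res$per_subject$auc >= 0 & res$per_subject$auc <= 1))
  expect_output(print(res), "\\+/-")
})
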