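## Metrics, post-processing, diversity, TFCV / LOO protocols ------------------

#' Confusion counts
#'
#' @param predicted,actual Binary vectors (1 = A phase, the positive class).
#' @return A list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  stopifnot(length(predicted) == length(actual))
  list(TP = sum(predicted == 1 & actual == 1),
       TN = sum(predicted == 0 & actual == 0),
       FP = sum(predicted == 1 & actual == 0),
       FN = sum(predicted == 0 & actual == 1))
}

#' Accuracy, sensitivity and specificity
#'
#' Standard definitions: `Acc = (TP+TN)/total`, `Sen = TP/(TP+FN)`,
#' `Spe = TN/(TN+FP)`.
#'
#' @param cm Confusion counts as returned by [confusion_counts()].
#' @return Named numeric vector `c(acc, sen, spe)`.
#' @export
#' @examples
#' classification_metrics(list(TP = 30, FN = 10, TN = 50, FP = 10))
classification_metrics <- function(cm) {
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0 || cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0)
    stopf("undefined metric: a confusion-matrix denominator is zero")
  c(acc = (cm$TP + cm$TN) / total,
    sen = cm$TP / (cm$TP + cm$FN),
    spe = cm$TN / (cm$TN + cm$FP))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic
#' `P(score_pos > score_neg) + P(tie)/2`, which equals the trapezoidal area
#' under the ROC curve and is invariant under strictly increasing score
#' transforms.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))  # 1
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stopf("AUC requires both classes in the labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Mean of accuracy, sensitivity and specificity
#'
#' A single balance-sensitive summary: the arithmetic mean of the three
#' rates, reported so that a high accuracy obtained by ignoring the rare
#' A-phase class cannot masquerade as good performance.
#'
#' @param acc,sen,spe Rates in `[0, 1]`.
#' @return Their arithmetic mean.
#' @export
#' @examples
#' mean_metric(0.79, 0.68, 0.81)  # 0.76
mean_metric <- function(acc, sen, spe) {
  stopifnot(all(c(acc, sen, spe) >= 0), all(c(acc, sen, spe) <= 1))
  (acc + sen + spe) / 3
}

#' Correct isolated one-second classifications
#'
#' A second bounded by two opposite classifications is considered
#' misclassified: in a single simultaneous pass over the *input* sequence,
#' `010` becomes `000` and `101` becomes `111`. Endpoints are never changed
#' and the pass is not iterated to a fixpoint.
#'
#' @param labels Binary vector.
#' @return Corrected binary vector of the same length.
#' @export
#' @examples
#' postprocess_labels(c(0, 1, 0))  # 0 0 0
#' postprocess_labels(c(1, 0, 1))  # 1 1 1
postprocess_labels <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 3) return(labels)
  out <- labels
  i <- 2:(n - 1)
  flip <- labels[i - 1] == labels[i + 1] & labels[i] != labels[i - 1]
  out[i][flip] <- labels[i - 1][flip]
  out
}

#' Normalized Hamming diversity of a population
#'
#' `(2 / (z L (z - 1))) * sum_{mu < theta} Ham(p_mu, p_theta)`: the mean
#' pairwise Hamming distance divided by the genome length, in `[0, 1]`.
#'
#' @param population List of equal-length bit vectors (`z >= 2`).
#' @return Diversity in `[0, 1]`.
#' @export
#' @examples
#' hamming_diversity(list(rep(0, 15), rep(1, 15)))  # 1
hamming_diversity <- function(population) {
  z <- length(population)
  stopifnot(z >= 2)
  L <- unique(lengths(population))
  if (length(L) != 1) stopf("all genomes must have the same length")
  M <- do.call(rbind, population)
  tot <- 0
  for (mu in seq_len(z - 1)) {
    tot <- tot + sum(abs(sweep(M[(mu + 1):z, , drop = FALSE], 2, M[mu, ])))
  }
  2 * tot / (z * L * (z - 1))
}

## Protocols ------------------------------------------------------------------

assert_disjoint_subjects <- function(train_w, test_w) {
  inter <- intersect(unique(train_w$subject), unique(test_w$subject))
  if (length(inter))
    stopf("subject-independence violated: %s in both folds",
          paste(inter, collapse = ", "))
}

cohort_groups <- function(cohort) {
  g <- vapply(cohort, function(r) r$group, "")
  if (any(is.na(g) | g == "")) g <- rep("all", length(cohort))
  g
}

#' Two-fold cross-validated fitness (mean AUC)
#'
#' Splits the cohort's subjects into two subject-independent folds,
#' stratified by group (disorder-free-like vs sleep-disorder-like), trains
#' a cold-started model on each fold and scores the other; the performance
#' metric is the mean of the two test AUCs. This is the fitness both
#' optimizers maximize.
#'
#' @param config A [cap_config()].
#' @param cohort List of `cap_recording` objects (>= 2 per group).
#' @param control A [cap_control()].
#' @param seed Seed controlling the fold split and the two cold starts.
#' @return The mean AUC of the two folds (the `PM`).
#' @export
tfcv_fitness <- function(config, cohort, control = cap_control(),
                         seed = control$seed) {
  windows <- prepare_cohort(cohort, config$time_steps)
  groups <- cohort_groups(cohort)
  with_seed(child_seed(seed, 17L), {
    fold <- integer(length(cohort))
    for (g in unique(groups)) {
      idx <- sample(which(groups == g))
      fold[idx] <- rep(1:2, length.out = length(idx))
    }
    aucs <- vapply(1:2, function(f) {
      train_w <- bind_windows(windows[fold != f])
      test_w <- bind_windows(windows[fold == f])
      assert_disjoint_subjects(train_w, test_w)
      ctl <- control
      ctl$seed <- child_seed(seed, 100L + f)
      fit <- cap_fusion(train_w, config, ctl)
      roc_auc(predict(fit, test_w), test_w$y)
    }, 0)
    mean(aucs)
  })
}

#' Architecture-search fitness function over genomes
#'
#' Returns a closure mapping a 15-bit genome to its [tfcv_fitness()], ready
#' to hand to [run_ga()] or [run_pso()]. Both optimizers share this fitness
#' and encoding, so their searches are directly comparable.
#'
#' @inheritParams tfcv_fitness
#' @return `function(bits) -> mean TFCV AUC`.
#' @export
make_tfcv_fitness <- function(cohort, control = cap_control(), seed = 1L) {
  force(cohort); force(control); force(seed)
  function(bits) {
    cfg <- decode_genome(bits)
    tfcv_fitness(cfg, cohort, control, seed = seed)
  }
}

#' Leave-one-subject-out evaluation
#'
#' For every subject: train a cold-started model on all other subjects,
#' pick the decision threshold maximizing Youden's J on the *training* ROC
#' curve, classify the held-out subject, correct isolated one-second
#' labels, and compute the confusion metrics and AUC.
#'
#' @param config A [cap_config()].
#' @param cohort List of >= 3 `cap_recording` objects.
#' @param control A [cap_control()].
#' @param seed Seed; each cycle's cold start derives from it.
#' @return A `cap_loo` object: data.frame `per_subject` (subject, group,
#'   acc, sen, spe, auc, threshold) plus a `summary` table of
#'   mean/sd/min/max per metric.
#' @export
loo_evaluate <- function(config, cohort, control = cap_control(),
                         seed = control$seed) {
  if (length(cohort) < 3) stopf("LOO needs at least 3 subjects")
  windows <- prepare_cohort(cohort, config$time_steps)
  rows <- lapply(seq_along(cohort), function(i) {
    train_w <- bind_windows(windows[-i])
    test_w <- windows[[i]]
    assert_disjoint_subjects(train_w, test_w)
    ctl <- control
    ctl$seed <- child_seed(seed, 300L + i)
    fit <- cap_fusion(train_w, config, ctl)
    thr <- select_threshold(predict(fit, train_w), train_w$y)
    scores <- predict(fit, test_w)
    pred <- postprocess_labels(as.integer(scores >= thr))
    cm <- confusion_counts(pred, test_w$y)
    met <- classification_metrics(cm)
    data.frame(subject = cohort[[i]]$subject_id,
               group = cohort[[i]]$group,
               acc = met["acc"], sen = met["sen"], spe = met["spe"],
               auc = roc_auc(scores, test_w$y), threshold = thr,
               row.names = NULL)
  })
  per_subject <- do.call(rbind, rows)
  structure(list(per_subject = per_subject,
                 summary = summarize_loo(per_subject), config = config),
            class = "cap_loo")
}

summarize_loo <- function(df) {
  mets <- c("acc", "sen", "spe", "auc")
  do.call(rbind, lapply(mets, function(m) {
    v <- df[[m]]
    data.frame(metric = m, mean = mean(v), sd = sd(v),
               min = min(v), max = max(v))
  }))
}

#' @export
print.cap_loo <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out evaluation over %d subjects\n",
              nrow(x$per_subject)))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: %5.2f%% +/- %.2f (%.2f-%.2f)\n",
                toupper(s$metric), 100 * s$mean, 100 * s$sd,
                100 * s$min, 100 * s$max))
  }
  invisible(x)
}
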