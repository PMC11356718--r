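# Evaluation protocol: repeated stratified k-fold cross-validation, rank
# metrics (AUROC via the Mann-Whitney statistic with ties at 1/2, average
# precision), per-cohort confusion rates, and the task runner.

#' Repeated stratified fold plan
#'
#' For each of `repeats` independent repetitions, mice are shuffled within
#' each label class and dealt round-robin into `folds` test folds, so test
#' sets partition the cohort and every fold keeps the class mix.
#'
#' @param labels Named (mouse id) binary label vector.
#' @param repeats Number of repetitions (default 5).
#' @param folds Folds per repetition (default 3).
#' @param seed Seed making the plan deterministic.
#' @return Object of class `fold_plan`: list of repeats, each a list of
#'   per-fold test-id character vectors.
#' @export
make_folds <- function(labels, repeats = 5L, folds = 3L, seed = 1L) {
  if (is.null(names(labels))) stop("'labels' must be named by mouse id")
  tab <- table(labels)
  if (any(tab < folds))
    stop(sprintf("class '%s' has %d members, fewer than %d folds",
                 names(tab)[which.min(tab)], min(tab), folds))
  plan <- with_seed(seed, lapply(seq_len(repeats), function(r) {
    assign_fold <- integer(length(labels))
    names(assign_fold) <- names(labels)
    for (cls in unique(labels)) {
      ids <- sample(names(labels)[labels == cls])
      assign_fold[ids] <- rep_len(seq_len(folds), length(ids))
    }
    lapply(seq_len(folds), function(f) names(assign_fold)[assign_fold == f])
  }))
  structure(plan, labels = labels, folds = as.integer(folds),
            repeats = as.integer(repeats), seed = as.integer(seed),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, ties counted 1/2 (Mann-Whitney statistic via midranks).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @return AUROC in `[0, 1]`; `NA` when only one class is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Sum over descending score thresholds of precision times the recall
#' increment, with tied scores processed as one threshold group.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; `NA` when no positives are present.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  if (np == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_g); nseen <- cumsum(n_g)
  prec <- tp / nseen
  rec <- tp / np
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Per-cohort confusion rates at a decision threshold
#'
#' TPR/FNR/FPR/TNR per cohort from a 2x2 contingency table at the given
#' threshold. A cohort with no positive mice reports `TPR = FNR = 0` (the
#' reporting convention for tumor-free control animals); likewise
#' `FPR = TNR = 0` with no negatives.
#'
#' @param scores,labels Scores and 0/1 labels.
#' @param cohorts Cohort tag per sample.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Data frame with one row per cohort.
#' @export
confusion_rates <- function(scores, labels, cohorts, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  pred <- as.integer(scores >= threshold)
  out <- lapply(unique(cohorts), function(cn) {
    i <- cohorts == cn
    tp <- sum(pred[i] == 1 & labels[i] == 1)
    fn <- sum(pred[i] == 0 & labels[i] == 1)
    fp <- sum(pred[i] == 1 & labels[i] == 0)
    tn <- sum(pred[i] == 0 & labels[i] == 0)
    np <- tp + fn; nn <- fp + tn
    data.frame(cohort = cn,
               tpr = if (np > 0) tp / np else 0,
               fnr = if (np > 0) fn / np else 0,
               fpr = if (nn > 0) fp / nn else 0,
               tnr = if (nn > 0) tn / nn else 0)
  })
  do.call(rbind, out)
}

aggregate_metrics <- function(per_fold) {
  vals <- per_fold[c("auroc", "auprc")]
  data.frame(metric = c("auroc", "auprc"),
             mean = vapply(vals, function(x) mean(x, na.rm = TRUE), numeric(1)),
             sd = vapply(vals, function(x) stats::sd(x[!is.na(x)]), numeric(1)))
}

#' Run one prediction task under repeated cross-validation
#'
#' Builds the task labels, extracts (or reuses) the per-mouse features for
#' the requested day window and modality set, and for every repeat x fold
#' trains the classifier head on the training mice and scores the test mice.
#' Reports per-fold AUROC/AUPRC, their mean/SD, and per-cohort confusion
#' rates pooled at threshold 0.5.
#'
#' @param cohort A rendered `tefuse_cohort`.
#' @param task `"progression"`, `"treatment"` or `"biomarker"`.
#' @param feature_days Measurement days the model may use (the progression
#'   task default is the three pre-progression time points 8, 11, 14).
#' @param modalities Modalities available to the model; the NMR branch is
#'   dropped automatically for the biomarker task (its panels are the
#'   target, not an input).
#' @param biomarker Biomarker name for `task = "biomarker"`.
#' @param model A `tefuse_model`, or `NULL` to build one from `model_config`.
#' @param model_config Configuration used when `model` is `NULL`.
#' @param encoding Optional [encode_cohort()] cache to reuse.
#' @param repeats,folds Cross-validation plan (default 5 x 3).
#' @param seed Seed for folds and head initialization.
#' @param control A [train_control()].
#' @param null_labels Permute labels (seeded) before folding: the no-signal
#'   calibration control.
#' @return Object of class `tefuse_metrics`.
#' @export
run_task <- function(cohort, task = c("progression", "treatment", "biomarker"),
                     feature_days = c(8L, 11L, 14L),
                     modalities = c("mri", "hpmrs", "nmr", "volume"),
                     biomarker = NULL, model = NULL,
                     model_config = tefuse::model_config(width_scale = 1/8),
                     encoding = NULL, repeats = 5L, folds = 3L, seed = 1L,
                     control = train_control(), null_labels = FALSE) {
  task <- match.arg(task)
  if (length(modalities) == 0L) stop("empty modality set")
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (task == "biomarker") modalities <- setdiff(modalities, "nmr")
  if (task == "progression" && any(feature_days > 24))
    stop("progression features must come from days 1-24")
  lab_df <- task_labels(cohort, task, biomarker)
  lab_df <- lab_df[!is.na(lab_df$label), , drop = FALSE]
  ids_all <- vapply(cohort, `[[`, character(1), "mouse_id")
  keep <- match(lab_df$mouse_id, ids_all)
  model <- model %||% build_model(model_config)
  encoding <- encoding %||% encode_cohort(cohort, model)
  X <- model_features(cohort, model, encoding, feature_days, modalities)
  blocks <- attr(X, "blocks")
  X <- structure(X[lab_df$mouse_id, , drop = FALSE], blocks = blocks)
  y0 <- stats::setNames(lab_df$label, lab_df$mouse_id)
  # Null control: an independent label permutation per repeat, so the
  # reported mean averages over permutations rather than inheriting one
  # permutation's accidental correlation with the features.
  y_rep <- lapply(seq_len(repeats), function(r) {
    if (!null_labels) return(y0)
    y <- y0; y[] <- with_seed(sub_seed(seed, 17L + r), sample(unname(y0))); y
  })
  per_fold <- list(); pooled_scores <- numeric(0); pooled_y <- numeric(0)
  pooled_cohort <- character(0)
  k <- 0L
  for (r in seq_len(repeats)) {
    y <- y_rep[[r]]
    plan <- make_folds(y, 1L, folds, seed = sub_seed(seed, 1000L + r))
    for (f in seq_len(folds)) {
      k <- k + 1L
      test_ids <- plan[[1L]][[f]]
      train_ids <- setdiff(names(y), test_ids)
      ctl <- control; ctl$seed <- sub_seed(seed, 100L + k)
      head <- fit_head(structure(X[train_ids, , drop = FALSE],
                                 blocks = attr(X, "blocks")),
                       unname(y[train_ids]), model$config, ctl)
      sc <- predict_head(head, X[test_ids, , drop = FALSE])
      per_fold[[k]] <- data.frame(repeat_ = r, fold = f,
                                  auroc = auroc(sc, unname(y[test_ids])),
                                  auprc = auprc(sc, unname(y[test_ids])))
      pooled_scores <- c(pooled_scores, sc)
      pooled_y <- c(pooled_y, unname(y[test_ids]))
      pooled_cohort <- c(pooled_cohort,
                         lab_df$cohort[match(test_ids, lab_df$mouse_id)])
    }
  }
  pf <- do.call(rbind, per_fold)
  structure(list(task = task, feature_days = feature_days,
                 modalities = modalities, n_mice = length(y),
                 per_fold = pf, summary = aggregate_metrics(pf),
                 confusion = confusion_rates(pooled_scores, pooled_y,
                                             pooled_cohort),
                 seed = seed),
            class = "tefuse_metrics")
}

#' @export
print.tefuse_metrics <- function(x, ...) {
  cat(sprintf("task: %s | days {%s} | modalities {%s} | n = %d mice\n",
              x$task, paste(x$feature_days, collapse = ","),
              paste(x$modalities, collapse = ","), x$n_mice))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %.3f (SD %.3f) over %d folds\n",
                toupper(s$metric[i]), s$mean[i], s$sd[i], nrow(x$per_fold)))
  cat("  per-cohort confusion at threshold 0.5:\n")
  print(x$confusion, row.names = FALSE)
  invisible(x)
}
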