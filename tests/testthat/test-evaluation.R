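# Fold construction and metric oracles.

test_that("stratified folds partition mice and balance classes", {
  labels <- setNames(c(1, 1, 1, 0, 0, 0), paste0("m", 1:6))
  plan <- make_folds(labels, repeats = 1, folds = 3, seed = 2)
  for (f in plan[[1]]) {
    expect_length(f, 2L)
    expect_identical(sort(unname(labels[f])), c(0, 1))
  }
  expect_identical(sort(unlist(plan[[1]])), sort(names(labels)))
  expect_identical(make_folds(labels, 2, 3, seed = 9),
                   make_folds(labels, 2, 3, seed = 9))
  plan5 <- make_folds(setNames(rep(c(0, 1), each = 6), paste0("m", 1:12)),
                      repeats = 5, folds = 3, seed = 1)
  expect_identical(sum(lengths(unlist(plan5, recursive = FALSE))) , 60L)
  expect_length(unlist(plan5, recursive = FALSE), 15L)
  expect_error(make_folds(setNames(c(1, 0, 0, 0), paste0("m", 1:4)), 1, 3, 1),
               "fewer than")
})

test_that("auroc equals the brute-force concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_true(is.na(auroc(c(0.1, 0.2), c(1, 1))))
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_identical(auroc(s, y), auroc_oracle(s, y))
  }
})

test_that("auprc behaves at the extremes and on a hand-worked case", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  # descending scores, labels 1,0,1,0: AP = 1/2 * 1 + 1/2 * 2/3
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_true(is.na(auprc(c(0.3, 0.4), c(0, 0))))
})

test_that("confusion rates match a contingency-table oracle per cohort", {
  expect_identical(
    confusion_rates(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), rep("a", 4))[, -1],
    data.frame(tpr = 1, fnr = 0, fpr = 0, tnr = 1))
  # all-negative cohort with no false alarms reports the 0/0 convention
  r <- confusion_rates(c(0.2, 0.3), c(0, 0), rep("control", 2))
  expect_identical(r$tpr, 0); expect_identical(r$fnr, 0)
  expect_identical(r$tnr, 1); expect_identical(r$fpr, 0)
  set.seed(14)
  for (i in 1:20) {
    n <- 10
    s <- runif(n); y <- rbinom(n, 1, 0.5); g <- sample(c("a", "b"), n, TRUE)
    out <- confusion_rates(s, y, g, threshold = 0.5)
    for (cn in unique(g)) {
      i2 <- g == cn; pred <- as.integer(s[i2] >= 0.5)
      tp <- sum(pred & y[i2]); fn <- sum(!pred & y[i2])
      fp <- sum(pred & !y[i2]); tn <- sum(!pred & !y[i2])
      row <- out[out$cohort == cn, ]
      if (tp + fn > 0) {
        expect_equal(row$tpr, tp / (tp + fn))
        expect_equal(row$fnr, fn / (tp + fn))
        expect_equal(row$tpr + row$fnr, 1, tolerance = 1e-12)
      } else {
        expect_identical(row$tpr, 0); expect_identical(row$fnr, 0)
      }
      if (fp + tn > 0) expect_equal(row$fpr, fp / (fp + tn))
    }
  }
})

test_that("reported summaries equal recomputation from per-fold values", {
  fx <- bench_fixture()
  res <- run_task(fx$cohort, "progression", feature_days = c(8, 11, 14),
                  model = tiny_model(), encoding = fx$encoding,
                  repeats = 2, folds = 3, seed = 3)
  expect_identical(nrow(res$per_fold), 6L)
  expect_equal(res$summary$mean[res$summary$metric == "auroc"],
               mean(res$per_fold$auroc), tolerance = 1e-12)
  expect_equal(res$summary$sd[res$summary$metric == "auprc"],
               sd(res$per_fold$auprc), tolerance = 1e-12)
  # determinism under seed
  res2 <- run_task(fx$cohort, "progression", feature_days = c(8, 11, 14),
                   model = tiny_model(), encoding = fx$encoding,
                   repeats = 2, folds = 3, seed = 3)
  expect_identical(res$per_fold, res2$per_fold)
  expect_error(run_task(fx$cohort, "progression", modalities = character(0)),
               "empty modality")
  expect_error(run_task(fx$cohort, "progression", feature_days = c(8, 28)),
               "days 1-24")
})
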