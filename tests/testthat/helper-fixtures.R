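# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# Width-scale 1/8 model used by every forward-pass test.
tiny_model <- function() memo("tiny_model",
  build_model(model_config(width_scale = 1/8, seed = 7)))

# Planted-signal benchmark cohort plus its day 8/11/14 encoding cache.
bench_fixture <- function() memo("bench", {
  coh <- benchmark_cohort(seed = 11)
  enc <- encode_cohort(coh, tiny_model(), days = c(8L, 11L, 14L))
  list(cohort = coh, encoding = enc)
})

# Small fully-observed rendered cohort (4 control + 4 untreated, days
# 8/11/14, uniform day-14 endpoint) for end-to-end single-mouse checks.
small_rendered <- function() memo("small_rendered",
  generate_cohort(cohort_config(
    n_control = 4L, n_untreated = 4L, n_treated = 0L,
    day_grid = c(8L, 11L, 14L), dropout_mri = 0, dropout_hpmrs = 0,
    nmr_entry_dropout = 0.2, fixed_terminal_day = 14L, seed = 3L)))

# Plan-only (unrendered) cohort at the default study conditions.
plan_cohort <- function() memo("plan_cohort",
  generate_cohort(cohort_config(n_control = 6L, n_untreated = 14L,
                                n_treated = 8L, seed = 21L), render = FALSE))

# Brute-force pairwise-concordance AUROC oracle (ties count 1/2).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
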