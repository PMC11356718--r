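# Fixed benchmark configurations for the learnability and calibration
# studies. These are deliberate, frozen study conditions (documented in the
# methods vignette), shared by the test-suite and the acceptance script.

#' Planted-signal learnability cohort
#'
#' A progression-study cohort whose labels are driven by the planted growth
#' signal alone: 20 tumor-free controls and 40 untreated PDX mice, all
#' followed on the full measurement grid to a uniform endpoint at day 35
#' with no modality dropout, growth-rate mean 0.10/day with per-mouse SD
#' 0.06/day and measurement noise 0.3 mm3, so that roughly half the PDX mice
#' cross the 25 mm3 progression threshold by day 35. Early euthanasia and
#' scan dropout are deliberately absent: they would inject label noise
#' unrelated to the planted signal, and missingness handling is exercised by
#' its own contracts, not by this benchmark. Used to verify that the
#' pipeline can learn (planted cohort), that it reports chance on permuted
#' labels (null control), and that three time points beat one (temporal
#' trend).
#'
#' @param seed Cohort seed.
#' @param n_control,n_untreated Cohort sizes.
#' @return A rendered `tefuse_cohort`.
#' @export
benchmark_cohort <- function(seed = 1L, n_control = 20L, n_untreated = 40L) {
  cc <- cohort_config(n_control = n_control, n_untreated = n_untreated,
                      n_treated = 0L,
                      day_grid = c(8L, 11L, 14L, 21L, 24L, 28L, 35L),
                      dropout_mri = 0, dropout_hpmrs = 0,
                      fixed_terminal_day = 35L,
                      seed = seed)
  gm <- growth_model(growth_rate = 0.10, growth_rate_sd = 0.06, noise_sd = 0.3)
  generate_cohort(cc, gm)
}
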