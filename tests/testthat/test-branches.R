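# Branch encoders: plane 3D encoder, HPMRS 2D encoder, tabular branch
# (imputation, NMR recurrence, volume features).

test_that("plane encoders emit the expected flattened widths at reduced scale", {
  m <- tiny_model()
  ch3 <- m$config$plane_conv[[3]]$out_channels
  widths <- c(sagittal = 3 * 3 * 4, axial = 2 * 3 * 4, coronal = 4 * 3 * 4) * ch3
  for (pl in names(plane_shapes())) {
    v <- plane_encoder(array(0.1, plane_shapes()[[pl]]), m, pl)
    expect_length(v, widths[[pl]])
    expect_true(all(v >= 0))
  }
  expect_error(plane_encoder(array(0, c(5, 107, 147)), m, "sagittal"), "shape")
})

test_that("the HPMRS encoder follows the reference stage shapes and masks days", {
  m <- tiny_model()
  sh <- model_shapes(m$config)$hpmrs
  expect_identical(sh[[1]]$pool[2:3], c(5L, 843L))
  expect_identical(sh[[2]]$pool[2:3], c(1L, 280L))
  v <- hpmrs_encoder(matrix(0, 18, 2532), m)
  expect_length(v, 280L)
  expect_true(all(v >= 0))
  expect_error(hpmrs_encoder(matrix(0, 18, 100), m), "shape")
  # temporal aggregation returns the final hidden state and honors masking
  set.seed(8)
  X <- matrix(rnorm(3 * 280, sd = 0.1), 3, 280)
  h <- hp_temporal(X, m, day_mask = c(FALSE, FALSE, TRUE))
  h2 <- hp_temporal(X[1:2, , drop = FALSE], m)
  expect_identical(h, h2)
  expect_length(h, m$config$hp_rnn$hidden)
})

test_that("cohort-mean imputation fills, flags, falls back, and never edits observed", {
  tab <- data.frame(cohort = c("untreated", "untreated"), day = c(8, 11),
                    valine = c(3, NA), alanine = c(2, 5))
  vals <- c(valine = NA_real_, alanine = 7)
  obs <- c(valine = FALSE, alanine = TRUE)
  out <- impute_cohort_mean(vals, obs, "untreated", 8, tab)
  expect_equal(out$values[["valine"]], 3)
  expect_equal(out$values[["alanine"]], 7)          # observed untouched
  expect_identical(unname(out$mask), c(TRUE, FALSE))
  # nearest-day fallback when the same day has no observed mean
  out2 <- impute_cohort_mean(vals, obs, "untreated", 11, tab)
  expect_equal(out2$values[["valine"]], 3)
  # idempotent on a fully-imputed panel
  out3 <- impute_cohort_mean(out$values, obs, "untreated", 8, tab)
  expect_identical(out3$values, out$values)
  # a biomarker never observed anywhere in the cohort is an error, by name
  tab2 <- tab; tab2$valine <- NA_real_
  expect_error(impute_cohort_mean(vals, obs, "untreated", 8, tab2), "valine")
})

test_that("panels imputed from a cohort keep means from observed values only", {
  coh <- small_rendered()
  tab <- nmr_cohort_table(coh)
  expect_true(all(c("cohort", "day", nmr_panel_reference()$biomarker) %in%
                  names(tab)))
  unt <- tab[tab$cohort == "untreated", , drop = FALSE]
  raw <- do.call(rbind, lapply(Filter(function(r) r$cohort == "untreated", coh),
                 function(r) { p <- r$nmr[[1]]
                               v <- p$values; v[!p$observed] <- NA; v }))
  expect_equal(unname(unt$alanine[unt$day == 14]),
               mean(raw[, "alanine"], na.rm = TRUE), tolerance = 1e-12)
})

test_that("NMR recurrence ignores masked entries and counts 180 parameters", {
  m <- tiny_model()
  expect_identical(count_parameters(m$config$nmr_rnn), 180L)
  set.seed(9)
  P <- matrix(rnorm(18), 2, 9)
  M <- matrix(FALSE, 2, 9); M[1, 3] <- TRUE; M[2, 7] <- TRUE
  h <- nmr_temporal(P, m, entry_mask = M)
  P2 <- P; P2[1, 3] <- 1e6; P2[2, 7] <- -42
  expect_identical(h, nmr_temporal(P2, m, entry_mask = M))
  # all entries masked equals the recurrence of zero inputs
  Mall <- matrix(TRUE, 2, 9)
  expect_identical(nmr_temporal(P, m, entry_mask = Mall),
                   nmr_temporal(matrix(0, 2, 9), m))
  expect_length(h, 9L)
})

test_that("volume features take the three most recent values, zero-padded", {
  v <- c(`8` = 1, `11` = 2, `14` = 3)
  expect_identical(volume_features(v)$values, c(1, 2, 3))
  expect_identical(volume_features(c(`8` = 5))$values, c(5, 0, 0))
  expect_identical(volume_features(c(`8` = 5))$mask, c(1, 0, 0))
  expect_identical(volume_features(numeric(0))$values, c(0, 0, 0))
  # a fourth, older measurement is dropped; the window is honored
  v4 <- c(`5` = 9, `8` = 1, `11` = 2, `14` = 3)
  expect_identical(volume_features(v4)$values, c(1, 2, 3))
  expect_identical(volume_features(v4, c(-Inf, 11))$values, c(9, 1, 2))
})
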