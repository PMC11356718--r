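# Synthetic cohort simulator: growth law, exchange kinetics, plane
# rendering, NMR panels, missingness and whole-cohort generation.

test_that("control mice carry no tumor and unknown cohorts are rejected", {
  v <- simulate_growth("control", growth_model(), c(8, 14, 21), seed = 1)
  expect_identical(unname(v), c(0, 0, 0))
  expect_identical(names(v), c("8", "14", "21"))
  expect_error(simulate_growth("mouse", growth_model(), c(8, 14)), "unknown cohort")
  expect_error(simulate_growth("untreated", growth_model(), integer(0)), "non-empty")
  expect_error(simulate_growth("untreated", growth_model(), c(8, 8, 14)), "increasing")
})

test_that("zero-noise growth follows the closed-form exponential from first measurement", {
  gm <- growth_model(v0_mean = 1.59, v0_sd = 0, growth_rate = 0.1,
                     growth_rate_sd = 0, noise_sd = 0)
  days <- c(8, 11, 14, 21)
  v <- simulate_growth("untreated", gm, days, seed = 4)
  expect_equal(unname(v), 1.59 * exp(0.1 * (days - 8)), tolerance = 1e-12)
  # treated mice track the untreated curve until the first radiotherapy day
  gm2 <- growth_model(v0_mean = 1.59, v0_sd = 0, growth_rate = 0.1,
                      growth_rate_sd = 0, regression_rate = 0.2,
                      regression_rate_sd = 0, noise_sd = 0)
  vt <- simulate_growth("treated", gm2, c(8, 14, 24, 28, 35), seed = 4)
  expect_equal(unname(vt[1:3]), 1.59 * exp(0.1 * (c(8, 14, 24) - 8)), tolerance = 1e-12)
  v25 <- 1.59 * exp(0.1 * 17)
  expect_equal(unname(vt[4:5]), v25 * exp(-0.2 * (c(28, 35) - 25)), tolerance = 1e-12)
  expect_lt(vt[["35"]], vt[["24"]])
})

test_that("default calibration reproduces the 1.59 mm3 first-measurement mean", {
  first <- vapply(seq_len(1000), function(s)
    simulate_growth("untreated", growth_model(), c(8, 11, 14), seed = s)[[1]],
    numeric(1))
  expect_lt(abs(mean(first) - 1.59) / 1.59, 0.10)
})

test_that("two-site exchange honors the no-conversion and conservation limits", {
  em0 <- exchange_model(k_pl = 0, t_grid = seq(0, 60, length.out = 200))
  S <- simulate_hpmrs(em0, noise_sd = 0)
  expect_true(all(S[hpmrs_rows()$lactate, ] == 0))
  # no-decay limit: total signal in every time column equals p0
  em <- exchange_model(p0 = 1, k_pl = 0.03, r1p = 0, r1l = 0,
                       t_grid = seq(0, 60, length.out = 300))
  S2 <- simulate_hpmrs(em, noise_sd = 0)
  expect_true(all(abs(colSums(S2) - 1) <= 1e-9))
  expect_error(exchange_model(k_pl = -0.1), "non-negative")
})

test_that("closed-form exchange matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  for (pars in list(c(0.02, 1/30, 1/30), c(0.3, 0.05, 0.2), c(1, 1, 0.7))) {
    em <- exchange_model(k_pl = pars[1], r1p = pars[2], r1l = pars[3],
                         t_grid = seq(0, 90, length.out = 181))
    sol <- exchange_solution(em)
    ode <- deSolve::lsoda(
      y = c(P = em$p0, L = 0), times = em$t_grid,
      func = function(t, y, p)
        list(c(-(p[1] + p[2]) * y[1], p[1] * y[1] - p[3] * y[2])),
      parms = pars, rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(sol$pyruvate - ode[, "P"])), 1e-6)
    expect_lt(max(abs(sol$lactate - ode[, "L"])), 1e-6)
  }
})

test_that("plane volumes have the fixed geometries and scale with tumor volume", {
  pv <- render_plane_volumes(0, noise_sd = 0)
  expect_identical(lapply(pv, dim), plane_shapes())
  expect_true(all(vapply(pv, function(x) all(x == 0), logical(1))))
  expect_identical(dim(render_plane_volumes(5, noise_sd = 0, seed = 1)$sagittal),
                   c(7L, 107L, 147L))
  # hyperintense voxel count doubles with volume (within 10% over seeds)
  ratios <- vapply(1:5, function(s) {
    a <- render_plane_volumes(5, seed = s)$coronal
    b <- render_plane_volumes(10, seed = s)$coronal
    sum(b > 0.5) / sum(a > 0.5)
  }, numeric(1))
  expect_true(abs(mean(ratios) - 2) < 0.2)
  expect_error(render_plane_volumes(-1), ">= 0")
})

test_that("NMR panels are 9-wide, deterministic under seed, and calibrated for controls", {
  p <- simulate_nmr_panel("control", 14, seed = 5)
  expect_length(p$values, 9L)
  expect_identical(p, simulate_nmr_panel("control", 14, seed = 5))
  draws <- vapply(seq_len(1000), function(s)
    simulate_nmr_panel("control", 14, seed = s)$values, numeric(9))
  ref <- nmr_panel_reference()
  se <- ref$sd / sqrt(1000)
  expect_true(all(abs(rowMeans(draws) - ref$mean) <= 2 * se))
  # tumor cohorts are shifted away from the control means at late days
  tum <- vapply(seq_len(200), function(s)
    simulate_nmr_panel("untreated", 21, seed = s)$values, numeric(9))
  expect_gt(mean(tum["alanine", ]), ref$mean[ref$biomarker == "alanine"])
})

test_that("missingness keeps the one-MRI-or-one-HPMRS guarantee and censors at terminal day", {
  coh <- plan_cohort()
  for (rec in coh) {
    expect_true(length(rec$plane_days) >= 1 || length(rec$hpmrs_days) >= 1)
    expect_true(all(rec$plane_days <= rec$terminal_day))
    expect_true(all(rec$hpmrs_days <= rec$terminal_day))
    expect_true(all(as.integer(names(rec$volumes)) <= rec$terminal_day))
    expect_identical(names(rec$nmr), as.character(rec$terminal_day))
  }
  expect_error(cohort_config(dropout_mri = 1, dropout_hpmrs = 1), "aggressive")
  # zero dropout removes nothing beyond the terminal-day rule
  rec <- generate_cohort(cohort_config(
    n_control = 0L, n_untreated = 1L, n_treated = 0L,
    day_grid = c(8L, 11L, 14L, 21L), dropout_mri = 0, dropout_hpmrs = 0,
    fixed_terminal_day = 14L, seed = 2L), render = FALSE)[[1]]
  expect_identical(rec$plane_days, c(8L, 11L, 14L))
  expect_identical(rec$hpmrs_days, c(8L, 11L, 14L))
  expect_false("21" %in% c(names(rec$volumes), names(rec$nmr)))
})

test_that("generate_cohort matches configured counts and is byte-reproducible", {
  cc <- cohort_config(n_control = 17L, n_untreated = 51L, n_treated = 0L, seed = 9L)
  coh <- generate_cohort(cc, render = FALSE)
  expect_length(coh, 68L)
  tags <- table(vapply(coh, `[[`, character(1), "cohort"))
  expect_identical(as.integer(tags[c("control", "untreated")]), c(17L, 51L))
  coh2 <- generate_cohort(cc, render = FALSE)
  expect_identical(serialize(coh, NULL), serialize(coh2, NULL))
  empty <- generate_cohort(cohort_config(0L, 0L, 0L, seed = 1L), render = FALSE)
  expect_length(empty, 0L)
  # rendered generation is deterministic too (single mouse to stay light)
  c1 <- generate_cohort(cohort_config(0L, 1L, 0L, day_grid = c(8L, 11L),
                                      fixed_terminal_day = 11L, seed = 5L))
  c2 <- generate_cohort(cohort_config(0L, 1L, 0L, day_grid = c(8L, 11L),
                                      fixed_terminal_day = 11L, seed = 5L))
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
})
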