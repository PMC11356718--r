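# Synthetic PDX-glioblastoma cohort simulator. Generates, from a seed, the
# longitudinal multi-modal records the model consumes: tumor-volume series,
# pre-segmented three-plane T2-w volumes, dynamic hyperpolarized 13C spectra,
# ex vivo NMR metabolite panels, and the euthanasia-driven missingness
# structure of a real preclinical study.

#' Fixed plane-volume geometries
#'
#' Spatial extents of the three single-channel anatomical plane volumes
#' (slices, height, width), back-derived from the encoder output shapes with
#' valid convolution and non-overlapping pooling.
#' @return Named list of integer 3-vectors.
#' @export
plane_shapes <- function() {
  list(sagittal = c(7L, 107L, 147L),
       axial    = c(6L, 107L, 147L),
       coronal  = c(9L, 107L, 147L))
}

#' @rdname plane_shapes
#' @export
hpmrs_shape <- function() c(18L, 2532L)

COHORT_TAGS <- c("control", "untreated", "treated")

assert_cohort_tag <- function(tag) {
  if (!is.character(tag) || length(tag) != 1L || !tag %in% COHORT_TAGS)
    stop(sprintf("unknown cohort tag %s (use one of %s)",
                 deparse(tag), paste(COHORT_TAGS, collapse = ", ")), call. = FALSE)
  tag
}

#' Tumor growth model
#'
#' Exponential growth with Gaussian measurement noise, and exponential
#' regression after the first radiotherapy day for treated mice. Time is
#' measured from the first scheduled measurement day, so the expected volume
#' at first measurement equals `v0_mean`. Per-mouse rate heterogeneity
#' (`growth_rate_sd`, `regression_rate_sd`) makes outcome labels vary within
#' a cohort. Volumes are clamped at zero.
#'
#' @param v0_mean,v0_sd Volume (mm3) at first measurement; defaults follow
#'   the study's printed first-measurement mean of 1.59 mm3.
#' @param growth_rate,growth_rate_sd Per-day log-growth rate (mean, per-mouse SD).
#' @param regression_rate,regression_rate_sd Per-day post-radiotherapy
#'   log-shrinkage (mean, per-mouse SD).
#' @param noise_sd Additive measurement noise SD (mm3).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(v0_mean = 1.59, v0_sd = 0.5,
                         growth_rate = 0.08, growth_rate_sd = 0.06,
                         regression_rate = 0.03, regression_rate_sd = 0.05,
                         noise_sd = 0.5) {
  stopifnot(v0_mean >= 0, v0_sd >= 0, noise_sd >= 0,
            growth_rate_sd >= 0, regression_rate_sd >= 0)
  structure(list(v0_mean = v0_mean, v0_sd = v0_sd,
                 growth_rate = growth_rate, growth_rate_sd = growth_rate_sd,
                 regression_rate = regression_rate,
                 regression_rate_sd = regression_rate_sd,
                 noise_sd = noise_sd),
            class = "growth_model")
}

#' Simulate a tumor-volume series for one mouse
#'
#' Non-PDX control mice carry no tumor and return all-zero volumes.
#' PDX mice grow exponentially from the first scheduled day
#' (`v(t) = v0 * exp(r * (t - day_grid[1]))` in expectation); treated mice
#' follow the untreated trajectory until the first radiotherapy day, then
#' shrink exponentially. Measurement noise is additive Gaussian and the
#' result is clamped at zero.
#'
#' @param cohort_tag One of `"control"`, `"untreated"`, `"treated"`.
#' @param gm A [growth_model()].
#' @param day_grid Strictly increasing integer days post-implantation.
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @param rt_days Radiotherapy days (default days 25 and 27).
#' @return Named numeric vector, day -> volume (mm3).
#' @export
simulate_growth <- function(cohort_tag, gm = growth_model(), day_grid,
                            seed = NULL, rt_days = c(25L, 27L)) {
  assert_cohort_tag(cohort_tag)
  if (length(day_grid) == 0L) stop("'day_grid' must be non-empty")
  if (is.unsorted(day_grid, strictly = TRUE)) stop("'day_grid' must be strictly increasing")
  with_seed(seed, {
    days <- as.numeric(day_grid)
    if (cohort_tag == "control") {
      v <- rep(0, length(days))
    } else {
      v0 <- max(stats::rnorm(1, gm$v0_mean, gm$v0_sd), 0)
      r <- stats::rnorm(1, gm$growth_rate, gm$growth_rate_sd)
      t0 <- days[1]
      v <- v0 * exp(r * (days - t0))
      if (cohort_tag == "treated") {
        t_rt <- min(rt_days)
        s <- stats::rnorm(1, gm$regression_rate, gm$regression_rate_sd)
        post <- days > t_rt
        v_rt <- v0 * exp(r * (t_rt - t0))
        v[post] <- v_rt * exp(-s * (days[post] - t_rt))
      }
      if (gm$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, gm$noise_sd)
      v <- pmax(v, 0)
    }
    names(v) <- day_grid
    v
  })
}

#' Two-site exchange model for hyperpolarized pyruvate
#'
#' Standard description of dynamic HP 13C data: injected pyruvate converts to
#' lactate at rate `k_pl` while both pools relax with rates `r1p`, `r1l`:
#' `P(t) = p0 exp(-(k_pl + r1p) t)` and `dL/dt = k_pl P - r1l L`, `L(0) = 0`.
#'
#' @param p0 Initial pyruvate signal (arbitrary units, default 1).
#' @param k_pl Pyruvate-to-lactate conversion rate (1/s).
#' @param r1p,r1l Longitudinal relaxation rates (1/s).
#' @param t_grid Acquisition time points (s); its length fixes the number of
#'   time columns of the dynamic spectrum.
#' @return An object of class `exchange_model`.
#' @export
exchange_model <- function(p0 = 1, k_pl = 0.02, r1p = 1/30, r1l = 1/30,
                           t_grid = seq(0, 90, length.out = 2532L)) {
  if (k_pl < 0 || r1p < 0 || r1l < 0) stop("rates must be non-negative")
  stopifnot(p0 >= 0, length(t_grid) >= 1)
  structure(list(p0 = p0, k_pl = k_pl, r1p = r1p, r1l = r1l,
                 t_grid = as.numeric(t_grid)),
            class = "exchange_model")
}

#' Closed-form pyruvate and lactate time courses
#'
#' Analytic solution of the two-site exchange system; used both to render
#' synthetic spectra and as the quantity checked against an independent ODE
#' integration in the test-suite.
#'
#' @param em An [exchange_model()].
#' @param t Time points (s); defaults to `em$t_grid`.
#' @return List with numeric vectors `pyruvate` and `lactate`.
#' @export
exchange_solution <- function(em, t = em$t_grid) {
  a <- em$k_pl + em$r1p
  P <- em$p0 * exp(-a * t)
  if (abs(a - em$r1l) < 1e-12) {
    L <- em$p0 * em$k_pl * t * exp(-a * t)
  } else {
    L <- em$p0 * em$k_pl * (exp(-em$r1l * t) - exp(-a * t)) / (a - em$r1l)
  }
  list(pyruvate = P, lactate = L)
}

# Truncated Gaussian line shape over spectral bins, normalized to unit sum so
# that summing a spectrum over bins recovers the pool signal exactly.
line_shape <- function(n_bins, center, width = 0.8, halfwidth_bins = 3L) {
  i <- seq_len(n_bins)
  g <- exp(-0.5 * ((i - center) / width)^2)
  g[abs(i - center) > halfwidth_bins] <- 0
  g / sum(g)
}

#' Rows carrying the pyruvate / lactate resonance
#'
#' The synthetic spectral axis places the pyruvate line at bin 5 and the
#' lactate line at bin 14, each with compact support of +/-3 bins.
#' @return Named list of integer row indices.
#' @export
hpmrs_rows <- function() list(pyruvate = 2:8, lactate = 11:17)

#' Simulate one dynamic HPMRS intensity matrix
#'
#' Renders the two-site exchange time courses as truncated Gaussian line
#' shapes along the spectral axis (rows) against acquisition time (columns),
#' plus optional seeded Gaussian noise. Row/column convention: 18 spectral
#' bins by `length(em$t_grid)` time points.
#'
#' @param em An [exchange_model()].
#' @param noise_sd Additive noise SD (signal units); 0 disables noise.
#' @param seed Integer seed or `NULL`.
#' @param n_bins Number of spectral bins (default 18).
#' @return Numeric matrix `(n_bins, length(em$t_grid))` with attribute
#'   `"day"` unset; wrap in a record to stamp the day.
#' @export
simulate_hpmrs <- function(em, noise_sd = 0.005, seed = NULL, n_bins = 18L) {
  sol <- exchange_solution(em)
  g_p <- line_shape(n_bins, 5)
  g_l <- line_shape(n_bins, 14)
  S <- outer(g_p, sol$pyruvate) + outer(g_l, sol$lactate)
  if (noise_sd > 0)
    S <- S + with_seed(seed, matrix(stats::rnorm(length(S), 0, noise_sd), nrow(S)))
  S
}

#' Render the three-plane volumes for one imaging day
#'
#' Produces pre-segmented single-channel volumes: zero background plus a
#' hyperintense (intensity 1) ellipsoid centered in each plane volume whose
#' voxel count is proportional to the tumor volume (100 voxels per mm3),
#' with optional Gaussian background noise. A zero volume yields pure
#' background.
#'
#' @param volume_mm3 Tumor volume in mm3 (>= 0).
#' @param noise_sd Background noise SD (default 0.05; 0 disables).
#' @param seed Integer seed or `NULL`.
#' @param voxels_per_mm3 Rendering density (voxels per mm3).
#' @return Named list of arrays `sagittal`, `axial`, `coronal` with the
#'   [plane_shapes()] geometries.
#' @export
render_plane_volumes <- function(volume_mm3, noise_sd = 0.05, seed = NULL,
                                 voxels_per_mm3 = 100) {
  if (!is.numeric(volume_mm3) || volume_mm3 < 0) stop("'volume_mm3' must be >= 0")
  shapes <- plane_shapes()
  with_seed(seed, {
    lapply(shapes, function(dm) {
      x <- array(0, dm)
      n_target <- volume_mm3 * voxels_per_mm3
      if (n_target >= 1) {
        # ellipsoid semi-axes proportional to the array extents
        s <- min((n_target / (4 / 3 * pi * prod(dm / 2)))^(1 / 3), 1)
        ax <- pmax(s * dm / 2, .51)
        ctr <- (dm + 1) / 2
        d1 <- ((seq_len(dm[1]) - ctr[1]) / ax[1])^2
        d2 <- ((seq_len(dm[2]) - ctr[2]) / ax[2])^2
        d3 <- ((seq_len(dm[3]) - ctr[3]) / ax[3])^2
        mask <- outer(outer(d1, d2, "+"), d3, "+") <= 1
        x[mask] <- 1
      }
      if (noise_sd > 0) x <- x + array(stats::rnorm(length(x), 0, noise_sd), dm)
      x
    })
  })
}

#' Reference NMR metabolite panel
#'
#' The nine-metabolite panel: amino-acid metabolism (valine, alanine,
#' glycine), cell-membrane metabolism (glycerophosphocholine, phosphocholine,
#' phosphoethanolamine), reactive-oxygen metabolism (glutathione, NAD), plus
#' glutamate. Normal means/SDs are plausible brain-tissue pool sizes in
#' arbitrary concentration units; the composition is configuration, not a
#' contract.
#'
#' @return Data frame with columns `biomarker`, `group`, `mean`, `sd`.
#' @export
nmr_panel_reference <- function() {
  data.frame(
    biomarker = c("valine", "alanine", "glycine",
                  "glycerophosphocholine", "phosphocholine", "phosphoethanolamine",
                  "glutathione", "nad", "glutamate"),
    group = c("amino", "amino", "amino",
              "membrane", "membrane", "membrane",
              "ros", "ros", "amino"),
    mean = c(0.45, 2.1, 1.3, 1.0, 0.8, 1.1, 1.9, 0.35, 5.5),
    sd   = c(0.045, 0.21, 0.13, 0.10, 0.08, 0.11, 0.19, 0.035, 0.55),
    stringsAsFactors = FALSE
  )
}

default_nmr_shifts <- function() c(amino = 2.0, membrane = 1.5, ros = -1.5)

#' Simulate one ex vivo NMR metabolite panel
#'
#' Control mice draw every entry from its configured normal distribution.
#' Tumor-bearing cohorts add a per-group mean shift (in SD units) that grows
#' linearly with day until day 21, mimicking progressive metabolic
#' derangement.
#'
#' @param cohort_tag Cohort of the mouse.
#' @param day Measurement day (shifts saturate at day 21).
#' @param seed Integer seed or `NULL`.
#' @param panel Panel definition, see [nmr_panel_reference()].
#' @param shifts Named per-group shifts in SD units for tumor cohorts.
#' @return List with `values` (named length-9 vector), `observed`
#'   (logical length-9, all `TRUE`), and `day`.
#' @export
simulate_nmr_panel <- function(cohort_tag, day, seed = NULL,
                               panel = nmr_panel_reference(),
                               shifts = default_nmr_shifts()) {
  assert_cohort_tag(cohort_tag)
  with_seed(seed, {
    mu <- panel$mean
    if (cohort_tag != "control") {
      frac <- min(day / 21, 1)
      mu <- mu + panel$sd * unname(shifts[panel$group]) * frac
    }
    v <- stats::rnorm(nrow(panel), mu, panel$sd)
    names(v) <- panel$biomarker
    list(values = v,
         observed = stats::setNames(rep(TRUE, nrow(panel)), panel$biomarker),
         day = day)
  })
}

#' Cohort configuration
#'
#' @param n_control,n_untreated,n_treated Cohort sizes (default: the study's
#'   day-14 progression row, 17 control / 51 untreated, and 46 treated).
#' @param day_grid Scheduled measurement days post-implantation.
#' @param rt_days Radiotherapy days for the treated cohort.
#' @param dropout_mri,dropout_hpmrs Per-day probability that the anatomical
#'   MRI (and its volume measurement) or the HPMRS acquisition is missing.
#' @param nmr_entry_dropout Per-entry probability that an observed panel
#'   value is missing (to exercise imputation).
#' @param fixed_terminal_day Optional single day: every mouse is followed to
#'   (and euthanized at) this day instead of drawing per-mouse terminal days;
#'   used by benchmark cohorts with a uniform observation window.
#' @param seed Integer seed; a fixed seed reproduces the dataset exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 17L, n_untreated = 51L, n_treated = 46L,
                          day_grid = c(8L, 11L, 14L, 21L, 24L, 28L, 35L, 42L, 48L),
                          rt_days = c(25L, 27L),
                          dropout_mri = 0.25, dropout_hpmrs = 0.35,
                          nmr_entry_dropout = 0.1,
                          fixed_terminal_day = NULL,
                          seed = 1L) {
  n_control <- assert_count(n_control, "n_control")
  n_untreated <- assert_count(n_untreated, "n_untreated")
  n_treated <- assert_count(n_treated, "n_treated")
  if (is.unsorted(day_grid, strictly = TRUE)) stop("'day_grid' must be strictly increasing")
  if (dropout_mri >= 1 && dropout_hpmrs >= 1)
    stop("dropout so aggressive that no mouse could keep an MRI or HPMRS measurement")
  stopifnot(dropout_mri >= 0, dropout_hpmrs >= 0, nmr_entry_dropout >= 0,
            nmr_entry_dropout <= 1)
  structure(list(n_control = n_control, n_untreated = n_untreated,
                 n_treated = n_treated, day_grid = as.integer(day_grid),
                 rt_days = as.integer(rt_days),
                 dropout_mri = dropout_mri, dropout_hpmrs = dropout_hpmrs,
                 nmr_entry_dropout = nmr_entry_dropout,
                 fixed_terminal_day = if (!is.null(fixed_terminal_day))
                   as.integer(fixed_terminal_day),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Terminal (euthanasia/NMR) day: untreated and control mice end between day
# 14 and 35, treated mice between day 28 and 48 (post-radiotherapy window),
# weighted toward later days.
draw_terminal_day <- function(cohort_tag, day_grid) {
  lo <- if (cohort_tag == "treated") 28L else 14L
  hi <- if (cohort_tag == "treated") 48L else 35L
  cand <- day_grid[day_grid >= lo & day_grid <= hi]
  if (!length(cand)) cand <- day_grid[length(day_grid)]
  wt <- rank(cand)
  cand[sample.int(length(cand), 1L, prob = wt)]
}

# Per-mouse modality-day plan under the euthanasia + dropout rules. Returns
# observed day vectors; guarantees >= 1 MRI day or >= 1 HPMRS day.
missingness_plan <- function(cohort_tag, day_grid, dropout_mri, dropout_hpmrs,
                             fixed_terminal_day = NULL) {
  terminal <- fixed_terminal_day %||% draw_terminal_day(cohort_tag, day_grid)
  days <- day_grid[day_grid <= terminal]
  keep_mri <- days[stats::runif(length(days)) >= dropout_mri]
  keep_hp <- days[stats::runif(length(days)) >= dropout_hpmrs]
  if (!length(keep_mri) && !length(keep_hp)) {
    if (dropout_mri < 1) keep_mri <- days[sample.int(length(days), 1L)]
    else keep_hp <- days[sample.int(length(days), 1L)]
  }
  list(terminal_day = terminal, mri_days = keep_mri, hpmrs_days = keep_hp)
}

# kPL planted signal: conversion scales with current tumor burden.
kpl_for <- function(cohort_tag, volume_mm3) {
  if (cohort_tag == "control") return(0.002)
  min(0.008 + 6e-4 * volume_mm3, 0.05)
}

#' Generate a full synthetic cohort
#'
#' Draws every mouse's growth trajectory, modality-day plan, plane volumes,
#' dynamic spectra and terminal-day NMR panel from a single seeded stream.
#' With `render = FALSE` the voxel arrays and spectra are skipped (the plan
#' and volume series are kept), which is enough for label-level work and
#' keeps large-cohort tests light.
#'
#' @param config A [cohort_config()].
#' @param gm A [growth_model()].
#' @param render Render plane volumes and spectra (default `TRUE`).
#' @return List of `mouse_record` objects with attribute `config`;
#'   class `tefuse_cohort`.
#' @export
generate_cohort <- function(config = cohort_config(), gm = growth_model(),
                            render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  tags <- rep(COHORT_TAGS, times = c(config$n_control, config$n_untreated,
                                     config$n_treated))
  records <- with_seed(config$seed, lapply(seq_along(tags), function(i) {
    tag <- tags[i]
    vols <- simulate_growth(tag, gm, config$day_grid, seed = NULL,
                            rt_days = config$rt_days)
    plan <- missingness_plan(tag, config$day_grid,
                             config$dropout_mri, config$dropout_hpmrs,
                             config$fixed_terminal_day)
    day_chr <- function(d) as.character(d)
    volumes <- vols[day_chr(plan$mri_days)]
    planes <- NULL
    hpmrs <- NULL
    if (render) {
      planes <- stats::setNames(lapply(plan$mri_days, function(d)
        render_plane_volumes(vols[[day_chr(d)]], seed = NULL)), day_chr(plan$mri_days))
      hpmrs <- stats::setNames(lapply(plan$hpmrs_days, function(d) {
        em <- exchange_model(k_pl = kpl_for(tag, vols[[day_chr(d)]]))
        simulate_hpmrs(em, seed = NULL)
      }), day_chr(plan$hpmrs_days))
    }
    pan <- simulate_nmr_panel(tag, plan$terminal_day, seed = NULL)
    if (config$nmr_entry_dropout > 0) {
      drop <- stats::runif(length(pan$values)) < config$nmr_entry_dropout
      pan$observed[drop] <- FALSE
      pan$values[drop] <- NA_real_
    }
    structure(list(mouse_id = sprintf("m%03d", i), cohort = tag,
                   volumes = volumes,
                   plane_days = plan$mri_days, hpmrs_days = plan$hpmrs_days,
                   planes = planes, hpmrs = hpmrs,
                   nmr = stats::setNames(list(pan), day_chr(plan$terminal_day)),
                   terminal_day = plan$terminal_day),
              class = "mouse_record")
  }))
  structure(records, config = config, growth_model = gm,
            rendered = render, class = "tefuse_cohort")
}

#' Apply the study's missingness rules to complete records
#'
#' Assigns each mouse a terminal day, censors every measurement after it,
#' restricts NMR to the terminal day, and removes whole modality-days at the
#' configured dropout rates while preserving the guarantee that every mouse
#' keeps at least one anatomical MRI day or one HPMRS day.
#'
#' @param records A `tefuse_cohort` or plain list of `mouse_record`s with
#'   complete modality maps.
#' @param dropout_mri,dropout_hpmrs Per-day dropout probabilities (both 1 is
#'   rejected: the guarantee could not hold).
#' @param seed Integer seed or `NULL`.
#' @return Records with the missingness structure applied.
#' @export
apply_missingness <- function(records, dropout_mri = 0.25, dropout_hpmrs = 0.35,
                              seed = NULL) {
  if (dropout_mri >= 1 && dropout_hpmrs >= 1)
    stop("dropout so aggressive that no mouse could keep an MRI or HPMRS measurement")
  out <- with_seed(seed, lapply(records, function(rec) {
    day_grid <- sort(unique(c(rec$plane_days, rec$hpmrs_days,
                              as.integer(names(rec$volumes)))))
    plan <- missingness_plan(rec$cohort, day_grid, dropout_mri, dropout_hpmrs)
    keep <- function(lst, days) {
      if (is.null(lst)) return(NULL)
      lst[names(lst) %in% as.character(days)]
    }
    rec$terminal_day <- plan$terminal_day
    rec$plane_days <- intersect(plan$mri_days, rec$plane_days)
    rec$hpmrs_days <- intersect(plan$hpmrs_days, rec$hpmrs_days)
    rec$planes <- keep(rec$planes, rec$plane_days)
    rec$hpmrs <- keep(rec$hpmrs, rec$hpmrs_days)
    rec$volumes <- rec$volumes[as.integer(names(rec$volumes)) %in% rec$plane_days]
    nmr_days <- as.integer(names(rec$nmr))
    rec$nmr <- rec$nmr[nmr_days == rec$terminal_day]
    rec
  }))
  attributes(out) <- attributes(records)
  out
}

#' @export
print.tefuse_cohort <- function(x, ...) {
  tags <- vapply(x, function(r) r$cohort, character(1))
  cat(sprintf("tefuse synthetic cohort: %d mice (%s)\n", length(x),
              paste(sprintf("%s %d", names(table(tags)), table(tags)), collapse = ", ")))
  cat(sprintf("rendered voxel data: %s\n", isTRUE(attr(x, "rendered"))))
  invisible(x)
}
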