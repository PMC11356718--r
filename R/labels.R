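# Outcome-label construction: the three rules that turn raw measurements
# into binary targets (tumor progression, radiotherapy treatment effect,
# ex vivo biomarker abnormality).

#' Tumor progression label
#'
#' A tumor has progressed when its volume strictly exceeds 25 mm3.
#'
#' @param volume_mm3 Tumor volume(s) in mm3, each >= 0.
#' @return Integer vector of 0/1 labels (1 = progressed).
#' @export
progression_label <- function(volume_mm3) {
  if (any(!is.finite(volume_mm3)) || any(volume_mm3 < 0))
    stop("'volume_mm3' must be finite and >= 0")
  as.integer(volume_mm3 > 25)
}

#' Fit the untreated reference line
#'
#' Ordinary least-squares fit (Gaussian-family, identity-link GLM) of tumor
#' volume on day over untreated PDX mice in the regression window. The
#' reference lower bound at day `d` is `slope * d + intercept - residual_sd`,
#' where `residual_sd` is the sample SD of the fit residuals.
#'
#' @param days,volumes Paired observations (at least two distinct days).
#' @return An object of class `reference_line` with fields `slope`,
#'   `intercept`, `residual_sd`.
#' @export
fit_reference_line <- function(days, volumes) {
  stopifnot(length(days) == length(volumes), length(days) >= 2)
  if (length(unique(days)) < 2)
    stop("all days identical: slope undefined")
  fit <- stats::lm(volumes ~ days)
  res <- stats::residuals(fit)
  rsd <- if (length(res) > 1) stats::sd(res) else 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = rsd),
            class = "reference_line")
}

#' Reference lower bound at a day
#'
#' @param ref A [fit_reference_line()] result.
#' @param day Day(s) at which to evaluate.
#' @return Estimated average volume minus one residual SD.
#' @export
reference_lower_bound <- function(ref, day) {
  stopifnot(inherits(ref, "reference_line"))
  ref$slope * day + ref$intercept - ref$residual_sd
}

#' Treatment-effect label for one treated mouse
#'
#' Over the tumor-regression window (days 25-48 post-implantation, with day
#' 28 designated post-radiotherapy day 1): with two or more measurements,
#' therapy is effective when day and volume are negatively Pearson-correlated
#' (zero or undefined correlation counts as not effective); with exactly one
#' measurement, therapy is effective when the volume falls strictly below the
#' untreated reference lower bound at that day.
#'
#' @param days,volumes Measurements inside the regression window.
#' @param reference A [fit_reference_line()] result (required for the
#'   single-measurement rule).
#' @return Integer 0/1 (1 = effective).
#' @export
treatment_effect_label <- function(days, volumes, reference = NULL) {
  stopifnot(length(days) == length(volumes))
  if (length(days) == 0L) stop("empty series")
  if (length(days) == 1L) {
    if (is.null(reference)) stop("a reference line is required for a single measurement")
    return(as.integer(volumes < reference_lower_bound(reference, days)))
  }
  if (stats::sd(volumes) == 0 || stats::sd(days) == 0) return(0L)
  as.integer(stats::cor(days, volumes, method = "pearson") < 0)
}

#' Normal range of a biomarker
#'
#' @param biomarker Biomarker name.
#' @param mean,sd Normal mean and SD (sd >= 0), estimated from untreated
#'   non-PDX-bearing mice.
#' @return An object of class `normal_range`.
#' @export
normal_range <- function(biomarker, mean, sd) {
  if (sd < 0) stop("'sd' must be >= 0")
  structure(list(biomarker = biomarker, mean = mean, sd = sd),
            class = "normal_range")
}

#' Biomarker abnormality status
#'
#' A value is abnormal when it lies strictly outside `[mean - sd, mean + sd]`;
#' the boundary itself is normal.
#'
#' @param value Measured value(s).
#' @param range A [normal_range()].
#' @return Character vector `"normal"` / `"abnormal"`.
#' @export
biomarker_status <- function(value, range) {
  stopifnot(inherits(range, "normal_range"))
  ifelse(value < range$mean - range$sd | value > range$mean + range$sd,
         "abnormal", "normal")
}

#' Estimate per-biomarker normal ranges from the control cohort
#'
#' Pools every observed NMR panel entry of untreated non-PDX-bearing mice.
#'
#' @param cohort A `tefuse_cohort`.
#' @return Named list of [normal_range()] objects.
#' @export
estimate_normal_ranges <- function(cohort) {
  ctrl <- Filter(function(r) r$cohort == "control", cohort)
  if (!length(ctrl)) stop("no control mice in cohort")
  vals <- do.call(rbind, unlist(lapply(ctrl, function(r)
    lapply(r$nmr, function(p) { v <- p$values; v[!p$observed] <- NA_real_; v })),
    recursive = FALSE))
  out <- lapply(colnames(vals), function(b) {
    v <- vals[, b]; v <- v[is.finite(v)]
    if (!length(v)) stop(sprintf("biomarker '%s' never observed in control cohort", b))
    normal_range(b, mean(v), if (length(v) > 1) stats::sd(v) else 0)
  })
  stats::setNames(out, colnames(vals))
}

# Volumes of one record restricted to a day window.
window_volumes <- function(rec, lo, hi) {
  d <- as.integer(names(rec$volumes))
  sel <- d >= lo & d <= hi
  list(days = d[sel], volumes = unname(rec$volumes[sel]))
}

#' Construct task labels for a cohort
#'
#' * `progression`: 1 when any measured volume on day >= 21 exceeds 25 mm3
#'   (control and untreated mice; mice with no measurement from day 21 get
#'   `NA` and are excluded from the task).
#' * `treatment`: the correlation / reference-line rule over days 25-48
#'   (treated mice only); the reference line is fitted to untreated mice in
#'   the same window.
#' * `biomarker`: abnormality of the named biomarker in the terminal-day
#'   panel against control-derived normal ranges (control and untreated mice).
#'
#' @param cohort A `tefuse_cohort`.
#' @param task One of `"progression"`, `"treatment"`, `"biomarker"`.
#' @param biomarker Biomarker name (for `task = "biomarker"`).
#' @return Data frame with `mouse_id`, `cohort`, `label` (0/1 or `NA`).
#' @export
task_labels <- function(cohort, task = c("progression", "treatment", "biomarker"),
                        biomarker = NULL) {
  task <- match.arg(task)
  if (task == "progression") {
    keep <- Filter(function(r) r$cohort %in% c("control", "untreated"), cohort)
    lab <- vapply(keep, function(r) {
      if (r$cohort == "control") return(0L)
      w <- window_volumes(r, 21L, 35L)
      if (!length(w$days)) return(NA_integer_)
      max(progression_label(w$volumes))
    }, integer(1))
  } else if (task == "treatment") {
    keep <- Filter(function(r) r$cohort == "treated", cohort)
    unt <- Filter(function(r) r$cohort == "untreated", cohort)
    pts <- do.call(rbind, lapply(unt, function(r) {
      w <- window_volumes(r, 25L, 48L)
      if (length(w$days)) cbind(w$days, w$volumes)
    }))
    ref <- if (!is.null(pts) && length(unique(pts[, 1])) >= 2)
      fit_reference_line(pts[, 1], pts[, 2]) else NULL
    lab <- vapply(keep, function(r) {
      w <- window_volumes(r, 25L, 48L)
      if (!length(w$days)) return(NA_integer_)
      if (length(w$days) == 1L && is.null(ref)) return(NA_integer_)
      treatment_effect_label(w$days, w$volumes, ref)
    }, integer(1))
  } else {
    if (is.null(biomarker)) stop("'biomarker' must be named for the biomarker task")
    keep <- Filter(function(r) r$cohort %in% c("control", "untreated"), cohort)
    ranges <- estimate_normal_ranges(cohort)
    if (!biomarker %in% names(ranges)) stop(sprintf("unknown biomarker '%s'", biomarker))
    lab <- vapply(keep, function(r) {
      p <- r$nmr[[as.character(r$terminal_day)]]
      if (is.null(p) || !isTRUE(p$observed[[biomarker]])) return(NA_integer_)
      as.integer(biomarker_status(p$values[[biomarker]], ranges[[biomarker]]) == "abnormal")
    }, integer(1))
  }
  data.frame(mouse_id = vapply(keep, `[[`, character(1), "mouse_id"),
             cohort = vapply(keep, `[[`, character(1), "cohort"),
             label = lab, stringsAsFactors = FALSE)
}
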