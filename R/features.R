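# Tabular branch and end-to-end feature extraction: cohort-mean imputation
# of NMR panels with masking, tumor-volume scalar features, per-mouse
# encoding of all modalities, and assembly of the classifier input.

#' Cohort/day table of observed NMR means
#'
#' Means of observed panel entries per (cohort, day), built from observed
#' values only; the basis for cohort-mean imputation.
#'
#' @param cohort A `tefuse_cohort`.
#' @return Data frame with columns `cohort`, `day`, one column per biomarker
#'   (`NA` where nothing was observed).
#' @export
nmr_cohort_table <- function(cohort) {
  rows <- list()
  for (rec in cohort)
    for (p in rec$nmr) {
      v <- p$values; v[!p$observed] <- NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(cohort = rec$cohort, day = p$day, t(v))
    }
  if (!length(rows)) stop("cohort contains no NMR panels")
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(df[, -(1:2), drop = FALSE],
                          by = df[c("cohort", "day")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg[agg == "NaN"] <- NA
  agg
}

#' Impute a panel from same-cohort same-day means
#'
#' Missing entries are replaced by the mean of observed values from the same
#' cohort on the same day; if that mean is undefined, by the cohort's
#' nearest-day mean. Filled entries are flagged imputed (masked); observed
#' entries are never altered. A biomarker never observed anywhere in the
#' cohort is an error.
#'
#' @param values Named length-9 numeric vector (`NA` = missing).
#' @param observed Logical length-9 flags.
#' @param cohort_tag,day Cohort and day of the panel.
#' @param table A [nmr_cohort_table()].
#' @return List `values`, `observed`, `mask` (`TRUE` = imputed).
#' @export
impute_cohort_mean <- function(values, observed, cohort_tag, day, table) {
  stopifnot(length(values) == length(observed))
  mask <- !observed
  if (!any(mask)) return(list(values = values, observed = observed, mask = mask))
  sub <- table[table$cohort == cohort_tag, , drop = FALSE]
  if (!nrow(sub)) stop(sprintf("no observed panels for cohort '%s'", cohort_tag))
  for (b in names(values)[mask]) {
    col <- sub[[b]]
    ok <- is.finite(col)
    if (!any(ok))
      stop(sprintf("biomarker '%s' never observed in cohort '%s'", b, cohort_tag))
    same <- ok & sub$day == day
    values[[b]] <- if (any(same)) col[same][1] else
      col[ok][which.min(abs(sub$day[ok] - day))]
  }
  list(values = values, observed = observed, mask = mask)
}

#' Tumor-volume scalar features
#'
#' The up-to-three most recent volume measurements within the feature
#' window, oldest first, zero-padded on the right with a matching
#' availability mask.
#'
#' @param volumes Named numeric vector (names = days).
#' @param day_window Inclusive `(lo, hi)` day window.
#' @return List `values` (length 3) and `mask` (1 = present).
#' @export
volume_features <- function(volumes, day_window = c(-Inf, Inf)) {
  d <- as.numeric(names(volumes))
  sel <- which(d >= day_window[1] & d <= day_window[2])
  sel <- sel[order(d[sel])]
  sel <- utils::tail(sel, 3L)
  v <- unname(volumes[sel])
  n <- length(v)
  list(values = c(v, numeric(3L - n)),
       mask = c(rep(1, n), numeric(3L - n)))
}

# ---- per-mouse encoding ----------------------------------------------------

#' Encode every mouse's raw modalities into per-day branch vectors
#'
#' Runs the convolutional encoders once per observed plane-day and HPMRS-day
#' (the expensive step) so that downstream fold training and day-window
#' ablations can reuse the cache.
#'
#' @param cohort A rendered `tefuse_cohort`.
#' @param model A `tefuse_model`.
#' @param days Day grid to encode over (defaults to the cohort's grid).
#' @param progress Print one line per 10 mice.
#' @return List per mouse: `plane` (list of day x width matrices + `day_mask`),
#'   `hp` (matrix + `day_mask`), plus the raw record index; class
#'   `tefuse_encoding` with attribute `days`.
#' @export
encode_cohort <- function(cohort, model, days = NULL, progress = FALSE) {
  if (!isTRUE(attr(cohort, "rendered")))
    stop("cohort must be generated with render = TRUE")
  cfg <- attr(cohort, "config")
  days <- as.integer(days %||% cfg$day_grid)
  enc <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    pl <- lapply(names(plane_shapes()), function(p) NULL)
    names(pl) <- names(plane_shapes())
    day_mask <- !(days %in% rec$plane_days)
    for (p in names(pl)) {
      m <- matrix(0, length(days), model$config$plane_rnn[[p]]$input)
      for (t in seq_along(days)) {
        dch <- as.character(days[t])
        if (!day_mask[t] && !is.null(rec$planes[[dch]]))
          m[t, ] <- plane_encoder(rec$planes[[dch]][[p]], model, p)
      }
      pl[[p]] <- m
    }
    hp_mask <- !(days %in% rec$hpmrs_days)
    hp <- matrix(0, length(days), model$config$hp_rnn$input)
    for (t in seq_along(days)) {
      dch <- as.character(days[t])
      if (!hp_mask[t] && !is.null(rec$hpmrs[[dch]]))
        hp[t, ] <- hpmrs_encoder(rec$hpmrs[[dch]], model)
    }
    enc[[i]] <- list(mouse_id = rec$mouse_id, plane = pl, plane_mask = day_mask,
                     hp = hp, hp_mask = hp_mask)
    if (progress && i %% 10L == 0L)
      message(sprintf("encoded %d/%d mice", i, length(cohort)))
  }
  structure(enc, days = days, class = "tefuse_encoding")
}

# Panels matrix (days x 9) + mask for one mouse over a day grid.
mouse_nmr_matrix <- function(rec, days, table) {
  nb <- nrow(nmr_panel_reference())
  P <- matrix(0, length(days), nb)
  M <- matrix(TRUE, length(days), nb)
  for (t in seq_along(days)) {
    dch <- as.character(days[t])
    if (!is.null(rec$nmr[[dch]])) {
      pan <- rec$nmr[[dch]]
      imp <- impute_cohort_mean(pan$values, pan$observed, rec$cohort,
                                days[t], table)
      P[t, ] <- imp$values
      M[t, ] <- imp$mask
    } else {
      # whole panel missing on this day: impute from the cohort table, mask all
      blank <- stats::setNames(rep(NA_real_, nb), nmr_panel_reference()$biomarker)
      imp <- impute_cohort_mean(blank, rep(FALSE, nb), rec$cohort, days[t], table)
      P[t, ] <- imp$values
      M[t, ] <- TRUE
    }
  }
  list(panels = P, mask = M)
}

#' Assemble classifier input features for every mouse
#'
#' Forward pass from the cached per-day encodings through the plane
#' recurrences, the three time-elapsed attention blocks, the HPMRS and NMR
#' recurrences and the volume features, restricted to `feature_days`.
#' Excluded modalities contribute zero vectors (the ablation mechanism).
#'
#' @param cohort A rendered `tefuse_cohort`.
#' @param model A `tefuse_model`.
#' @param encoding An [encode_cohort()] cache.
#' @param feature_days Days whose measurements the model may use.
#' @param modalities Subset of `c("mri", "hpmrs", "nmr", "volume")`.
#' @param table Optional precomputed [nmr_cohort_table()] (defaults to the
#'   table of `cohort`).
#' @return Matrix `n_mice x (fused + hp + 9 + 3)` with `rownames` = mouse ids
#'   and attribute `blocks` giving the column split.
#' @export
model_features <- function(cohort, model, encoding, feature_days,
                           modalities = c("mri", "hpmrs", "nmr", "volume"),
                           table = NULL) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  days <- attr(encoding, "days")
  sel <- match(as.integer(feature_days), days)
  if (anyNA(sel)) stop("feature_days must be a subset of the encoded day grid")
  cfg <- model$config
  table <- table %||% nmr_cohort_table(cohort)
  n <- length(cohort)
  X <- matrix(0, n, cfg$fused_width + cfg$hp_rnn$hidden + 9L + 3L)
  rownames(X) <- vapply(cohort, `[[`, character(1), "mouse_id")
  for (i in seq_len(n)) {
    rec <- cohort[[i]]
    e <- encoding[[i]]
    fused <- numeric(cfg$fused_width)
    if ("mri" %in% modalities) {
      mats <- lapply(names(plane_shapes()), function(p)
        temporal_aggregate(e$plane[[p]][sel, , drop = FALSE], model, p,
                           day_mask = e$plane_mask[sel]))
      names(mats) <- names(plane_shapes())
      blocks <- lapply(1:3, function(b) time_elapsed_block(mats, model, b))
      fused <- fuse_views(blocks)
    }
    hp <- numeric(cfg$hp_rnn$hidden)
    if ("hpmrs" %in% modalities && any(!e$hp_mask[sel]))
      hp <- hp_temporal(e$hp[sel, , drop = FALSE], model,
                        day_mask = e$hp_mask[sel])
    nmr <- numeric(9L)
    if ("nmr" %in% modalities) {
      nm <- mouse_nmr_matrix(rec, days[sel], table)
      nmr <- nmr_temporal(nm$panels, model, entry_mask = nm$mask)
    }
    vol <- numeric(3L)
    if ("volume" %in% modalities)
      vol <- volume_features(rec$volumes,
                             c(-Inf, max(as.numeric(feature_days))))$values
    X[i, ] <- c(fused, hp, nmr, vol)
  }
  attr(X, "blocks") <- c(fused = cfg$fused_width, hp = cfg$hp_rnn$hidden,
                         nmr = 9L, vol = 3L)
  X
}

#' End-to-end prediction for one mouse
#'
#' Full forward pass from raw record to positive-class probability with the
#' given head (the model's initialized head by default). Used by the masking
#' contract: perturbing any imputed-and-masked value leaves the returned
#' probability bit-identical.
#'
#' @param model A `tefuse_model`.
#' @param cohort A rendered `tefuse_cohort` containing the mouse.
#' @param mouse_id Mouse identifier.
#' @param feature_days Day window for features.
#' @param modalities Modalities available to the model.
#' @param head Optional trained head (defaults to the initialized one).
#' @return Positive-class probability.
#' @export
model_predict <- function(model, cohort, mouse_id, feature_days,
                          modalities = c("mri", "hpmrs", "nmr", "volume"),
                          head = NULL) {
  idx <- which(vapply(cohort, `[[`, character(1), "mouse_id") == mouse_id)
  if (!length(idx)) stop(sprintf("unknown mouse '%s'", mouse_id))
  sub <- structure(cohort[idx], class = "tefuse_cohort",
                   config = attr(cohort, "config"), rendered = TRUE)
  enc <- encode_cohort(sub, model, days = feature_days)
  X <- model_features(sub, model, enc, feature_days, modalities,
                      table = nmr_cohort_table(cohort))
  b <- attr(X, "blocks")
  cuts <- cumsum(b)
  f <- X[1, seq_len(cuts[1])]
  hp <- X[1, (cuts[1] + 1):cuts[2]]
  nmr <- X[1, (cuts[2] + 1):cuts[3]]
  vol <- X[1, (cuts[3] + 1):cuts[4]]
  unname(fuse_and_classify(f, hp, nmr, vol, head %||% model$weights$head,
                           model$config)["positive"])
}
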