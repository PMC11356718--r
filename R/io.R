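# Dataset disk layout: one directory per mouse with plane volumes as NIfTI,
# dynamic spectra as plain CSV matrices, volumes and NMR panels in one tidy
# CSV per cohort, and a JSON manifest.

#' Write a cohort to disk
#'
#' Layout: `<dir>/manifest.json` (cohort tags, terminal days, day plans),
#' `<dir>/tabular.csv` (long table: mouse_id, cohort, day, field, value,
#' observed_flag for volumes and NMR entries), and per mouse
#' `<dir>/<id>/<plane>_d<day>.nii.gz` plus `<dir>/<id>/hpmrs_d<day>.csv`.
#'
#' @param cohort A `tefuse_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort, function(r)
    list(mouse_id = r$mouse_id, cohort = r$cohort,
         terminal_day = r$terminal_day,
         plane_days = as.integer(r$plane_days),
         hpmrs_days = as.integer(r$hpmrs_days)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  rows <- list()
  for (r in cohort) {
    for (d in names(r$volumes))
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = r$mouse_id, cohort = r$cohort, day = as.integer(d),
        field = "volume_mm3", value = unname(r$volumes[[d]]), observed_flag = 1L)
    for (d in names(r$nmr)) {
      p <- r$nmr[[d]]
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = r$mouse_id, cohort = r$cohort, day = as.integer(d),
        field = names(p$values), value = unname(p$values),
        observed_flag = as.integer(p$observed))
    }
    mdir <- file.path(dir, r$mouse_id)
    if (length(r$planes) || length(r$hpmrs))
      dir.create(mdir, showWarnings = FALSE)
    for (d in names(r$planes))
      for (pl in names(r$planes[[d]]))
        RNifti::writeNifti(r$planes[[d]][[pl]],
                           file.path(mdir, sprintf("%s_d%s.nii.gz", pl, d)))
    for (d in names(r$hpmrs))
      utils::write.csv(r$hpmrs[[d]],
                       file.path(mdir, sprintf("hpmrs_d%s.csv", d)),
                       row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "tabular.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Dataset directory.
#' @return A `tefuse_cohort` (rendered if voxel files are present). Values
#'   round-trip within float32 write precision for NIfTI volumes and exactly
#'   for CSV fields.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  tab <- utils::read.csv(file.path(dir, "tabular.csv"), stringsAsFactors = FALSE)
  panel_names <- nmr_panel_reference()$biomarker
  records <- lapply(manifest, function(m) {
    mt <- tab[tab$mouse_id == m$mouse_id, , drop = FALSE]
    vt <- mt[mt$field == "volume_mm3", , drop = FALSE]
    volumes <- stats::setNames(vt$value, vt$day)
    nmr <- list()
    nt <- mt[mt$field %in% panel_names, , drop = FALSE]
    for (d in unique(nt$day)) {
      sd_ <- nt[nt$day == d, , drop = FALSE]
      idx <- match(panel_names, sd_$field)
      nmr[[as.character(d)]] <- list(
        values = stats::setNames(sd_$value[idx], panel_names),
        observed = stats::setNames(sd_$observed_flag[idx] == 1L, panel_names),
        day = d)
    }
    mdir <- file.path(dir, m$mouse_id)
    planes <- NULL; hpmrs <- NULL
    if (dir.exists(mdir)) {
      planes <- stats::setNames(lapply(m$plane_days, function(d)
        stats::setNames(lapply(names(plane_shapes()), function(pl) {
          arr <- RNifti::readNifti(file.path(mdir, sprintf("%s_d%d.nii.gz", pl, d)))
          array(as.numeric(arr), dim(arr))
        }), names(plane_shapes()))), as.character(m$plane_days))
      hpmrs <- stats::setNames(lapply(m$hpmrs_days, function(d)
        as.matrix(utils::read.csv(file.path(mdir, sprintf("hpmrs_d%d.csv", d)),
                                  check.names = FALSE))), as.character(m$hpmrs_days))
      hpmrs <- lapply(hpmrs, function(h) { dimnames(h) <- NULL; h })
    }
    structure(list(mouse_id = m$mouse_id, cohort = m$cohort, volumes = volumes,
                   plane_days = as.integer(m$plane_days),
                   hpmrs_days = as.integer(m$hpmrs_days),
                   planes = planes, hpmrs = hpmrs, nmr = nmr,
                   terminal_day = m$terminal_day),
              class = "mouse_record")
  })
  structure(records, rendered = any(dir.exists(file.path(dir,
              vapply(manifest, `[[`, character(1), "mouse_id")))),
            class = "tefuse_cohort")
}
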