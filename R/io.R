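# NIfTI + YAML bundle I/O and measurement-table CSV I/O.
# A dataset bundle is a directory with vx.nii / vy.nii / vz.nii (4-D volumes,
# one per velocity component, m/s), mask.nii (3-D), and meta.yaml carrying
# spacing, timing, VENC, the wrapped flag and the provenance log — the
# sidecar is authoritative for all metadata.

#' Write a velocity field + mask bundle
#'
#' @param field A [velocity_field()].
#' @param mask A [la_mask()] (or `NULL` to omit).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flow_bundle <- function(field, mask, dir) {
  stopifnot(inherits(field, "velocity_field"))
  if (!is.null(mask)) check_mask_field(field, mask)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- field$grid
  comp_names <- c("vx", "vy", "vz")
  for (c_ in 1:3) {
    RNifti::writeNifti(
      RNifti::asNifti(field$data[, , , , c_],
                      pixdim = c(grid$spacing_mm, grid$frame_duration_s),
                      datatype = "double"),
      file.path(dir, paste0(comp_names[c_], ".nii")))
  }
  if (!is.null(mask)) {
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)),
                      pixdim = grid$spacing_mm, datatype = "uint8"),
      file.path(dir, "mask.nii"))
  }
  meta <- list(spacing_mm = as.numeric(grid$spacing_mm),
               n_frames = grid$n_frames,
               frame_duration_s = grid$frame_duration_s,
               mv_open_frame = grid$mv_open_frame,
               venc_m_s = field$venc_m_s,
               wrapped = field$wrapped,
               log = as.list(field$log))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a velocity field + mask bundle
#'
#' Reconstructs the [velocity_field()] (and [la_mask()] when present) from a
#' bundle directory; metadata comes from the YAML sidecar. Inconsistent
#' component shapes are rejected with a three-way shape report, and a
#' `wrapped` flag without a VENC is an error.
#'
#' @param dir Bundle directory written by [write_flow_bundle()].
#' @return List with `field` and `mask` (`NULL` when no mask file exists).
#' @export
read_flow_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) {
    stop("bundle sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  for (fld in c("spacing_mm", "n_frames", "frame_duration_s",
                "mv_open_frame")) {
    if (is.null(meta[[fld]])) {
      stop("sidecar meta.yaml is missing required field `", fld, "`",
           call. = FALSE)
    }
  }
  comp_names <- c("vx", "vy", "vz")
  paths <- file.path(dir, paste0(comp_names, ".nii"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing velocity component file(s): ",
         paste(comp_names[missing], collapse = ", "), call. = FALSE)
  }
  arrs <- lapply(paths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim(a))
  })
  shapes <- vapply(arrs, function(a) paste(dim(a), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) {
    stop("velocity component shapes disagree: vx ", shapes[1], ", vy ",
         shapes[2], ", vz ", shapes[3], call. = FALSE)
  }
  d <- dim(arrs[[1]])
  if (length(d) != 4) {
    stop("component volumes must be 4-D (x, y, z, frame); got ", shapes[1],
         call. = FALSE)
  }
  grid <- grid_spec(d[1:3], meta$spacing_mm, meta$n_frames,
                    meta$frame_duration_s, meta$mv_open_frame)
  if (d[4] != grid$n_frames) {
    stop("sidecar n_frames (", grid$n_frames, ") does not match volume (",
         d[4], " frames)", call. = FALSE)
  }
  wrapped <- isTRUE(meta$wrapped)
  if (wrapped && is.null(meta$venc_m_s)) {
    stop("sidecar flags the data as wrapped but carries no venc_m_s",
         call. = FALSE)
  }
  data <- array(0, c(d, 3L))
  for (c_ in 1:3) data[, , , , c_] <- arrs[[c_]]
  field <- velocity_field(data, grid, venc_m_s = meta$venc_m_s,
                          wrapped = wrapped,
                          log = unlist(meta$log %||% character()))
  mask <- NULL
  mask_path <- file.path(dir, "mask.nii")
  if (file.exists(mask_path)) {
    marr <- RNifti::readNifti(mask_path)
    mask <- la_mask(array(as.numeric(marr) != 0, dim(marr)),
                    grid$spacing_mm)
  }
  list(field = field, mask = mask)
}

#' Measurement-table CSV I/O
#'
#' Reads / writes the long-format repeated-measures table with the schema
#' `subject_id, group, session, observer, biomarker, value, hr_bpm,
#' sbp_mmHg`.
#'
#' @param table A `measurement_table` tibble.
#' @param path CSV path.
#' @return The path / the tibble.
#' @export
write_measurement_table <- function(table, path) {
  need <- c("subject_id", "group", "session", "observer", "biomarker",
            "value", "hr_bpm", "sbp_mmHg")
  stopifnot(all(need %in% names(table)))
  readr::write_csv(tibble::as_tibble(table)[need], path)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    session = readr::col_character(),
    observer = readr::col_character(),
    biomarker = readr::col_character(),
    value = readr::col_double(),
    hr_bpm = readr::col_double(),
    sbp_mmHg = readr::col_double()))
  class(tab) <- c("measurement_table", class(tab))
  tab
}

#' Export pathlines as CSV
#'
#' Writes `pathline_id, release_frame, t_s, x_mm, y_mm, z_mm, terminated`
#' suitable for external visualisation tools.
#'
#' @param pl A `pathline_set`.
#' @param path CSV path.
#' @export
write_pathlines_csv <- function(pl, path) {
  terms <- attr(pl, "terminations")
  out <- dplyr::left_join(tibble::as_tibble(pl),
                          dplyr::select(terms, "pathline_id",
                                        terminated = "reason"),
                          by = "pathline_id")
  readr::write_csv(out, path)
  invisible(path)
}
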