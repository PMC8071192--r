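#' Write / read a cohort table
#'
#' CSV round trip at full double precision.
#'
#' @param cohort Cohort tibble.
#' @param path CSV path.
#' @return `read_cohort()` returns the tibble; `write_cohort()` the path,
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  expected <- c("subject_id", "tumor_type", "solid_stress",
                "interstitial_fluid_pressure", "volume", "collagen_fraction",
                "cellularity", "basal_elasticity", "basal_viscosity",
                "stiffening_slope")
  out <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(expected, names(out))
  if (length(missing) > 0) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out$tumor_type <- factor(out$tumor_type, levels = c("HCC", "CCA"))
  out
}

nifti_with_geometry <- function(arr, geometry) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$voxel_size / 1000 # um -> mm
  img
}

#' Write / read a wrapped-phase acquisition as NIfTI volumes
#'
#' One gzipped NIfTI file per encoding direction and offset
#' (`phase_dir<d>_off<o>.nii.gz`) with the voxel size in the header, plus a
#' JSON sidecar (`geometry.json`) carrying the acquisition geometry, the
#' tissue support mask and the noise level.
#'
#' @param acq A `cmre_acquisition`.
#' @param dir Output directory (created if needed).
#' @return `read_acquisition()` returns a `cmre_acquisition` (without the
#'   simulator ground truth); `write_acquisition()` the directory, invisibly.
#' @export
write_acquisition <- function(acq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- acq$geometry
  for (dd in 1:3) {
    for (j in seq_len(g$n_offsets)) {
      RNifti::writeNifti(
        nifti_with_geometry(acq$wrapped_phase[, , , j, dd], g),
        file.path(dir, sprintf("phase_dir%d_off%d.nii.gz", dd, j))
      )
    }
  }
  sidecar <- list(
    matrix_rows = g$matrix_rows, matrix_cols = g$matrix_cols,
    n_slices = g$n_slices, voxel_size = g$voxel_size,
    vibration_frequency = g$vibration_frequency, n_offsets = g$n_offsets,
    encoding_directions = g$encoding_directions,
    encoding_efficiency = g$encoding_efficiency,
    noise_sd = acq$noise_sd,
    support = which(acq$support)
  )
  jsonlite::write_json(sidecar, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_acquisition
#' @export
read_acquisition <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  g <- acquisition_geometry(
    matrix_rows = side$matrix_rows, matrix_cols = side$matrix_cols,
    n_slices = side$n_slices, voxel_size = side$voxel_size,
    vibration_frequency = side$vibration_frequency,
    n_offsets = side$n_offsets,
    encoding_directions = matrix(unlist(side$encoding_directions), 3, 3),
    encoding_efficiency = side$encoding_efficiency
  )
  d <- grid_dim(g)
  ph <- array(NA_real_, dim = c(d, g$n_offsets, 3))
  for (dd in 1:3) {
    for (j in seq_len(g$n_offsets)) {
      f <- file.path(dir, sprintf("phase_dir%d_off%d.nii.gz", dd, j))
      if (!file.exists(f)) stop("missing acquisition volume: ", f)
      ph[, , , j, dd] <- as.array(RNifti::readNifti(f))
    }
  }
  support <- array(FALSE, dim = d)
  support[side$support] <- TRUE
  structure(
    list(geometry = g, wrapped_phase = ph, support = support,
         noise_sd = side$noise_sd),
    class = "cmre_acquisition"
  )
}

#' Write an elastogram as NIfTI parametric maps
#'
#' Writes `storage_kpa.nii.gz`, `loss_kpa.nii.gz` and `validity.nii.gz`
#' with the voxel size in the header.
#'
#' @param maps A `cmre_elastogram`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_elastogram <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- maps$geometry
  RNifti::writeNifti(nifti_with_geometry(maps$storage_modulus, g),
                     file.path(dir, "storage_kpa.nii.gz"))
  RNifti::writeNifti(nifti_with_geometry(maps$loss_modulus, g),
                     file.path(dir, "loss_kpa.nii.gz"))
  RNifti::writeNifti(nifti_with_geometry(maps$validity_mask * 1, g),
                     file.path(dir, "validity.nii.gz"))
  invisible(dir)
}

#' Write / read a histology tile
#'
#' TIFF image plus a JSON sidecar carrying the pixel size (um) and stain.
#'
#' @param slide A `cmre_slide`.
#' @param path TIFF path (sidecar gets extension `.json`).
#' @return `read_slide()` returns a `cmre_slide` (without ground-truth
#'   fields); `write_slide()` the path, invisibly.
#' @export
write_slide <- function(slide, path) {
  tiff::writeTIFF(slide$pixels, path, bits.per.sample = 16L)
  meta <- list(pixel_size = slide$pixel_size, stain = slide$stain)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing slide sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(
    list(pixels = tiff::readTIFF(path), pixel_size = meta$pixel_size,
         stain = meta$stain),
    class = "cmre_slide"
  )
}

#' Read a report back from JSON
#'
#' Inverse of [report_json()] for the tabular parts of the report (cohort
#' measurements are persisted separately as CSV).
#'
#' @param path JSON path.
#' @return A list mirroring the JSON structure, with tibbles for the tables.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("group_summaries", "partial_correlations", "repeatability",
               "sample_size")) {
    x[[nm]] <- tibble::as_tibble(x[[nm]])
  }
  x$roc_results <- lapply(x$roc_results, tibble::as_tibble)
  x
}
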