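#' Acquisition geometry for an MRE scan
#'
#' Describes the spin-echo MRE acquisition grid and motion encoding: an
#' 87 x 67 in-plane matrix over 9 slices at 300 x 300 x 350 um resolution,
#' a 600 Hz mechanical vibration sampled at 4 phase offsets over one period,
#' and three orthogonal motion-encoding directions. The angular frequency
#' `omega = 2 * pi * vibration_frequency` is always derived, never stored.
#'
#' @param matrix_rows,matrix_cols,n_slices Grid dimensions (positive counts).
#' @param voxel_size Numeric length-3, voxel edge lengths in micrometres
#'   (row, column, slice).
#' @param vibration_frequency Mechanical excitation frequency in Hz.
#' @param n_offsets Number of phase offsets sampled over one vibration period.
#' @param encoding_directions 3 x 3 matrix whose rows are mutually orthogonal
#'   unit vectors (motion-encoding directions). Defaults to the coordinate axes.
#' @param encoding_efficiency Phase accumulated per unit displacement,
#'   rad/um.
#'
#' @return An object of class `cmre_geometry`.
#' @export
#' @examples
#' geom <- acquisition_geometry()
#' omega(geom) / (2 * pi) # 600 Hz
acquisition_geometry <- function(matrix_rows = 87L, matrix_cols = 67L,
                                 n_slices = 9L,
                                 voxel_size = c(300, 300, 350),
                                 vibration_frequency = 600,
                                 n_offsets = 4L,
                                 encoding_directions = diag(3),
                                 encoding_efficiency = 1) {
  counts <- c(matrix_rows, matrix_cols, n_slices, n_offsets)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("matrix dimensions, slice and offset counts must be positive integers")
  }
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths (um)")
  }
  if (vibration_frequency <= 0) stop("vibration_frequency must be positive")
  if (encoding_efficiency <= 0) stop("encoding_efficiency must be positive")
  ed <- as.matrix(encoding_directions)
  if (!all(dim(ed) == c(3, 3)) ||
      max(abs(crossprod(t(ed)) - diag(3))) > 1e-8) {
    stop("encoding_directions must be 3 mutually orthogonal unit row vectors")
  }
  structure(
    list(
      matrix_rows = as.integer(matrix_rows),
      matrix_cols = as.integer(matrix_cols),
      n_slices = as.integer(n_slices),
      voxel_size = as.numeric(voxel_size),
      vibration_frequency = vibration_frequency,
      n_offsets = as.integer(n_offsets),
      encoding_directions = ed,
      encoding_efficiency = encoding_efficiency
    ),
    class = "cmre_geometry"
  )
}

#' Angular frequency of the mechanical excitation
#'
#' @param geometry A [acquisition_geometry()] object.
#' @return `2 * pi * vibration_frequency`, rad/s.
#' @export
omega <- function(geometry) 2 * pi * geometry$vibration_frequency

#' @export
print.cmre_geometry <- function(x, ...) {
  cat(sprintf(
    "MRE acquisition geometry: %d x %d x %d voxels (%g x %g x %g um), %g Hz, %d offsets\n",
    x$matrix_rows, x$matrix_cols, x$n_slices,
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$vibration_frequency, x$n_offsets
  ))
  invisible(x)
}

grid_dim <- function(geometry) {
  c(geometry$matrix_rows, geometry$matrix_cols, geometry$n_slices)
}
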