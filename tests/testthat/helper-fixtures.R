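# Shared fixtures: small geometries, analytic plane-wave curls, tiny configs.

small_geometry <- function(rows = 40, cols = 40, slices = 9) {
  acquisition_geometry(matrix_rows = rows, matrix_cols = cols,
                       n_slices = slices)
}

# Analytic curl of a transverse plane wave: a complex vector field
# p * exp(-i k d . r) satisfying the Helmholtz equation with k^2 = rho w^2/G*.
# Returns a cmre_curl ready for helmholtz_invert().
plane_wave_curl <- function(g_star_kpa, geometry = small_geometry(),
                            azimuth = 20, tilt = 6, density = 1000) {
  k <- shear_wavenumber(g_star_kpa, density, geometry$vibration_frequency)
  az <- azimuth * pi / 180
  ti <- tilt * pi / 180
  dir <- c(cos(az) * cos(ti), sin(az) * cos(ti), sin(ti))
  h <- geometry$voxel_size * 1e-6
  d <- c(geometry$matrix_rows, geometry$matrix_cols, geometry$n_slices)
  xr <- (seq_len(d[1]) - (d[1] + 1) / 2) * h[1]
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * h[2]
  zs <- (seq_len(d[3]) - (d[3] + 1) / 2) * h[3]
  field <- outer(outer(exp(-1i * k * dir[1] * xr),
                       exp(-1i * k * dir[2] * yc)),
                 exp(-1i * k * dir[3] * zs))
  pol <- c(-sin(az), cos(az), 0) # transverse
  q <- array(0i, dim = c(d, 3))
  # curl of p*exp(-i k d.r) is (-i k) (d x p) exp(-i k d.r)
  dxp <- c(dir[2] * pol[3] - dir[3] * pol[2],
           dir[3] * pol[1] - dir[1] * pol[3],
           dir[1] * pol[2] - dir[2] * pol[1])
  for (comp in 1:3) q[, , , comp] <- -1i * k * dxp[comp] * field
  structure(list(values = q, validity_mask = array(TRUE, dim = d),
                 geometry = geometry),
            class = "cmre_curl")
}

# interior ROI means: exclude the border rings (where masked smoothing and
# the fallback stencil operate), as a drawn ROI would
roi_means_of <- function(maps, margin = 4) {
  d <- dim(maps$validity_mask)
  roi <- array(FALSE, dim = d)
  roi[(margin + 1):(d[1] - margin), (margin + 1):(d[2] - margin), ] <- TRUE
  st <- roi_statistics(maps, roi)
  c(storage = st$mean_storage, loss = st$mean_loss)
}

tiny_config_yaml <- function() {
  f <- tempfile(fileext = ".yaml")
  writeLines(
    "cohort:
  n_hcc: 3
  n_cca: 2
  compression_levels: [0.0, 2.0]
mre:
  n_repeatability: 2
histology:
  collagen_tile_px: 160
  nucleus_field_area: 0.16
", f)
  f
}

demo_subject <- function(elasticity = 1.6, viscosity = 1.1, slope = 0.6) {
  list(basal_elasticity = elasticity, basal_viscosity = viscosity,
       stiffening_slope = slope)
}
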