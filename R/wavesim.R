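#' Complex shear wavenumber from the dispersion relation
#'
#' For a viscoelastic medium with complex shear modulus `G* = G' + i G''`
#' (kPa) and density `rho` (kg/m^3), a time-harmonic shear wave obeys
#' `k = omega * sqrt(rho / G*)` (principal branch), so that the spatial
#' factor `exp(-i k d . r)` propagates along `d` with decay.
#'
#' @param g_star Complex shear modulus in kPa.
#' @param density Density in kg/m^3 (soft-tissue convention 1000).
#' @param frequency Vibration frequency in Hz.
#' @return Complex wavenumber in 1/m (negative imaginary part).
#' @export
shear_wavenumber <- function(g_star, density = 1000, frequency = 600) {
  if (Re(g_star) <= 0) stop("storage modulus must be positive")
  2 * pi * frequency * sqrt(density / (as.complex(g_star) * 1000))
}

#' Default plane-wave set for the acquisition simulator
#'
#' Three transverse plane waves from fixed azimuths with a mild amplitude
#' taper and small out-of-plane tilts, with polarization angles mixing the
#' quasi-through-plane and in-plane transverse directions so that all three
#' curl components carry signal.
#'
#' @return A tibble with columns `azimuth`, `tilt` (degrees),
#'   `rel_amplitude`, `pol_angle` (degrees) and `longitudinal` (logical;
#'   `TRUE` turns the wave into a compressional, curl-free wave for testing
#'   compressional-wave rejection).
#' @export
default_waves <- function() {
  tibble::tibble(
    azimuth = c(15, 135, 255),
    tilt = c(8, -8, 8),
    rel_amplitude = c(1, 0.8, 0.65),
    pol_angle = c(0, 60, 120),
    longitudinal = FALSE
  )
}

wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi

# in-plane disk support mask (rows x cols x slices)
support_mask <- function(geometry, radius_vox) {
  d <- grid_dim(geometry)
  rc <- (d[1] + 1) / 2
  cc <- (d[2] + 1) / 2
  disk <- outer(seq_len(d[1]), seq_len(d[2]),
                function(r, c) (r - rc)^2 + (c - cc)^2 <= radius_vox^2)
  array(disk, dim = d)
}

#' Simulate a wrapped-phase MRE acquisition
#'
#' Forward model for one scan of one subject at one applied compression.
#' The true complex modulus is `G'(sigma) = basal_elasticity +
#' stiffening_slope * sigma` (the loss modulus is held at its basal value),
#' optionally jittered by a per-session factor. The displacement field is a
#' superposition of transverse plane waves with the dispersion-relation
#' wavenumber, restricted to a finite tumor disk centred in the field of
#' view; outside the tumor the phase is pure background noise. Motion
#' encoding projects the displacement on each encoding direction and samples
#' `n_offsets` phase offsets over one vibration period; wave amplitudes are
#' normalized so the steepest phase gradient stays safely below pi per voxel
#' (emulating per-scan encoding adjustment), Gaussian phase noise is added,
#' and phases are wrapped to `[-pi, pi)`.
#'
#' @param subject One-row data frame (or list) with `basal_elasticity`,
#'   `basal_viscosity` (kPa) and `stiffening_slope`.
#' @param compression Applied compression in kPa (>= 0).
#' @param geometry An [acquisition_geometry()].
#' @param seed Optional integer seed for the noise.
#' @param noise_sd Gaussian phase noise SD per sample, rad.
#' @param waves Wave table as in [default_waves()].
#' @param support_radius Tumor disk radius in voxels.
#' @param session_factor Length-2 multiplicative jitter applied to (G', G'').
#' @param density Density, kg/m^3.
#' @param grad_target Target maximum phase gradient per voxel, rad.
#' @return A `cmre_acquisition`: wrapped phase array
#'   `[row, col, slice, offset, direction]`, geometry, support mask, and the
#'   simulated modulus (`g_star_true`) retained for testing.
#' @export
simulate_wave_acquisition <- function(subject, compression = 0,
                                      geometry = acquisition_geometry(),
                                      seed = NULL,
                                      noise_sd = 0.03,
                                      waves = default_waves(),
                                      support_radius = 8,
                                      session_factor = c(1, 1),
                                      density = 1000,
                                      grad_target = 2.4) {
  if (compression < 0) stop("compression must be >= 0 kPa")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  gp <- (subject$basal_elasticity + subject$stiffening_slope * compression) *
    session_factor[1]
  gpp <- subject$basal_viscosity * session_factor[2]
  if (!is.finite(gp) || gp <= 0) {
    stop("non-positive storage modulus at compression ", compression, " kPa")
  }
  if (gpp < 0) stop("loss modulus must be >= 0")
  g_star <- complex(real = gp, imaginary = gpp)
  k <- shear_wavenumber(g_star, density, geometry$vibration_frequency)
  h_m <- geometry$voxel_size * 1e-6
  lambda_vox <- 2 * pi / Re(k) / min(h_m)
  if (lambda_vox < 4) {
    warning("shear wavelength below 4 voxels; inversion unreliable")
  }
  if (!is.null(seed)) set.seed(seed)

  d <- grid_dim(geometry)
  # voxel-centre coordinates (m), origin at grid centre
  xr <- (seq_len(d[1]) - (d[1] + 1) / 2) * h_m[1]
  yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * h_m[2]
  zs <- (seq_len(d[3]) - (d[3] + 1) / 2) * h_m[3]

  U <- array(0i, dim = c(d, 3))
  for (w in seq_len(nrow(waves))) {
    az <- waves$azimuth[w] * pi / 180
    ti <- waves$tilt[w] * pi / 180
    dir <- c(cos(az) * cos(ti), sin(az) * cos(ti), sin(ti))
    p_in <- c(-sin(az), cos(az), 0)                  # in-plane transverse
    p_tp <- c(dir[2] * p_in[3] - dir[3] * p_in[2],   # dir x p_in
              dir[3] * p_in[1] - dir[1] * p_in[3],
              dir[1] * p_in[2] - dir[2] * p_in[1])
    psi <- waves$pol_angle[w] * pi / 180
    pol <- if (isTRUE(waves$longitudinal[w])) dir else {
      cos(psi) * p_tp + sin(psi) * p_in
    }
    er <- exp(-1i * k * dir[1] * xr)
    ec <- exp(-1i * k * dir[2] * yc)
    es <- exp(-1i * k * dir[3] * zs)
    wavefield <- outer(outer(er, ec), es) * waves$rel_amplitude[w]
    for (comp in 1:3) {
      U[, , , comp] <- U[, , , comp] + pol[comp] * wavefield
    }
  }

  support <- support_mask(geometry, support_radius)
  # project on encoding directions
  E <- geometry$encoding_directions
  M <- array(0i, dim = c(d, 3))
  for (dd in 1:3) {
    M[, , , dd] <- E[dd, 1] * U[, , , 1] + E[dd, 2] * U[, , , 2] +
      E[dd, 3] * U[, , , 3]
  }
  # amplitude normalization: steepest phase gradient below grad_target
  xi <- geometry$encoding_efficiency               # rad/um
  umax <- 0
  for (dd in 1:3) umax <- max(umax, max(abs(M[, , , dd])[support]))
  steep <- (abs(Re(k)) + abs(Im(k))) * max(h_m)    # rad change per voxel
  amp <- grad_target / (xi * 1e6 * umax * steep)   # displacement scale, um
  M <- M * amp * 1e6                               # now in um

  nof <- geometry$n_offsets
  ph <- array(NA_real_, dim = c(d, nof, 3))
  n_bg <- sum(!support)
  for (dd in 1:3) {
    for (j in seq_len(nof)) {
      f <- xi * Re(M[, , , dd] * exp(2i * pi * (j - 1) / nof))
      if (noise_sd > 0) f <- f + array(rnorm(prod(d), 0, noise_sd), dim = d)
      f[!support] <- runif(n_bg, -pi, pi)
      ph[, , , j, dd] <- wrap_phase(f)
    }
  }
  structure(
    list(
      geometry = geometry,
      wrapped_phase = ph,
      support = support,
      noise_sd = noise_sd,
      g_star_true = g_star,
      wavenumber = k,
      displacement_true = M,
      compression = compression
    ),
    class = "cmre_acquisition"
  )
}

#' @export
print.cmre_acquisition <- function(x, ...) {
  cat(sprintf(
    "MRE acquisition: %s voxels, %d offsets x 3 directions, noise SD %.3g rad\n",
    paste(grid_dim(x$geometry), collapse = " x "),
    x$geometry$n_offsets, x$noise_sd
  ))
  invisible(x)
}
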