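# ---- small array helpers ----------------------------------------------------

# shift a 3-D array by n voxels along an axis, filling vacated entries
shift3 <- function(a, n, axis, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  if (abs(n) >= d[axis]) return(out)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (n > 0) {
    dst[[axis]] <- (n + 1):d[axis]
    src[[axis]] <- 1:(d[axis] - n)
  } else if (n < 0) {
    dst[[axis]] <- 1:(d[axis] + n)
    src[[axis]] <- (1 - n):d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# masked separable convolution along one axis (zero-padded, renormalized)
conv_axis_masked <- function(num, den, kernel, axis) {
  r <- (length(kernel) - 1) / 2
  n2 <- array(0, dim = dim(num))
  d2 <- array(0, dim = dim(den))
  storage.mode(n2) <- storage.mode(num)
  for (i in seq_along(kernel)) {
    s <- i - r - 1
    n2 <- n2 + kernel[i] * shift3(num, s, axis)
    d2 <- d2 + kernel[i] * shift3(den, s, axis)
  }
  list(num = n2, den = d2)
}

# 3-D Gaussian smoothing of a (complex) field restricted to a mask
smooth_masked <- function(a, mask, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  num <- a
  num[!mask] <- 0
  den <- array(as.numeric(mask), dim = dim(mask))
  for (ax in 1:3) {
    res <- conv_axis_masked(num, den, kern, ax)
    num <- res$num
    den <- res$den
  }
  out <- array(NA_complex_, dim = dim(a))
  ok <- den > 1e-12
  out[ok] <- num[ok] / den[ok]
  out[!mask] <- NA
  out
}

# second central difference along one axis (spacing h), NA at borders
second_diff <- function(a, axis, h) {
  (shift3(a, 1, axis, fill = NA) - 2 * a + shift3(a, -1, axis, fill = NA)) / h^2
}

erode_shifts <- function(mask, reach, axis) {
  out <- mask
  for (s in seq_len(reach)) {
    out <- out & shift3(mask, s, axis, fill = FALSE) &
      shift3(mask, -s, axis, fill = FALSE)
  }
  out
}

# ---- phase unwrapping -------------------------------------------------------

unwrap1d <- function(x) {
  if (length(x) < 2) return(x)
  cumsum(c(x[1], wrap_phase(diff(x))))
}

# Itoh-style 2-D unwrap: reference row, then per-column integration.
# With a mask, only in-mask voxels are unwrapped (others returned unchanged);
# columns not meeting the reference row are aligned to the nearest processed
# neighbour column by a congruence-preserving 2*pi shift.
unwrap2d <- function(w, mask = NULL) {
  d <- dim(w)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  out <- w
  if (!any(mask)) return(out)
  r0 <- which.max(rowSums(mask))
  cols_ref <- which(mask[r0, ])
  if (length(cols_ref) > 0) {
    out[r0, cols_ref] <- unwrap1d(w[r0, cols_ref])
  }
  done <- logical(d[2])
  unwrap_col <- function(cc, anchor_row, anchor_val) {
    rows <- which(mask[, cc])
    vals <- w[rows, cc]
    ia <- match(anchor_row, rows)
    up <- if (ia > 1) rev(anchor_val + cumsum(wrap_phase(diff(rev(vals[1:ia])))))
          else numeric(0)
    dn <- if (ia < length(rows)) anchor_val + cumsum(wrap_phase(diff(vals[ia:length(rows)])))
          else numeric(0)
    out[rows, cc] <<- c(up, anchor_val, dn)
  }
  for (cc in cols_ref) {
    unwrap_col(cc, r0, out[r0, cc])
    done[cc] <- TRUE
  }
  # stragglers: align to an adjacent processed column at a shared row
  remaining <- setdiff(which(colSums(mask) > 0), which(done))
  guard <- 0
  while (length(remaining) > 0 && guard < d[2]) {
    guard <- guard + 1
    for (cc in remaining) {
      for (nb in c(cc - 1, cc + 1)) {
        if (nb < 1 || nb > d[2] || !done[nb]) next
        shared <- which(mask[, cc] & mask[, nb])
        if (length(shared) == 0) next
        rr <- shared[1]
        anchor <- w[rr, cc] +
          2 * pi * round((out[rr, nb] - w[rr, cc]) / (2 * pi))
        unwrap_col(cc, rr, anchor)
        done[cc] <- TRUE
        break
      }
    }
    remaining <- setdiff(remaining, which(done))
  }
  out
}

#' Unwrap wrapped MR phase images
#'
#' Removes 2*pi wrapping from phase images by integrating wrapped phase
#' differences (Itoh's method) along a reference row and then along each
#' column, per slice, followed by a congruence-preserving 2*pi alignment of
#' consecutive slices. The output equals the input plus an integer multiple
#' of 2*pi at every voxel; the result is exact whenever the true phase
#' changes by less than pi between neighbouring voxels.
#'
#' @param wrapped Matrix (one slice) or 3-D array `[row, col, slice]` with
#'   values in `[-pi, pi)`.
#' @param mask Optional logical mask of the same shape restricting the
#'   unwrap to tissue; voxels outside are returned unchanged.
#' @return Unwrapped phase, same shape, congruent to the input modulo 2*pi.
#' @export
unwrap_phase <- function(wrapped, mask = NULL) {
  if (max(abs(wrapped[if (is.null(mask)) TRUE else mask])) > pi + 1e-9) {
    stop("wrapped phase must lie in [-pi, pi)")
  }
  if (is.matrix(wrapped)) return(unwrap2d(wrapped, mask))
  stopifnot(length(dim(wrapped)) == 3)
  d <- dim(wrapped)
  out <- wrapped
  for (s in seq_len(d[3])) {
    ms <- if (is.null(mask)) NULL else mask[, , s]
    out[, , s] <- unwrap2d(wrapped[, , s], ms)
  }
  # align slices by a 2*pi multiple of the median inter-slice difference
  for (s in seq_len(d[3])[-1]) {
    shared <- if (is.null(mask)) array(TRUE, d[1:2]) else
      (mask[, , s] & mask[, , s - 1])
    if (!any(shared)) next
    dmed <- median((out[, , s] - out[, , s - 1])[shared])
    out[, , s] <- out[, , s] - 2 * pi * round(dmed / (2 * pi))
  }
  out
}

# ---- harmonic extraction ----------------------------------------------------

#' Extract the fundamental harmonic over phase offsets
#'
#' Computes the complex amplitude of the vibration-frequency component per
#' voxel by a discrete Fourier transform over the offset dimension, so that a
#' series `A * cos(2*pi*j/N + phi0)` yields `A * exp(i*phi0)`. The result is
#' converted to micrometres of displacement using the encoding efficiency.
#'
#' @param offset_series Array whose **last** dimension indexes the offsets
#'   (already unwrapped phase, rad).
#' @param encoding_efficiency Phase per displacement, rad/um.
#' @return Complex array (one dimension fewer), displacement amplitude in um.
#' @export
extract_harmonic <- function(offset_series, encoding_efficiency = 1) {
  d <- dim(offset_series)
  n <- d[length(d)]
  if (is.null(n) || n < 3) {
    stop("at least 3 offsets are required to identify the fundamental")
  }
  m <- matrix(offset_series, ncol = n)
  kern <- exp(-2i * pi * (seq_len(n) - 1) / n)
  out <- (2 / n) * drop(m %*% kern) / encoding_efficiency
  array(out, dim = d[-length(d)])
}

# ---- curl -------------------------------------------------------------------

#' Curl of a complex displacement field
#'
#' Central finite differences with anisotropic voxel spacing. The curl
#' removes the compressional (irrotational) part of the wave field before
#' Helmholtz inversion. The one-voxel border (and one voxel inside any
#' provided support mask) is marked invalid.
#'
#' @param displacement Complex array `[row, col, slice, component]` in um.
#' @param geometry An [acquisition_geometry()] providing the spacing.
#' @param mask Optional logical support mask `[row, col, slice]`.
#' @return A `cmre_curl`: `values` (complex array, 1/m-scaled curl),
#'   `validity_mask`, `geometry`.
#' @export
curl_field <- function(displacement, geometry, mask = NULL) {
  d <- dim(displacement)
  if (length(d) != 4 || d[4] != 3) {
    stop("displacement must be [row, col, slice, component]")
  }
  if (any(d[1:3] < 3)) stop("need at least 3 voxels along every axis")
  h <- geometry$voxel_size * 1e-6 # meters
  D <- function(a, axis) {
    (shift3(a, -1, axis, fill = NA) - shift3(a, 1, axis, fill = NA)) /
      (2 * h[axis])
  }
  u1 <- displacement[, , , 1]
  u2 <- displacement[, , , 2]
  u3 <- displacement[, , , 3]
  if (!is.null(mask)) {
    u1[!mask] <- NA
    u2[!mask] <- NA
    u3[!mask] <- NA
  }
  q <- array(NA_complex_, dim = d)
  q[, , , 1] <- D(u3, 2) - D(u2, 3)
  q[, , , 2] <- D(u1, 3) - D(u3, 1)
  q[, , , 3] <- D(u2, 1) - D(u1, 2)
  valid <- is.finite(Re(q[, , , 1])) & is.finite(Re(q[, , , 2])) &
    is.finite(Re(q[, , , 3]))
  structure(list(values = q, validity_mask = valid, geometry = geometry),
            class = "cmre_curl")
}

# ---- Helmholtz inversion ----------------------------------------------------

#' Invert the Helmholtz equation for the complex shear modulus
#'
#' Per-voxel algebraic inversion `G* = -rho * omega^2 * q / laplacian(q)`
#' applied to the curl of the displacement field. The complex curl is first
#' smoothed with a 3-D Gaussian (mask-aware, default SD 0.9 voxel), then the Laplacian is taken
#' with 2nd-order central differences per axis plus a compact 4th-order
#' correction term `-h^2/12 * D2(D2 q)` that removes the plane-wave
#' discretization bias. Curl components whose Laplacian magnitude falls
#' below `stability_floor` times the grid median are excluded per voxel; the
#' remaining components are combined by a `|laplacian|^2`-weighted average
#' (equivalently, a per-voxel least-squares fit of `q = G * (-laplacian /
#' (rho*omega^2))`), or by a component-wise median. Voxels with no
#' admissible component are masked. Negative loss moduli are clamped to zero
#' and flagged.
#'
#' @param curl A `cmre_curl` from [curl_field()].
#' @param density Density rho, kg/m^3.
#' @param angular_frequency omega, rad/s.
#' @param stability_floor Relative floor on `|laplacian|` (default 1e-3 of
#'   the grid median); must be >= 0.
#' @param smooth_sigma Gaussian smoothing SD in voxels (0 disables).
#' @param combine `"weighted"` (default) or `"median"`.
#' @return A `cmre_elastogram`: `storage_modulus` and `loss_modulus` (kPa
#'   arrays), `validity_mask`, `clamped`, plus `density` and
#'   `angular_frequency`.
#' @export
helmholtz_invert <- function(curl, density = 1000, angular_frequency,
                             stability_floor = 1e-3, smooth_sigma = 0.9,
                             combine = c("weighted", "median")) {
  combine <- match.arg(combine)
  if (stability_floor < 0) stop("stability_floor must be >= 0")
  if (density <= 0 || angular_frequency <= 0) {
    stop("density and angular_frequency must be positive")
  }
  q <- curl$values
  valid <- curl$validity_mask
  if (!any(valid)) stop("no valid voxels to invert")
  h <- curl$geometry$voxel_size * 1e-6
  d3 <- dim(valid)

  qs <- array(NA_complex_, dim = dim(q))
  L <- array(NA_complex_, dim = dim(q))
  for (i in 1:3) {
    qi <- smooth_masked(q[, , , i], valid, smooth_sigma)
    qs[, , , i] <- qi
    Li <- array(0i, dim = d3)
    for (ax in 1:3) {
      d2 <- second_diff(qi, ax, h[ax])
      d4 <- second_diff(d2, ax, h[ax])
      # compact 4th-order correction where the wider stencil fits,
      # plain 2nd-order differences at the remaining border ring
      corr <- d2
      has4 <- is.finite(Re(d4))
      corr[has4] <- d2[has4] - (h[ax]^2 / 12) * d4[has4]
      Li <- Li + corr
    }
    L[, , , i] <- Li
  }
  vL <- valid
  for (ax in 1:3) vL <- erode_shifts(vL, 1, ax)
  vL <- vL & is.finite(Re(L[, , , 1])) & is.finite(Re(L[, , , 2])) &
    is.finite(Re(L[, , , 3]))
  if (!any(vL)) stop("no valid voxels to invert")

  floors <- vapply(1:3, function(i) {
    stability_floor * median(abs(L[, , , i])[vL])
  }, numeric(1))

  num <- array(0i, dim = d3)
  den <- array(0, dim = d3)
  n_adm <- array(0L, dim = d3)
  Gcomp <- if (combine == "median") array(NA_complex_, dim = dim(q)) else NULL
  for (i in 1:3) {
    Li <- L[, , , i]
    adm <- vL & is.finite(abs(Li)) & abs(Li) >= floors[i] & abs(Li) > 0
    n_adm <- n_adm + adm
    if (combine == "weighted") {
      qi <- qs[, , , i]
      qi[!adm] <- 0
      Li[!adm] <- 0
      num <- num + qi * Conj(Li)
      den <- den + abs(Li)^2
    } else {
      gi <- array(NA_complex_, dim = d3)
      gi[adm] <- qs[, , , i][adm] / Li[adm]
      Gcomp[, , , i] <- gi
    }
  }
  ok <- vL & n_adm > 0
  G <- array(NA_complex_, dim = d3)
  if (combine == "weighted") {
    G[ok] <- -density * angular_frequency^2 * num[ok] / den[ok]
  } else {
    med_c <- function(idx) {
      x <- Gcomp[, , , 1][idx]
      y <- Gcomp[, , , 2][idx]
      z <- Gcomp[, , , 3][idx]
      m <- cbind(x, y, z)
      complex(real = apply(Re(m), 1, median, na.rm = TRUE),
              imaginary = apply(Im(m), 1, median, na.rm = TRUE))
    }
    G[ok] <- -density * angular_frequency^2 * med_c(ok)
  }
  Gk <- G / 1000
  storage_mod <- Re(Gk)
  loss_mod <- Im(Gk)
  ok <- ok & is.finite(storage_mod) & is.finite(loss_mod) & storage_mod > 0
  clamped <- ok & loss_mod < 0
  loss_mod[clamped] <- 0
  storage_mod[!ok] <- NA_real_
  loss_mod[!ok] <- NA_real_
  if (!any(ok)) stop("no valid voxels to invert (degenerate Laplacian)")
  structure(
    list(storage_modulus = storage_mod, loss_modulus = loss_mod,
         validity_mask = ok, clamped = clamped,
         density = density, angular_frequency = angular_frequency,
         geometry = curl$geometry),
    class = "cmre_elastogram"
  )
}

#' @export
print.cmre_elastogram <- function(x, ...) {
  v <- x$validity_mask
  cat(sprintf(
    "Elastogram: %s voxels, %d valid; median G' %.2f kPa, G'' %.2f kPa\n",
    paste(dim(v), collapse = " x "), sum(v),
    median(x$storage_modulus[v]), median(x$loss_modulus[v])
  ))
  invisible(x)
}

# ---- ROI statistics ---------------------------------------------------------

#' Summarize an elastogram over a region of interest
#'
#' Restricts to the five central slices (slices 3-7 of a 9-slice stack),
#' erodes the ROI in-plane by one voxel to avoid tumor borders, intersects
#' with the elastogram validity mask, and returns the mean storage and loss
#' moduli with the contributing voxel count.
#'
#' @param maps A `cmre_elastogram`.
#' @param roi_mask Logical array on the map grid.
#' @return A tibble: `mean_storage`, `mean_loss` (kPa), `n_voxels`.
#' @export
roi_statistics <- function(maps, roi_mask) {
  d <- dim(maps$validity_mask)
  if (!all(dim(roi_mask) == d)) stop("roi_mask must match the map grid")
  ns <- d[3]
  central <- if (ns >= 5) (floor((ns - 5) / 2) + 1):(floor((ns - 5) / 2) + 5) else {
    warning("fewer than 5 slices; using all")
    seq_len(ns)
  }
  roi <- roi_mask
  # in-plane one-voxel erosion (3x3)
  for (ax in 1:2) roi <- erode_shifts(roi, 1, ax)
  keep <- array(FALSE, dim = d)
  keep[, , central] <- TRUE
  eff <- roi & keep & maps$validity_mask
  if (!any(eff)) stop("effective ROI is empty")
  tibble::tibble(
    mean_storage = mean(maps$storage_modulus[eff]),
    mean_loss = mean(maps$loss_modulus[eff]),
    n_voxels = sum(eff)
  )
}

# ---- full reconstruction ----------------------------------------------------

#' Reconstruct an elastogram from a wrapped-phase acquisition
#'
#' Pipeline: per-slice phase unwrapping within the tissue support, harmonic
#' extraction over offsets, inverse encoding projection, curl, and Helmholtz
#' inversion.
#'
#' @param acq A `cmre_acquisition` from [simulate_wave_acquisition()].
#' @param ... Passed to [helmholtz_invert()].
#' @return A `cmre_elastogram`.
#' @export
reconstruct_acquisition <- function(acq, ...) {
  geom <- acq$geometry
  d <- grid_dim(geom)
  nof <- geom$n_offsets
  U <- array(0i, dim = c(d, 3))
  for (dd in 1:3) {
    unw <- array(NA_real_, dim = c(d, nof))
    for (j in seq_len(nof)) {
      unw[, , , j] <- unwrap_phase(acq$wrapped_phase[, , , j, dd],
                                   mask = acq$support)
    }
    U[, , , dd] <- extract_harmonic(unw, geom$encoding_efficiency)
  }
  # invert the (orthogonal) encoding projection
  Einv <- t(geom$encoding_directions)
  u <- array(0i, dim = c(d, 3))
  for (comp in 1:3) {
    u[, , , comp] <- Einv[comp, 1] * U[, , , 1] + Einv[comp, 2] * U[, , , 2] +
      Einv[comp, 3] * U[, , , 3]
  }
  q <- curl_field(u, geom, mask = acq$support)
  helmholtz_invert(q, density = 1000, angular_frequency = omega(geom), ...)
}

#' Default tumor ROI for a simulated acquisition
#'
#' The tissue support eroded in-plane by `margin` voxels, emulating a
#' manually drawn ROI that avoids the tumor borders.
#'
#' @param acq A `cmre_acquisition`.
#' @param margin In-plane erosion in voxels.
#' @return Logical array.
#' @export
default_roi <- function(acq, margin = 3) {
  roi <- acq$support
  for (ax in 1:2) roi <- erode_shifts(roi, margin, ax)
  roi
}
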