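test_that("unwrapping recovers wrapped ramps up to a global 2*pi offset", {
  # linear ramp spanning 6*pi across the grid
  n <- 64
  true <- outer(seq(0, 6 * pi, length.out = n), rep(1, n)) +
    outer(rep(1, n), seq(0, 2 * pi, length.out = n))
  wrapped <- ((true + pi) %% (2 * pi)) - pi
  un <- unwrap_phase(wrapped)
  offs <- (un - true) / (2 * pi)
  expect_lt(max(abs(offs - round(mean(offs)))), 1e-9)
  # congruence: output - input is an integer multiple of 2*pi everywhere
  k <- (un - wrapped) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-9)
  # already-unwrapped smooth field is returned unchanged
  smooth_in <- wrapped / 4
  expect_equal(unwrap_phase(smooth_in), smooth_in)
  # constant input unchanged
  cst <- matrix(0.3, 8, 8)
  expect_equal(unwrap_phase(cst), cst)
})

test_that("unwrapping tolerates moderate phase noise", {
  set.seed(1)
  n <- 64
  true <- outer(seq(0, 6 * pi, length.out = n), rep(1, n)) +
    matrix(rnorm(n * n, 0, 0.1), n, n)
  wrapped <- ((true + pi) %% (2 * pi)) - pi
  un <- unwrap_phase(wrapped)
  err <- un - true
  err <- err - 2 * pi * round(median(err) / (2 * pi))
  expect_lt(sqrt(mean(err^2)), 0.15)
})

test_that("harmonic extraction is the single-bin DFT identity", {
  j <- 0:3
  for (phi0 in c(0, pi / 3, -1.2)) {
    series <- array(cos(2 * pi * j / 4 + phi0), dim = c(1, 1, 1, 4))
    h <- extract_harmonic(series)
    expect_equal(Mod(h[1, 1, 1]), 1, tolerance = 1e-10)
    expect_equal(Arg(h[1, 1, 1]), phi0, tolerance = 1e-10)
  }
  # constant (DC) series has zero fundamental
  dc <- array(0.7, dim = c(2, 2, 1, 4))
  expect_equal(max(Mod(extract_harmonic(dc))), 0)
  expect_error(extract_harmonic(array(0, dim = c(2, 2, 2))), "3 offsets")
})

test_that("harmonic extraction averages white noise", {
  set.seed(2)
  n <- 100
  amp <- array(NA_real_, dim = c(n, n, 1, 4))
  for (j in 1:4) {
    amp[, , 1, j] <- cos(2 * pi * (j - 1) / 4 + 0.4) +
      matrix(rnorm(n * n, 0, 0.2), n, n)
  }
  h <- extract_harmonic(amp)
  err <- Mod(h - exp(0.4i))
  # complex-amplitude noise SD is 0.2 * sqrt(2/N) = 0.2/sqrt(2)
  expect_lt(mean(err), 0.2 / sqrt(2) * 1.3)
})

test_that("curl kills constant and irrotational fields", {
  geom <- small_geometry(20, 20, 9)
  d <- c(20, 20, 9)
  cst <- array(1 + 2i, dim = c(d, 3))
  qc <- curl_field(cst, geom)
  expect_equal(max(abs(qc$values[, , , 1][qc$validity_mask])), 0)
  # u = grad(phi) for smooth phi -> curl at discretization floor
  h <- geom$voxel_size * 1e-6
  xr <- (1:20) * h[1]; yc <- (1:20) * h[2]; zs <- (1:9) * h[3]
  kx <- 500; ky <- 300; kz <- 150
  phase <- outer(outer(kx * xr, ky * yc, "+"), kz * zs, "+")
  phi <- sin(phase)
  u <- array(0i, dim = c(d, 3))
  u[, , , 1] <- kx * cos(phase)
  u[, , , 2] <- ky * cos(phase)
  u[, , , 3] <- kz * cos(phase)
  qg <- curl_field(u, geom)
  scale <- max(abs(u)) * max(kx, ky, kz) # typical first-derivative magnitude
  valid <- qg$validity_mask
  rel <- max(abs(qg$values[, , , 2][valid])) / scale
  expect_lt(rel, 0.01) # below the discretization floor
})

test_that("curl of a transverse plane wave has amplitude |k||u|", {
  geom <- small_geometry(40, 40, 9)
  gs <- complex(real = 2, imaginary = 0.8)
  k <- shear_wavenumber(gs, 1000, 600)
  # build the displacement, take the numeric curl, compare to the analytic one
  d <- c(40, 40, 9)
  h <- geom$voxel_size * 1e-6
  az <- 35 * pi / 180
  dir <- c(cos(az), sin(az), 0)
  pol <- c(0, 0, 1)
  xr <- (seq_len(40) - 20.5) * h[1]
  yc <- (seq_len(40) - 20.5) * h[2]
  zs <- (seq_len(9) - 5) * h[3]
  field <- outer(outer(exp(-1i * k * dir[1] * xr),
                       exp(-1i * k * dir[2] * yc)),
                 exp(-1i * k * dir[3] * zs))
  u <- array(0i, dim = c(d, 3))
  for (cc in 1:3) u[, , , cc] <- pol[cc] * field
  q <- curl_field(u, geom)
  valid <- q$validity_mask
  qn <- sqrt(abs(q$values[, , , 1])^2 + abs(q$values[, , , 2])^2 +
               abs(q$values[, , , 3])^2)
  expected <- abs(k) * abs(field)
  rel <- abs(qn[valid] / expected[valid] - 1)
  # central differences attenuate a plane wave by about (kh)^2/6
  kh <- abs(k) * max(geom$voxel_size) * 1e-6
  expect_lt(median(rel), kh^2 / 6)
  # 2nd-order accuracy: quadrupling G* halves kh and quarters the error
  k2 <- shear_wavenumber(4 * gs, 1000, 600)
  field2 <- outer(outer(exp(-1i * k2 * dir[1] * xr),
                        exp(-1i * k2 * dir[2] * yc)),
                  exp(-1i * k2 * dir[3] * zs))
  u2 <- array(0i, dim = c(d, 3))
  for (cc in 1:3) u2[, , , cc] <- pol[cc] * field2
  qb <- curl_field(u2, geom)
  qn2 <- sqrt(abs(qb$values[, , , 1])^2 + abs(qb$values[, , , 2])^2 +
                abs(qb$values[, , , 3])^2)
  rel2 <- abs(qn2[valid] / (abs(k2) * abs(field2))[valid] - 1)
  ratio <- median(rel) / median(rel2)
  expect_gt(ratio, 2.5)
  expect_error(curl_field(u[, , 1:2, , drop = FALSE], geom), "3 voxels")
})

test_that("Helmholtz inversion recovers plane-wave moduli within 2%", {
  geom <- small_geometry(48, 48, 9)
  # wavelength ~ 10 voxels: G* = 3 + 1i kPa at 600 Hz, rho = 1000
  gs <- complex(real = 3, imaginary = 1)
  q <- plane_wave_curl(gs, geom)
  maps <- helmholtz_invert(q, density = 1000, angular_frequency = omega(geom))
  m <- roi_means_of(maps)
  expect_lt(abs(m["storage"] - 3) / 3, 0.02)
  expect_lt(abs(m["loss"] - 1) / 1, 0.02)
})

test_that("inversion is invariant to complex scaling of the curl", {
  geom <- small_geometry(32, 32, 9)
  q <- plane_wave_curl(2 + 1i, geom)
  q2 <- q
  q2$values <- q$values * (0.3 - 1.7i)
  m1 <- helmholtz_invert(q, 1000, omega(geom))
  m2 <- helmholtz_invert(q2, 1000, omega(geom))
  expect_equal(m1$storage_modulus, m2$storage_modulus, tolerance = 1e-9)
  expect_equal(m1$loss_modulus, m2$loss_modulus, tolerance = 1e-9)
})

test_that("linear-in-space curl regions are masked, not infinite", {
  geom <- small_geometry(16, 16, 9)
  d <- c(16, 16, 9)
  xr <- seq_len(16)
  lin <- outer(outer(xr, rep(1, 16)), rep(1, 9)) # laplacian exactly zero
  q <- array(0i, dim = c(d, 3))
  for (cc in 1:3) q[, , , cc] <- lin + 0i
  curl <- structure(list(values = q, validity_mask = array(TRUE, dim = d),
                         geometry = geom), class = "cmre_curl")
  # smoothing disabled so the Laplacian of the linear field is exactly zero
  expect_error(helmholtz_invert(curl, 1000, omega(geom), smooth_sigma = 0),
               "no valid voxels")
  # mixing a plane wave with a linear patch keeps the patch masked
  pw <- plane_wave_curl(2 + 1i, geom)
  mix <- pw
  mix$values[1:6, , , ] <- q[1:6, , , ]
  maps <- helmholtz_invert(mix, 1000, omega(geom), smooth_sigma = 0)
  expect_false(any(maps$validity_mask[2:4, 8:9, 5]))
  expect_true(all(is.finite(maps$storage_modulus[maps$validity_mask])))
})

test_that("valid voxels never carry non-finite moduli", {
  geom <- small_geometry(24, 24, 9)
  set.seed(4)
  for (gs in c(1 + 0.5i, 3 + 2i)) {
    q <- plane_wave_curl(gs, geom)
    q$values <- q$values +
      array(complex(real = rnorm(length(q$values), 0, 1e-3),
                    imaginary = rnorm(length(q$values), 0, 1e-3)),
            dim = dim(q$values))
    maps <- helmholtz_invert(q, 1000, omega(geom))
    ok <- maps$validity_mask
    expect_true(all(is.finite(maps$storage_modulus[ok])))
    expect_true(all(is.finite(maps$loss_modulus[ok])))
    expect_true(all(maps$storage_modulus[ok] > 0))
    expect_true(all(maps$loss_modulus[ok] >= 0))
  }
})

test_that("ROI statistics restrict to the five central slices and the mask", {
  geom <- small_geometry(20, 20, 9)
  d <- c(20, 20, 9)
  storage <- array(1.6, dim = d)
  storage[, , c(1, 2, 8, 9)] <- 99 # outer slices must not contribute
  maps <- structure(
    list(storage_modulus = storage, loss_modulus = array(0.8, dim = d),
         validity_mask = array(TRUE, dim = d),
         clamped = array(FALSE, dim = d), density = 1000,
         angular_frequency = omega(geom), geometry = geom),
    class = "cmre_elastogram"
  )
  roi <- array(TRUE, dim = d)
  st <- roi_statistics(maps, roi)
  expect_equal(st$mean_storage, 1.6)
  expect_equal(st$mean_loss, 0.8)
  # half the ROI invalid -> mean over the valid half, count halved
  maps$validity_mask[1:10, , ] <- FALSE
  maps$storage_modulus[1:10, , ] <- NA
  st2 <- roi_statistics(maps, roi)
  expect_equal(st2$mean_storage, 1.6)
  expect_lt(st2$n_voxels, st$n_voxels)
  maps$validity_mask[] <- FALSE
  expect_error(roi_statistics(maps, roi), "empty")
})
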