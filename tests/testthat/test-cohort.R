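test_that("acquisition geometry validates its invariants", {
  g <- acquisition_geometry()
  expect_equal(omega(g), 2 * pi * 600)
  expect_equal(g$voxel_size, c(300, 300, 350))
  expect_error(acquisition_geometry(matrix_rows = 0), "positive")
  expect_error(acquisition_geometry(voxel_size = c(300, -1, 350)), "positive")
  expect_error(
    acquisition_geometry(encoding_directions = matrix(1, 3, 3)),
    "orthogonal"
  )
})

test_that("same config and seed give identical cohorts", {
  cfg <- cohort_config()
  expect_identical(sample_cohort(cfg, seed = 42), sample_cohort(cfg, seed = 42))
  expect_false(identical(sample_cohort(cfg, seed = 1),
                         sample_cohort(cfg, seed = 2)))
})

test_that("default cohort has 15 HCC and 9 CCA subjects", {
  co <- sample_cohort(cohort_config(), seed = 1)
  expect_equal(sum(co$tumor_type == "HCC"), 15)
  expect_equal(sum(co$tumor_type == "CCA"), 9)
  expect_true(all(co$solid_stress >= 0))
  expect_true(all(co$interstitial_fluid_pressure >= 0))
  expect_true(all(co$collagen_fraction >= 0 & co$collagen_fraction <= 100))
  expect_true(all(co$basal_elasticity > 0))
  expect_true(all(co$basal_viscosity >= 0))
  # physical validity over the configured compression range
  expect_true(all(co$basal_elasticity + 4 * co$stiffening_slope > 0))
})

test_that("large samples recover the configured covariate means", {
  cfg <- cohort_config(n_hcc = 5000, n_cca = 5000)
  co <- sample_cohort(cfg, seed = 3)
  hcc <- co[co$tumor_type == "HCC", ]
  se <- 0.4 / sqrt(5000)
  expect_lt(abs(mean(hcc$collagen_fraction) - 1.1), 2 * se + 0.02)
})

test_that("structural calibration matches configured group means and R^2", {
  cfg <- cohort_config(n_hcc = 100000, n_cca = 100000)
  co <- sample_cohort(cfg, seed = 9)
  for (tt in c("HCC", "CCA")) {
    g <- co[co$tumor_type == tt, ]
    m <- cfg$outcomes
    idx <- if (tt == "HCC") "hcc" else "cca"
    expect_lt(abs(mean(g$basal_elasticity) -
                    m$elasticity$group_means[[idx]]) /
                m$elasticity$group_means[[idx]], 0.005)
    expect_lt(abs(mean(g$basal_viscosity) -
                    m$viscosity$group_means[[idx]]) /
                m$viscosity$group_means[[idx]], 0.005)
    expect_lt(abs(mean(g$stiffening_slope) -
                    m$slope$group_means[[idx]]) /
                m$slope$group_means[[idx]], 0.005)
  }
  r2_e <- summary(lm(basal_elasticity ~ interstitial_fluid_pressure +
                       collagen_fraction + tumor_type, co))$r.squared
  r2_v <- summary(lm(basal_viscosity ~ interstitial_fluid_pressure +
                       collagen_fraction + tumor_type, co))$r.squared
  r2_s <- summary(lm(stiffening_slope ~ solid_stress + collagen_fraction +
                       cellularity + tumor_type, co))$r.squared
  expect_lt(abs(r2_e - 0.82), 0.02)
  expect_lt(abs(r2_v - 0.87), 0.02)
  expect_lt(abs(r2_s - 0.75), 0.02)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_hcc = 1), "at least 2")
  expect_error(cohort_config(compression_levels = c(2, 2)), "distinct")
  bad <- cohort_config()
  oc <- bad$outcomes
  oc$elasticity$r_squared <- 1.4
  expect_error(cohort_config(outcomes = oc), "R\\^2")
  sds <- list(
    hcc = c(solid_stress = -1, ifp = 0.9, volume = 210, collagen = 0.4,
            cellularity = 10),
    cca = c(solid_stress = 6.6, ifp = 1, volume = 222, collagen = 0.8,
            cellularity = 16)
  )
  expect_error(cohort_config(covariate_sds = sds), "SD")
})

test_that("pressure readings are duplicate-averaged and unbiased", {
  co <- sample_cohort(cohort_config(), seed = 5)
  # zero noise: additive identity, solid stress = total - IFP
  m0 <- simulate_pressure_readings(co, noise_sd = 0, seed = 1)
  expect_equal(m0$measured_total_pressure,
               co$solid_stress + co$interstitial_fluid_pressure)
  expect_equal(m0$measured_ifp, co$interstitial_fluid_pressure)
  expect_equal(m0$measured_solid_stress, co$solid_stress)
  expect_error(simulate_pressure_readings(co, noise_sd = -1), ">= 0")
  # replicate averaging: 10^4 subjects, unit noise -> bias < 0.1 mmHg
  big <- sample_cohort(cohort_config(n_hcc = 5000, n_cca = 5000), seed = 2)
  mb <- simulate_pressure_readings(big, noise_sd = 1, seed = 3)
  expect_lt(abs(mean(mb$measured_solid_stress - big$solid_stress)), 0.1)
})
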