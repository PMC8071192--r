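test_that("stiffening rate is the OLS slope of elasticity on compression", {
  fit <- stiffening_rate(data.frame(compression = c(0, 2, 4),
                                    elasticity = c(1.6, 2.8, 4.0)))
  expect_equal(fit$slope, 0.6)
  expect_equal(fit$intercept, 1.6)
  expect_equal(fit$r_squared, 1)
  # constant elasticity -> zero slope
  flat <- stiffening_rate(data.frame(compression = c(0, 2, 4),
                                     elasticity = rep(2, 3)))
  expect_equal(flat$slope, 0)
  expect_error(stiffening_rate(data.frame(compression = c(2, 2),
                                          elasticity = c(1, 2))), "distinct")
  expect_error(stiffening_rate(data.frame(compression = c(0, 2),
                                          elasticity = c(-1, 2))), "positive")
})

test_that("the slope is invariant to common unit rescaling of both axes", {
  set.seed(1)
  x <- c(0, 2, 4)
  y <- 1.5 + 0.7 * x + rnorm(3, 0, 0.05)
  f1 <- stiffening_rate(data.frame(compression = x, elasticity = y))
  f2 <- stiffening_rate(data.frame(compression = x * 7.5006, # kPa -> mmHg
                                   elasticity = y * 7.5006))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
})

test_that("per-subject slopes are recovered across a noise-free cohort", {
  # ground-truth slopes against OLS recovery on exact lines; the full
  # simulate+reconstruct path is covered in the wave-simulation tests
  co <- sample_cohort(cohort_config(n_hcc = 120, n_cca = 80), seed = 8)
  slopes <- vapply(seq_len(nrow(co)), function(i) {
    x <- c(0, 2, 4)
    y <- co$basal_elasticity[i] + co$stiffening_slope[i] * x
    stiffening_rate(data.frame(compression = x, elasticity = y))$slope
  }, numeric(1))
  expect_lt(mean(abs(slopes - co$stiffening_slope)), 0.05)
})

test_that("repeatability index follows the 1.96 x SD(relative difference) rule", {
  m <- c(100, 100, 100, 100, 100)
  expect_equal(repeatability_index(m, m), 0)
  # construct 5 pairs whose relative differences have SD exactly 11.22%
  d_target <- c(-1, -0.5, 0, 0.5, 1)
  d_target <- d_target / sd(d_target) * 11.22 # percent
  m1 <- 100 * (1 + d_target / 200)
  m2 <- 100 * (1 - d_target / 200) # then 100*(m1-m2)/mean = d_target
  expect_equal(repeatability_index(m1, m2), 1.96 * 11.22, tolerance = 1e-9)
  # relabeling replicates flips the sign of every difference: SD unchanged
  expect_equal(repeatability_index(m2, m1), repeatability_index(m1, m2))
  expect_error(repeatability_index(c(1, -2), c(1, 0)), "positive")
  expect_error(repeatability_index(1, 1), "2 replicate pairs")
  # the within-subject CV convention is available as an alternative
  expect_gt(repeatability_index(m1, m2, method = "cv"), 0)
})

test_that("session jitter produces a repeatability index near 22 percent", {
  # two sessions of the same subjects differing only by the lognormal
  # session factor (sdlog 0.08): 1.96 * sqrt(2) * 8% is about 22%
  set.seed(42)
  n <- 400
  truth <- rep(1.6, n)
  s1 <- truth * exp(rnorm(n, 0, 0.08))
  s2 <- truth * exp(rnorm(n, 0, 0.08))
  idx <- repeatability_index(s1, s2)
  expect_gt(idx, 18)
  expect_lt(idx, 26)
})
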