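# independent enumeration oracle for the exact Mann-Whitney p-value:
# enumerate all assignments of ranks to group A and count |U - n1*n2/2|
# at least as extreme as observed
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  centre <- n1 * n2 / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

test_that("Mann-Whitney matches exact enumeration on 3 + 3", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney(a, b)
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 0.1) # 2/20 orderings
  expect_equal(res$p_value, enumerate_mw_p(a, b))
  expect_true(res$exact)
  # a less extreme configuration, still against the oracle
  a2 <- c(1, 4, 5); b2 <- c(2, 3, 6)
  expect_equal(mann_whitney(a2, b2)$p_value, enumerate_mw_p(a2, b2))
  # near-identical groups give p close to 1
  expect_gt(mann_whitney(c(1, 2, 3), c(1.1, 2.1, 2.9))$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("group difference in solid stress is detectable in a larger cohort", {
  co <- sample_cohort(cohort_config(n_hcc = 150, n_cca = 90), seed = 4)
  res <- mann_whitney(co$solid_stress[co$tumor_type == "HCC"],
                      co$solid_stress[co$tumor_type == "CCA"])
  expect_lt(res$p_value, 0.05)
  expect_false(res$exact) # normal approximation at this n
})

test_that("partial correlation behaves at its analytic anchors", {
  set.seed(1)
  x <- rnorm(50)
  cov <- rbinom(50, 1, 0.5)
  expect_equal(partial_correlation(x, x, cov)$r, 1)
  # constant covariate reduces to plain Pearson correlation
  y <- 0.5 * x + rnorm(50)
  expect_equal(partial_correlation(x, y, rep(1, 50))$r, cor(x, y))
  # association purely driven by the covariate vanishes after adjustment
  set.seed(2)
  lvl <- rbinom(2000, 1, 0.5)
  x2 <- rnorm(2000) + 3 * lvl
  y2 <- rnorm(2000) + 3 * lvl
  expect_lt(abs(partial_correlation(x2, y2, lvl)$r), 0.05)
  expect_error(partial_correlation(x[1:3], x[1:3], cov[1:3]), "at least 4")
  expect_error(partial_correlation(cov, x, cov), "residual variance")
})

test_that("partial correlation p-values use n - 3 degrees of freedom", {
  set.seed(3)
  n <- 24
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rbinom(n, 1, 0.4)
  pc <- partial_correlation(x, y, z)
  tstat <- pc$r * sqrt((n - 3) / (1 - pc$r^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tstat), n - 3))
})

test_that("stepwise regression selects true predictors and drops noise", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = 2 * x1 + rnorm(n, 0, 0.5), x1 = x1, x2 = x2)
  m <- stepwise_regression(d, "y", c("x1", "x2"))
  expect_identical(m$included, "x1")
  expect_identical(m$excluded, "x2")
  expect_equal(m$coefficients$estimate, 2, tolerance = 0.1)
  expect_gt(m$r_squared, 0.9)
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(5)
  n <- 100
  x1 <- rnorm(n)
  d <- data.frame(y = x1 + rnorm(n, 0, 0.2), x1 = x1, dup = x1)
  expect_warning(m <- stepwise_regression(d, "y", c("x1", "dup")),
                 "collinear")
  expect_length(m$included, 1)
})

test_that("stepwise selection is a fixed point of itself", {
  co <- sample_cohort(cohort_config(n_hcc = 150, n_cca = 90), seed = 6)
  d <- data.frame(
    y = co$stiffening_slope, solid_stress = co$solid_stress,
    ifp = co$interstitial_fluid_pressure, volume = co$volume,
    collagen = co$collagen_fraction, cellularity = co$cellularity,
    type = as.integer(co$tumor_type) - 1
  )
  m1 <- stepwise_regression(d, "y", setdiff(names(d), "y"))
  m2 <- stepwise_regression(d, "y", m1$included)
  expect_setequal(m2$included, m1$included)
  # structural predictors recovered with the structural signs
  expect_true(all(c("solid_stress", "collagen", "cellularity", "type")
                  %in% m1$included))
  est <- setNames(m1$coefficients$estimate, m1$coefficients$term)
  expect_lt(est[["solid_stress"]], 0)
  expect_lt(est[["collagen"]], 0)
  expect_gt(est[["cellularity"]], 0)
})

test_that("AUC equals the rank estimator and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    n <- 40
    scores <- rnorm(n) + rep(c(0, 1), each = n / 2)
    labels <- rep(c(0, 1), each = n / 2)
    ours <- roc_auc(scores, labels)
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(ours$auc, ref, tolerance = 1e-12)
  }
})

test_that("AUC/Mann-Whitney duality holds, including ties", {
  set.seed(8)
  for (i in 1:10) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    scores <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1)) # ties likely
    labels <- c(rep(1, n1), rep(0, n0))
    a <- roc_auc(scores, labels)
    u <- suppressWarnings(wilcox.test(scores[labels == 1],
                                      scores[labels == 0]))$statistic
    expect_equal(a$auc * n1 * n0, unname(u), tolerance = 1e-9)
  }
})

test_that("ROC handles orientation, degeneracy and the null", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  neg <- roc_auc(c(1, 2, 3, 10, 11), c(1, 1, 1, 0, 0), negate = TRUE)
  expect_equal(neg$auc, 1)
  expect_true(neg$negated)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both label classes")
  set.seed(9)
  perm <- roc_auc(rnorm(2000), sample(rep(0:1, 1000)))
  expect_lt(abs(perm$auc - 0.5), 0.03)
})

test_that("Hanley-McNeil SE and the z-test drive the significance call", {
  set.seed(10)
  scores <- c(rnorm(20, 1.6), rnorm(20))
  labels <- rep(c(1, 0), each = 20)
  r <- roc_auc(scores, labels)
  a <- r$auc; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se_ref <- sqrt((a * (1 - a) + 19 * (q1 - a^2) + 19 * (q2 - a^2)) / 400)
  expect_equal(r$se, se_ref)
  expect_equal(r$p_vs_half, 2 * pnorm(-abs(a - 0.5) / se_ref))
})

test_that("dichotomization applies the boundary rule", {
  expect_equal(dichotomize(c(10, 15.6, 20), 15.6), c(0L, 1L, 1L))
  expect_equal(dichotomize(c(1, 2), 5), c(0L, 0L))
  expect_equal(dichotomize(c(1, 2), 1.5, direction = "le"), c(1L, 0L))
  expect_error(dichotomize(1:3, NA), "finite")
})

test_that("AUC sample size reproduces the 22-subject power calculation", {
  res <- auc_sample_size(0.85, 0.5, 0.05, 0.8, 1.7)
  expect_equal(res$n_total, 22)
  expect_equal(res$n_pos, 8)
  expect_equal(res$n_neg, 14)
  expect_gte(res$achieved_power, 0.8)
  # higher expected AUC needs fewer subjects
  expect_lt(auc_sample_size(0.95, 0.5, 0.05, 0.8, 1.7)$n_total, 22)
  expect_error(auc_sample_size(0.4), "null_auc")
})

test_that("the computed n sits at the analytic power boundary", {
  res <- auc_sample_size(0.85, 0.5, 0.05, 0.8, 1.0)
  hm_power <- function(n_pos, n_neg, a = 0.85) {
    v0 <- cmre:::hanley_mcneil_var(0.5, n_pos, n_neg)
    v1 <- cmre:::hanley_mcneil_var(a, n_pos, n_neg)
    pnorm((a - 0.5 - qnorm(0.975) * sqrt(v0)) / sqrt(v1))
  }
  expect_gte(hm_power(res$n_pos, res$n_neg), 0.8)
  expect_lt(hm_power(res$n_pos - 1, ceiling(1.0 * (res$n_pos - 1))), 0.8)
})
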