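#' Mann-Whitney U test between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. The p-value is exact for
#' a combined sample size of at most 20 without ties, and uses the normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param group_a,group_b Numeric vectors (each at least 2 values).
#' @return A tibble: `u` (U statistic of `group_a`), `p_value`,
#'   `n_a`, `n_b`, `exact` (logical).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # exact two-sided p = 0.1
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    stop("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 20 && !ties
  wt <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    n_a = length(group_a),
    n_b = length(group_b),
    exact = exact
  )
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariate (which may be a binary group indicator or
#' factor). The p-value uses the t distribution with `n - 3` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors.
#' @param covariate Numeric vector or factor of the same length.
#' @return A tibble: `r`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    stop("x, y and covariate must have equal length")
  }
  if (n < 4) stop("at least 4 observations are required")
  z <- if (is.factor(covariate) || is.character(covariate)) {
    as.numeric(as.factor(covariate))
  } else as.numeric(covariate)
  rx <- lm.fit(cbind(1, z), x)$residuals
  ry <- lm.fit(cbind(1, z), y)$residuals
  if (var(rx) < .Machine$double.eps || var(ry) < .Machine$double.eps) {
    stop("zero residual variance after removing the covariate")
  }
  r <- cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, p_value = 2 * pt(-abs(tstat), df), n = n)
}

#' Stepwise multiple regression (forward selection, backward elimination)
#'
#' MedCalc-style stepwise linear regression: at each step, the candidate
#' whose partial F-test has the smallest p-value enters the model if
#' `p < p_enter`; after each entry, included predictors with `p > p_remove`
#' are eliminated; iterate to a fixed point. Candidates that are perfectly
#' collinear with the included set are skipped with a warning. Reported per
#' included predictor: coefficient, partial correlation
#' (`sign(t) * sqrt(t^2 / (t^2 + df))`) and p-value; plus the overall R^2.
#'
#' @param data Data frame containing the response and candidates.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter,p_remove Entry and removal thresholds (defaults 0.05 and
#'   0.10).
#' @return An object of class `cmre_stepwise` with elements `response`,
#'   `included` (ordered), `excluded`, `coefficients` tibble (`term`,
#'   `estimate`, `partial_r`, `p_value`), `r_squared`, `n`, `model` (the lm
#'   fit).
#' @export
stepwise_regression <- function(data, response, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  data <- data[complete.cases(data[, c(response, candidates)]), , drop = FALSE]
  data <- as.data.frame(lapply(data[, c(response, candidates), drop = FALSE],
                               function(col) {
    if (is.factor(col) || is.character(col)) as.numeric(as.factor(col)) - 1
    else as.numeric(col)
  }))
  n <- nrow(data)
  if (n <= length(candidates) + 2) {
    stop("need more observations than candidates + 2")
  }
  y <- data[[response]]
  included <- character(0)
  skipped <- character(0)

  term_p <- function(terms) {
    # p-value and t of each term in the model y ~ terms
    X <- as.matrix(cbind(`(Intercept)` = 1, data[, terms, drop = FALSE]))
    fit <- lm(y ~ X - 1)
    s <- summary(fit)$coefficients
    rownames(s) <- c("(Intercept)", terms)
    s
  }
  repeat {
    changed <- FALSE
    # forward step: best candidate by partial F (= t-test of its coefficient)
    pool <- setdiff(candidates, c(included, skipped))
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(cand) {
        X <- as.matrix(cbind(1, data[, c(included, cand), drop = FALSE]))
        if (qr(X)$rank < ncol(X)) return(NA_real_)
        s <- term_p(c(included, cand))
        s[cand, 4]
      }, numeric(1))
      if (any(is.na(pvals))) {
        coll <- pool[is.na(pvals)]
        warning("skipping collinear candidate(s): ",
                paste(coll, collapse = ", "))
        skipped <- c(skipped, coll)
        pvals <- pvals[!is.na(pvals)]
        pool <- setdiff(pool, coll)
      }
      if (length(pool) > 0 && min(pvals) < p_enter) {
        included <- c(included, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward step
    if (length(included) > 0) {
      s <- term_p(included)
      worst <- included[which.max(s[included, 4])]
      if (s[worst, 4] > p_remove) {
        included <- setdiff(included, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included) > 0) {
    s <- term_p(included)
    df <- n - length(included) - 1
    tvals <- s[included, 3]
    coefs <- tibble::tibble(
      term = included,
      estimate = unname(s[included, 1]),
      partial_r = unname(sign(tvals) * sqrt(tvals^2 / (tvals^2 + df))),
      p_value = unname(s[included, 4])
    )
    fit <- lm(stats::reformulate(included, response = response), data = data)
    r2 <- summary(fit)$r.squared
  } else {
    coefs <- tibble::tibble(term = character(0), estimate = numeric(0),
                            partial_r = numeric(0), p_value = numeric(0))
    fit <- lm(y ~ 1)
    r2 <- 0
  }
  structure(
    list(response = response, included = included,
         excluded = setdiff(candidates, included),
         coefficients = coefs, r_squared = r2, n = n, model = fit),
    class = "cmre_stepwise"
  )
}

#' @export
print.cmre_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise regression of %s (n = %d, R^2 = %.2f)\n",
              x$response, x$n, x$r_squared))
  if (nrow(x$coefficients) > 0) print(x$coefficients)
  if (length(x$excluded) > 0) {
    cat("Not included:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cmre_stepwise <- function(x, ...) {
  dplyr::bind_rows(
    x$coefficients,
    tibble::tibble(term = x$excluded, estimate = NA_real_,
                   partial_r = NA_real_, p_value = NA_real_)
  )
}

#' @export
glance.cmre_stepwise <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n = x$n,
                 n_included = length(x$included))
}

#' Dichotomize a continuous marker at a cutoff
#'
#' Labels are positive (1) when the value is `>= cutoff` (direction `"ge"`,
#' the default, so the boundary value itself is positive) or `<= cutoff`
#' (direction `"le"`).
#'
#' @param values Numeric vector.
#' @param cutoff Finite cutoff.
#' @param direction `"ge"` or `"le"`.
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' dichotomize(c(10, 15.6, 20), 15.6) # 0 1 1
dichotomize <- function(values, cutoff, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (direction == "ge") as.integer(values >= cutoff) else
    as.integer(values <= cutoff)
}

hanley_mcneil_var <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
      (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC by the rank (Mann-Whitney) estimator with midrank tie correction; the
#' standard error uses the Hanley-McNeil formula and the p-value is the
#' two-sided z-test of the AUC against 0.5. For markers negatively
#' associated with the condition (such as the compression stiffening rate
#' versus solid stress), set `negate = TRUE` to use the negated scores; the
#' flag is recorded in the result.
#'
#' @param scores Numeric marker values.
#' @param labels Binary labels (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param negate Use `-scores` as the classifier (records the flag).
#' @return A `cmre_roc` tibble row: `auc`, `se`, `p_vs_half`, `n_pos`,
#'   `n_neg`, `negated`.
#' @export
roc_auc <- function(scores, labels, negate = FALSE) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(unique(labels)) < 2) {
    stop("both label classes must be present")
  }
  if (length(scores) != length(labels)) stop("length mismatch")
  s <- if (negate) -scores else scores
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(s) # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  se <- sqrt(hanley_mcneil_var(auc, n_pos, n_neg))
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else NA_real_
  out <- tibble::tibble(auc = auc, se = se, p_vs_half = p,
                        n_pos = n_pos, n_neg = n_neg, negated = negate)
  class(out) <- c("cmre_roc", class(out))
  attr(out, "scores") <- s
  attr(out, "labels") <- labels
  out
}

#' @export
tidy.cmre_roc <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("auc", "se", "p_vs_half", "n_pos", "n_neg",
                                 "negated")])
}

#' @export
glance.cmre_roc <- function(x, ...) tidy(x)

#' Sample size for detecting an AUC above a null value
#'
#' Smallest total sample size such that a two-sided z-test of the AUC
#' against `null_auc`, with Hanley-McNeil variances under the null and the
#' alternative, reaches the requested power. The negative group size is
#' `ceiling(neg_pos_ratio * n_pos)`; the search increments the positive
#' group size.
#'
#' @param expected_auc AUC under the alternative (`null_auc < expected_auc < 1`).
#' @param null_auc AUC under the null (default 0.5).
#' @param alpha Two-sided significance level.
#' @param power Requested power.
#' @param neg_pos_ratio Ratio of negative to positive subjects.
#' @return A tibble: `n_total`, `n_pos`, `n_neg`, `achieved_power`.
#' @export
#' @examples
#' auc_sample_size(0.85)$n_total # 22 subjects at the default 1.7 ratio
auc_sample_size <- function(expected_auc, null_auc = 0.5, alpha = 0.05,
                            power = 0.8, neg_pos_ratio = 1.7) {
  if (!(null_auc >= 0.5 && null_auc < expected_auc && expected_auc < 1)) {
    stop("need 0.5 <= null_auc < expected_auc < 1")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (neg_pos_ratio <= 0) stop("neg_pos_ratio must be positive")
  za <- qnorm(1 - alpha / 2)
  for (n_pos in 2:10000) {
    n_neg <- ceiling(neg_pos_ratio * n_pos)
    se0 <- sqrt(hanley_mcneil_var(null_auc, n_pos, n_neg))
    se1 <- sqrt(hanley_mcneil_var(expected_auc, n_pos, n_neg))
    pw <- pnorm((expected_auc - null_auc - za * se0) / se1)
    if (pw >= power) {
      return(tibble::tibble(n_total = n_pos + n_neg, n_pos = n_pos,
                            n_neg = n_neg, achieved_power = pw))
    }
  }
  stop("no feasible sample size below 10000 positives")
}
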