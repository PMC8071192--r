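#' Compression stiffening rate
#'
#' Ordinary least-squares slope of tumor elasticity (kPa) on applied
#' compression (kPa) for one subject. Both axes are in kPa, so the slope is
#' dimensionless ("adim"); the intercept estimates the basal elasticity.
#'
#' @param series Data frame with columns `compression` and `elasticity`
#'   (kPa), at least two distinct compression values, elasticities > 0.
#' @return A tibble: `slope`, `intercept` (kPa), `r_squared`, `n_points`,
#'   of class `cmre_stiffening_fit`.
#' @export
#' @examples
#' stiffening_rate(data.frame(compression = c(0, 2, 4),
#'                            elasticity = c(1.6, 2.8, 4.0)))
stiffening_rate <- function(series) {
  x <- series$compression
  y <- series$elasticity
  if (length(unique(x)) < 2) {
    stop("at least 2 distinct compression values are required")
  }
  if (any(y <= 0)) stop("elasticities must be positive")
  fit <- lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(fit$residuals^2) / tss
  out <- tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_points = length(x)
  )
  class(out) <- c("cmre_stiffening_fit", class(out))
  out
}

#' Test-retest repeatability index
#'
#' For replicate pairs (m1, m2), the relative difference of each pair is
#' `d = 100 * (m1 - m2) / mean(m1, m2)` percent; the repeatability index is
#' `1.96 * SD(d)` across pairs. The alternative `"cv"` convention returns
#' `1.96 * sqrt(2) * within-subject CV` in percent.
#'
#' @param m1,m2 Paired positive measurements (first and second session).
#' @param method `"relative_difference"` (default) or `"cv"`.
#' @return Repeatability index in percent.
#' @export
repeatability_index <- function(m1, m2,
                                method = c("relative_difference", "cv")) {
  method <- match.arg(method)
  if (length(m1) != length(m2) || length(m1) < 2) {
    stop("need at least 2 replicate pairs")
  }
  mid <- (m1 + m2) / 2
  if (any(!is.finite(mid)) || any(mid <= 0)) {
    stop("pair means must be positive")
  }
  if (method == "relative_difference") {
    d <- 100 * (m1 - m2) / mid
    1.96 * sd(d)
  } else {
    cv <- sqrt(mean(((m1 - m2)^2 / 2) / mid^2))
    1.96 * sqrt(2) * 100 * cv
  }
}

#' Simulate and reconstruct a compression series for one subject
#'
#' Runs the full forward + inverse pipeline at each applied compression of
#' one scan session: a shared session jitter multiplies the subject's true
#' moduli, one acquisition is simulated per compression level, reconstructed
#' with [reconstruct_acquisition()], and ROI means are extracted.
#'
#' @param subject One-row cohort data frame.
#' @param compressions Applied compressions, kPa.
#' @param geometry An [acquisition_geometry()].
#' @param seed Integer seed for this session.
#' @param noise_sd Phase noise SD, rad.
#' @param session_sdlog Log-SD of the session modulus jitter (0 disables).
#' @param roi_margin In-plane erosion of the tissue support for the ROI.
#' @param ... Passed to [simulate_wave_acquisition()].
#' @return A tibble with one row per compression: `compression`,
#'   `elasticity`, `viscosity`, `n_voxels`.
#' @export
simulate_compression_series <- function(subject, compressions = c(0, 2, 4),
                                        geometry = acquisition_geometry(),
                                        seed = NULL, noise_sd = 0.03,
                                        session_sdlog = 0, roi_margin = 3,
                                        ...) {
  if (!is.null(seed)) set.seed(seed)
  sf <- if (session_sdlog > 0) exp(rnorm(2, 0, session_sdlog)) else c(1, 1)
  purrr::map_dfr(compressions, function(cmp) {
    acq <- simulate_wave_acquisition(subject, compression = cmp,
                                     geometry = geometry, seed = NULL,
                                     noise_sd = noise_sd,
                                     session_factor = sf, ...)
    maps <- reconstruct_acquisition(acq)
    st <- roi_statistics(maps, default_roi(acq, margin = roi_margin))
    tibble::tibble(compression = cmp, elasticity = st$mean_storage,
                   viscosity = st$mean_loss, n_voxels = st$n_voxels)
  })
}
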