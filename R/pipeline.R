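#' Default experiment configuration
#'
#' Reads the packaged YAML configuration that reproduces the calibrated
#' 15 HCC + 9 CCA cohort (see [read_config()] for the schema).
#'
#' @return A `cmre_config` list.
#' @export
default_config <- function() {
  read_config(system.file("extdata", "default_cohort.yaml", package = "cmre"))
}

config_schema <- function() {
  list(
    cohort = c("n_hcc", "n_cca", "compression_levels", "phase_noise_sd",
               "pressure_noise_sd", "session_sdlog"),
    mre = c("support_radius", "roi_margin", "n_repeatability", "grad_target"),
    histology = c("collagen_tile_px", "collagen_pixel_size",
                  "nucleus_pixel_size", "nucleus_field_area",
                  "overlap_fraction"),
    stats = c("solid_stress_cutoff", "collagen_cutoff", "p_enter", "p_remove"),
    power = c("expected_auc", "null_auc", "alpha", "power", "neg_pos_ratio")
  )
}

#' Read and validate an experiment configuration
#'
#' The YAML file has five sections (`cohort`, `mre`, `histology`, `stats`,
#' `power`); unknown sections or keys raise an error naming the offending
#' key path. Missing keys fall back to the packaged defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cmre_config` list with elements `cohort` (a [cohort_config()]),
#'   `mre`, `histology`, `stats`, `power`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  for (section in names(raw)) {
    if (!section %in% names(schema)) {
      stop("unknown config section: ", section)
    }
    bad <- setdiff(names(raw[[section]]), schema[[section]])
    if (length(bad) > 0) {
      stop("unknown config key: ", section, ".", bad[1])
    }
  }
  defaults <- list(
    mre = list(support_radius = 8, roi_margin = 3, n_repeatability = 5,
               grad_target = 2.4),
    histology = list(collagen_tile_px = 512, collagen_pixel_size = 2,
                     nucleus_pixel_size = 0.5, nucleus_field_area = 1,
                     overlap_fraction = 0.1),
    stats = list(solid_stress_cutoff = 15.6, collagen_cutoff = 1.7,
                 p_enter = 0.05, p_remove = 0.10),
    power = list(expected_auc = 0.85, null_auc = 0.5, alpha = 0.05,
                 power = 0.8, neg_pos_ratio = 1.7)
  )
  cfg <- list(cohort = do.call(cohort_config, raw$cohort %||% list()))
  for (section in names(defaults)) {
    cfg[[section]] <- modifyList(defaults[[section]],
                                 raw[[section]] %||% list())
  }
  structure(cfg, class = "cmre_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measure_histology <- function(cohort, hist_cfg, seed) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    ps_slide <- render_picrosirius_slide(
      min(cohort$collagen_fraction[i], 100),
      tile_px = hist_cfg$collagen_tile_px,
      pixel_size = hist_cfg$collagen_pixel_size,
      seed = seed + 101 * i
    )
    cf <- collagen_fraction(ps_slide)
    nuc <- render_nucleus_field(
      cohort$cellularity[i],
      field_area = hist_cfg$nucleus_field_area,
      overlap_fraction = hist_cfg$overlap_fraction,
      pixel_size = hist_cfg$nucleus_pixel_size,
      seed = seed + 101 * i + 50
    )
    cn <- count_nuclei(nuc)
    tibble::tibble(subject_id = cohort$subject_id[i],
                   measured_collagen = cf$collagen_fraction,
                   measured_cellularity = cn$cell_density)
  })
}

measure_mre <- function(cohort, config, seed, progress = FALSE) {
  cc <- config$cohort
  mre <- config$mre
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    if (progress) message("  MRE subject ", cohort$subject_id[i])
    res <- tryCatch({
      series <- simulate_compression_series(
        cohort[i, ], compressions = cc$compression_levels,
        seed = seed + 977 * i, noise_sd = cc$phase_noise_sd,
        session_sdlog = cc$session_sdlog,
        support_radius = mre$support_radius, roi_margin = mre$roi_margin,
        grad_target = mre$grad_target
      )
      fit <- stiffening_rate(series)
      tibble::tibble(
        subject_id = cohort$subject_id[i],
        measured_elasticity = series$elasticity[1],
        measured_viscosity = series$viscosity[1],
        measured_slope = fit$slope,
        slope_r_squared = fit$r_squared,
        excluded = FALSE, exclusion_reason = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(subject_id = cohort$subject_id[i],
                     measured_elasticity = NA_real_,
                     measured_viscosity = NA_real_,
                     measured_slope = NA_real_, slope_r_squared = NA_real_,
                     excluded = TRUE, exclusion_reason = conditionMessage(e))
    })
    res
  })
}

measure_repeatability <- function(cohort, config, seed) {
  n_rep <- min(config$mre$n_repeatability,
               sum(cohort$tumor_type == "HCC"))
  if (n_rep < 2) {
    return(tibble::tibble(parameter = character(0), index = numeric(0)))
  }
  subj <- cohort[cohort$tumor_type == "HCC", ][seq_len(n_rep), ]
  sessions <- purrr::map_dfr(1:2, function(s) {
    m <- measure_mre(subj, config, seed + 31013 * s)
    m$session <- s
    m
  })
  s1 <- sessions[sessions$session == 1, ]
  s2 <- sessions[sessions$session == 2, ]
  ok <- !s1$excluded & !s2$excluded
  tibble::tibble(
    parameter = c("elasticity", "viscosity", "stiffening_rate"),
    index = c(
      repeatability_index(s1$measured_elasticity[ok],
                          s2$measured_elasticity[ok]),
      repeatability_index(s1$measured_viscosity[ok],
                          s2$measured_viscosity[ok]),
      tryCatch(
        repeatability_index(s1$measured_slope[ok], s2$measured_slope[ok]),
        error = function(e) NA_real_
      )
    )
  )
}

cohort_variables <- function() {
  c("measured_elasticity", "measured_viscosity", "measured_slope",
    "measured_solid_stress", "measured_ifp", "volume",
    "measured_collagen", "measured_cellularity")
}

#' Run the full synthetic compression-MRE experiment
#'
#' Generates the calibrated cohort, simulates pressure readings, renders and
#' quantifies histology, simulates and reconstructs the MRE compression
#' series per subject (subjects whose reconstruction fails are excluded and
#' counted), and runs the statistical battery: group summaries and
#' Mann-Whitney comparisons, partial correlations with tumor type as
#' covariate, stepwise regressions for elasticity, viscosity and stiffening
#' rate, four ROC analyses (stiffening rate and elasticity versus elevated
#' solid stress and substantial collagen), a test-retest repeatability
#' substudy, and the AUC-based sample-size calculation.
#'
#' @param config A `cmre_config` (default [default_config()]) or a path to a
#'   YAML file.
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   report.
#' @param outdir Optional directory: writes `cohort.csv`, `report.json` and
#'   `report.txt` (parametric maps and tiles can be written with
#'   [write_elastogram()] and [write_slide()]).
#' @param skip_mre,skip_histology Skip the expensive imaging stages (their
#'   measured values fall back to the ground truth); used for quick
#'   statistical analyses of the cohort itself.
#' @param progress Print per-subject progress messages.
#' @return A `cmre_report` list; see [report_json()].
#' @export
run_experiment <- function(config = default_config(), seed = 1,
                           outdir = NULL, skip_mre = FALSE,
                           skip_histology = FALSE, progress = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "cmre_config"))
  cc <- config$cohort

  cohort <- sample_cohort(cc, seed = seed)
  cohort <- simulate_pressure_readings(cohort, cc$pressure_noise_sd,
                                       seed = seed + 1)

  hist_meas <- if (skip_histology) {
    tibble::tibble(subject_id = cohort$subject_id,
                   measured_collagen = cohort$collagen_fraction,
                   measured_cellularity = cohort$cellularity)
  } else {
    measure_histology(cohort, config$histology, seed = seed + 2)
  }
  mre_meas <- if (skip_mre) {
    tibble::tibble(subject_id = cohort$subject_id,
                   measured_elasticity = cohort$basal_elasticity,
                   measured_viscosity = cohort$basal_viscosity,
                   measured_slope = cohort$stiffening_slope,
                   slope_r_squared = NA_real_,
                   excluded = FALSE, exclusion_reason = NA_character_)
  } else {
    measure_mre(cohort, config, seed = seed + 3, progress = progress)
  }
  full <- dplyr::left_join(cohort, hist_meas, by = "subject_id")
  full <- dplyr::left_join(full, mre_meas, by = "subject_id")
  analyzed <- full[!full$excluded, ]
  n_excluded <- sum(full$excluded)

  vars <- cohort_variables()
  summaries <- purrr::map_dfr(vars, function(v) {
    a <- analyzed[[v]][analyzed$tumor_type == "HCC"]
    b <- analyzed[[v]][analyzed$tumor_type == "CCA"]
    mw <- mann_whitney(a, b)
    tibble::tibble(variable = v,
                   mean_hcc = mean(a), sd_hcc = sd(a),
                   mean_cca = mean(b), sd_cca = sd(b),
                   p_value = mw$p_value)
  })

  predictors <- c("measured_solid_stress", "measured_ifp", "volume",
                  "measured_collagen", "measured_cellularity")
  outcomes <- c("measured_elasticity", "measured_viscosity", "measured_slope")
  partials <- purrr::map_dfr(outcomes, function(oc) {
    purrr::map_dfr(predictors, function(pv) {
      pc <- partial_correlation(analyzed[[pv]], analyzed[[oc]],
                                analyzed$tumor_type)
      tibble::tibble(outcome = oc, predictor = pv, r = pc$r,
                     p_value = pc$p_value)
    })
  })

  step_data <- analyzed[, c(outcomes, predictors, "tumor_type")]
  stepwise <- lapply(setNames(outcomes, outcomes), function(oc) {
    tryCatch(
      stepwise_regression(step_data, oc, c(predictors, "tumor_type"),
                          p_enter = config$stats$p_enter,
                          p_remove = config$stats$p_remove),
      error = function(e) {
        warning("stepwise regression for ", oc, " skipped at degenerate n: ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
  })

  ss_labels <- dichotomize(analyzed$measured_solid_stress,
                           config$stats$solid_stress_cutoff)
  col_labels <- dichotomize(analyzed$measured_collagen,
                            config$stats$collagen_cutoff)
  safe_roc <- function(scores, labels, negate = FALSE) {
    if (length(unique(labels)) < 2) {
      warning("ROC skipped: only one label class present at this cohort size",
              call. = FALSE)
      out <- tibble::tibble(auc = NA_real_, se = NA_real_,
                            p_vs_half = NA_real_, n_pos = sum(labels == 1),
                            n_neg = sum(labels == 0), negated = negate)
      class(out) <- c("cmre_roc", class(out))
      return(out)
    }
    roc_auc(scores, labels, negate = negate)
  }
  roc <- list(
    slope_vs_solid_stress =
      safe_roc(analyzed$measured_slope, ss_labels, negate = TRUE),
    elasticity_vs_solid_stress =
      safe_roc(analyzed$measured_elasticity, ss_labels),
    elasticity_vs_collagen =
      safe_roc(analyzed$measured_elasticity, col_labels),
    slope_vs_collagen =
      safe_roc(analyzed$measured_slope, col_labels, negate = TRUE)
  )

  repeatability <- if (skip_mre) {
    tibble::tibble(parameter = character(0), index = numeric(0))
  } else {
    measure_repeatability(cohort, config, seed = seed + 4)
  }

  sample_size <- auc_sample_size(config$power$expected_auc,
                                 config$power$null_auc,
                                 config$power$alpha, config$power$power,
                                 config$power$neg_pos_ratio)

  report <- structure(
    list(
      cohort = full,
      n_analyzed = nrow(analyzed),
      n_excluded = n_excluded,
      group_summaries = summaries,
      partial_correlations = partials,
      stepwise_models = stepwise,
      roc_results = roc,
      repeatability = repeatability,
      sample_size = sample_size,
      provenance = list(seed = seed, config_hash = rlang::hash(config))
    ),
    class = "cmre_report"
  )
  if (!is.null(outdir)) write_report_artifacts(report, config, outdir, seed)
  report
}

#' @export
print.cmre_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Human-readable report table
#'
#' Group summaries and test results rounded to display precision (full
#' precision is kept in the JSON form, [report_json()]).
#'
#' @param report A `cmre_report`.
#' @return Character vector of lines.
#' @export
report_text <- function(report) {
  fmt <- function(m, s) sprintf("%.2f +/- %.2f", m, s)
  gs <- report$group_summaries
  lines <- c(
    sprintf("Compression MRE experiment: %d analyzed, %d excluded",
            report$n_analyzed, report$n_excluded),
    "",
    "Group summaries (HCC vs CCA, Mann-Whitney p):",
    sprintf("  %-24s %-18s %-18s p=%.3g", gs$variable,
            fmt(gs$mean_hcc, gs$sd_hcc), fmt(gs$mean_cca, gs$sd_cca),
            gs$p_value),
    "",
    "ROC analyses:",
    sprintf("  %-28s AUC %.2f +/- %.2f (p=%.3g)%s",
            names(report$roc_results),
            vapply(report$roc_results, function(r) r$auc, 1),
            vapply(report$roc_results, function(r) r$se, 1),
            vapply(report$roc_results, function(r) r$p_vs_half, 1),
            ifelse(vapply(report$roc_results, function(r) r$negated, TRUE),
                   " [negated scores]", "")),
    "",
    sprintf("AUC-based required sample size: %d subjects",
            report$sample_size$n_total)
  )
  if (nrow(report$repeatability) > 0) {
    lines <- c(lines, "",
               sprintf("Repeatability index %s: %.0f%%",
                       report$repeatability$parameter,
                       report$repeatability$index))
  }
  lines
}

#' Serialize a report to JSON
#'
#' Full-precision JSON representation of every reported quantity (group
#' summaries, partial correlations, stepwise models, ROC results,
#' repeatability, sample size, provenance). Identical config and seed give
#' byte-identical JSON.
#'
#' @param report A `cmre_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  x <- list(
    n_analyzed = report$n_analyzed,
    n_excluded = report$n_excluded,
    group_summaries = report$group_summaries,
    partial_correlations = report$partial_correlations,
    stepwise_models = lapply(report$stepwise_models, function(m) {
      if (is.null(m)) return(NULL)
      list(response = m$response, included = as.list(m$included),
           excluded = as.list(m$excluded),
           coefficients = m$coefficients, r_squared = m$r_squared, n = m$n)
    }),
    roc_results = lapply(report$roc_results, tidy),
    repeatability = report$repeatability,
    sample_size = report$sample_size,
    provenance = report$provenance
  )
  jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

write_report_artifacts <- function(report, config, outdir, seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, file.path(outdir, "cohort.csv"))
  writeLines(report_json(report), file.path(outdir, "report.json"))
  writeLines(report_text(report), file.path(outdir, "report.txt"))
  invisible(outdir)
}
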