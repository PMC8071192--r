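#' Plot a ROC curve
#'
#' Empirical ROC curve of the scores stored with a [roc_auc()] result,
#' annotated with the AUC and its Hanley-McNeil standard error.
#'
#' @param object A `cmre_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cmre_roc <- function(object, ...) {
  s <- attr(object, "scores")
  l <- attr(object, "labels")
  th <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(th, function(t) {
    tibble::tibble(tpr = mean(s[l == 1] >= t), fpr = mean(s[l == 0] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.65, y = 0.15,
                      label = sprintf("AUC = %.2f +/- %.2f",
                                      object$auc, object$se)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::coord_equal()
}

#' Plot elastogram slices
#'
#' Raster maps of the storage (or loss) modulus for chosen slices.
#'
#' @param object A `cmre_elastogram`.
#' @param slices Slice indices (default: the central slice).
#' @param map `"storage"` or `"loss"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cmre_elastogram <- function(object, slices = NULL,
                                     map = c("storage", "loss"), ...) {
  map <- match.arg(map)
  arr <- if (map == "storage") object$storage_modulus else object$loss_modulus
  d <- dim(arr)
  if (is.null(slices)) slices <- ceiling(d[3] / 2)
  df <- purrr::map_dfr(slices, function(s) {
    tibble::tibble(
      row = rep(seq_len(d[1]), d[2]),
      col = rep(seq_len(d[2]), each = d[1]),
      slice = s,
      value = as.vector(arr[, , s])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = sprintf("%s modulus (kPa)", map)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a compression series with its stiffening fit
#'
#' Scatter of elasticity versus applied compression with the ordinary
#' least-squares line whose slope is the compression stiffening rate.
#'
#' @param series Data frame with `compression` and `elasticity` (optionally
#'   a `subject_id` column for facetting).
#' @return A ggplot.
#' @export
plot_compression_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$compression,
                                            y = .data$elasticity)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Applied compression (kPa)", y = "Elasticity (kPa)")
  if ("subject_id" %in% names(series)) {
    p <- p + ggplot2::facet_wrap(~subject_id)
  }
  p
}
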