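map_slice_df <- function(values, slice) {
  m <- values[, , slice]
  tibble::tibble(row = as.vector(row(m)), col = as.vector(col(m)),
                 value = as.vector(m))
}

#' Plot a T0 map slice
#'
#' @param object A `t0_map`.
#' @param slice Slice index.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot t0_map
#' @export
autoplot.t0_map <- function(object, slice = 1L, ...) {
  df <- map_slice_df(object$t0, slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10", name = "T0 (ms)") +
    ggplot2::labs(title = sprintf("Zero-crossing map, slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a property map slice
#'
#' @param object A `property_map`.
#' @param slice Slice index.
#' @param ... Unused.
#' @method autoplot property_map
#' @export
autoplot.property_map <- function(object, slice = 1L, ...) {
  df <- map_slice_df(object$values, slice)
  unit <- if (object$property == "conductivity") "S/m" else "rel. permittivity"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10", name = unit) +
    ggplot2::labs(title = sprintf("%s map (%s)", object$property,
                                  object$model_kind),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-phantom ROI errors
#'
#' @param object An `eval_report` from [roi_compare()].
#' @param ... Unused.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$position),
                                       y = .data$pct_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "phantom", y = "signed error (%)",
                  title = sprintf("%s ROI errors (%s), MAPE %.2f%%",
                                  attr(object, "property"),
                                  attr(object, "model_kind"),
                                  mean(object$abs_pct_error))) +
    ggplot2::theme_minimal()
}

#' Plot the permittivity--T0 curve fit over its data
#'
#' @param object A `permittivity_fit`.
#' @param data Optional tibble with `t0_ms`, `eps` to overlay.
#' @param ... Unused.
#' @method autoplot permittivity_fit
#' @export
autoplot.permittivity_fit <- function(object, data = NULL, ...) {
  grid <- tibble::tibble(t0_ms = seq(100, 1600, by = 10))
  grid$eps <- predict(object, grid$t0_ms)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$t0_ms, y = .data$eps)) +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "T0 (ms)", y = "relative permittivity",
                  title = sprintf("Debye-type fit: RMSE %.2f, R2 %.3f",
                                  object$rmse, object$r2)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.35, size = 0.8)
  }
  p
}

#' Plot cross-validated predictions of a regression model
#'
#' @param object An `ept_reg_model`.
#' @param ... Unused.
#' @method autoplot ept_reg_model
#' @export
autoplot.ept_reg_model <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$obs, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "observed", y = "out-of-fold prediction",
                  title = sprintf("%s: CV RMSE %.3f, R2 %.3f", object$kind,
                                  object$metrics$rmse, object$metrics$r2)) +
    ggplot2::theme_minimal()
}
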