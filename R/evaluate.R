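#' Compare map ROI means against reference values
#'
#' Averages a centred `roi_px` x `roi_px` window of the property map over
#' each disk and compares it with the phantom's reference (measured) value:
#' signed percent error `100 (est - ref) / ref` per phantom, plus summary
#' statistics (mean signed error, mean absolute percentage error, max
#' absolute error, RMSE and R2 over the phantom pairs).
#'
#' @param map A [property_map()] (`permittivity_map()` /
#'   `conductivity_map()` output).
#' @param layout [phantom_layout()] of the imaged slice.
#' @param truth Tibble with `position` and `value` (reference per phantom).
#' @param roi_px ROI side; must sit inside the disks. `Inf` (or `"disk"`)
#'   averages over the whole disk instead of a centred square — the footing
#'   used for conductivity maps, whose models amplify T0 noise.
#' @param slice Slice index to evaluate.
#' @return Tibble of class `eval_report` (per-phantom rows) whose summary is
#'   available through [generics::glance()] and always recomputable from the
#'   rows.
#' @export
roi_compare <- function(map, layout = map$layout, truth, roi_px = 5,
                        slice = 1L) {
  stopifnot(inherits(map, "property_map"),
            all(c("position", "value") %in% names(truth)))
  if (any(truth$value == 0)) {
    stop("reference value of 0: percent error undefined")
  }
  grid <- dim(map$values)[1]
  full_disk <- identical(roi_px, "disk") || is.infinite(roi_px)
  est <- vapply(truth$position, function(p) {
    vals <- if (full_disk) {
      map$values[, , slice][layout$assignment == p]
    } else {
      ctr <- layout$centers[layout$centers$position == p, ]
      w <- roi_window(c(ctr$row, ctr$col), roi_px, grid)
      map$values[w$rows, w$cols, slice]
    }
    if (all(is.na(vals))) {
      stop("ROI of position ", p, " is fully masked")
    }
    mean(vals, na.rm = TRUE)
  }, 1)

  rows <- tibble::tibble(
    position = truth$position,
    measured = truth$value,
    estimated = est,
    pct_error = 100 * (est - truth$value) / truth$value,
    abs_pct_error = abs(100 * (est - truth$value) / truth$value)
  )
  if ("id" %in% names(truth)) rows <- dplyr::bind_cols(id = truth$id, rows)
  structure(rows,
            class = c("eval_report", class(rows)),
            property = map$property, model_kind = map$model_kind,
            roi_px = roi_px, slice = slice)
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  m <- regression_metrics(x$measured, x$estimated)
  tibble::tibble(
    property = attr(x, "property"), model = attr(x, "model_kind"),
    mean_signed_error = mean(x$pct_error),
    mape = mean(x$abs_pct_error),
    max_abs_error = max(x$abs_pct_error),
    rmse = m$rmse, r2 = m$r2, n = nrow(x)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", attr(x, "property"), " via ", attr(x, "model_kind"),
      ": MAPE ", format(mean(x$abs_pct_error), digits = 3), "%\n", sep = "")
  NextMethod()
}
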