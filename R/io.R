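#' Write an IR stack to NIfTI with a JSON sidecar
#'
#' One NIfTI file per slice with the inversion time along the fourth
#' dimension, plus `<prefix>.json` holding the acquisition metadata and the
#' layout parameters needed to rebuild it.
#'
#' @param stack [simulate_ir_stack()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_ir_stack <- function(stack, dir, prefix = "ir_stack") {
  stopifnot(inherits(stack, "ir_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$images)
  paths <- character(0)
  for (s in seq_len(d[4])) {
    vol <- array(stack$images[, , , s], dim = c(d[1], d[2], 1, d[3]))
    p <- file.path(dir, sprintf("%s_slice%02d.nii.gz", prefix, s))
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(1, 4)), p)
    paths <- c(paths, p)
  }
  lay <- stack$layout
  sidecar <- list(
    ti_list_ms = stack$ti_list_ms, tr_ms = stack$tr_ms,
    magnitude = stack$magnitude, noise_sd = stack$noise_sd,
    phantom_ids = stack$phantom_ids,
    layout = list(n_phantoms = nrow(lay$centers), grid = lay$grid,
                  fov_mm = lay$grid * lay$pixel_mm,
                  frame_diameter_mm = lay$frame_diameter_mm,
                  phantom_diameter_mm = lay$phantom_diameter_mm,
                  n_slices = lay$n_slices)
  )
  jp <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(sidecar, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read an IR stack written by [write_ir_stack()]
#'
#' @param dir Directory holding the NIfTI files and sidecar.
#' @param prefix File name prefix used when writing.
#' @return An `ir_stack` object.
#' @export
read_ir_stack <- function(dir, prefix = "ir_stack") {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                                 simplifyVector = TRUE)
  lay <- sidecar$layout
  layout <- phantom_layout(lay$n_phantoms, lay$grid, lay$fov_mm,
                           lay$frame_diameter_mm, lay$phantom_diameter_mm,
                           lay$n_slices)
  files <- sort(list.files(dir, pattern = paste0("^", prefix, "_slice.*\\.nii"),
                           full.names = TRUE))
  stopifnot(length(files) == lay$n_slices)
  vols <- lapply(files, function(f) as.array(RNifti::readNifti(f)))
  grid <- lay$grid
  n_ti <- length(sidecar$ti_list_ms)
  images <- array(0, dim = c(grid, grid, n_ti, lay$n_slices))
  for (s in seq_along(vols)) images[, , , s] <- vols[[s]][, , 1, ]
  structure(list(images = images, ti_list_ms = sidecar$ti_list_ms,
                 tr_ms = sidecar$tr_ms, layout = layout,
                 phantom_ids = sidecar$phantom_ids,
                 magnitude = isTRUE(sidecar$magnitude),
                 noise_sd = sidecar$noise_sd),
            class = "ir_stack")
}

#' Write map arrays as NIfTI
#'
#' Works for [fit_t0_map()] results (writes T0/a/b/T1 volumes) and for
#' [permittivity_map()]/[conductivity_map()] results (one volume).
#'
#' @param map A `t0_map` or `property_map`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_map_nifti <- function(map, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- if (inherits(map, "t0_map")) {
    list(t0 = map$t0, a = map$a, b = map$b, T1 = map$T1)
  } else {
    setNames(list(map$values), map$property)
  }
  paths <- vapply(names(arrays), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(RNifti::asNifti(arrays[[nm]]), p)
    p
  }, "")
  invisible(paths)
}

fit_to_json <- function(fit) {
  if (inherits(fit, "t1ept_curve_fit")) {
    list(class = class(fit)[1], coefficients = as.list(fit$coefficients),
         rmse = fit$rmse, r2 = fit$r2, n = fit$n)
  } else if (inherits(fit, "sodium_family_fit")) {
    list(class = "sodium_family_fit", levels = fit$levels,
         s1_trend = as.list(coef(fit$meta_s1)),
         s2_trend = as.list(coef(fit$meta_s2)))
  } else if (inherits(fit, "semicircle_fit")) {
    list(class = "semicircle_fit", bins = fit$bins)
  } else if (inherits(fit, "ept_reg_model")) {
    out <- list(class = "ept_reg_model", kind = fit$kind,
                metrics = fit$metrics, folds = fit$folds,
                grouped = fit$grouped, seed = fit$seed)
    if (inherits(fit$model, "gpr_model")) {
      out$hyperparams <- fit$model$hyperparams
    } else {
      out$coefficients <- as.list(fit$model$coefficients)
    }
    out
  } else if (inherits(fit, "nnf_model")) {
    list(class = "nnf_model", algorithm = fit$algorithm, hidden = fit$hidden,
         weights = fit$weights, metrics = fit$metrics)
  } else {
    stop("cannot serialise object of class ", class(fit)[1])
  }
}

#' Serialise fitted models to JSON
#'
#' @param fits Named list of fitted objects (curve fits, regression models,
#'   neural fits).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fits_json <- function(fits, path) {
  jsonlite::write_json(lapply(fits, fit_to_json), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
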