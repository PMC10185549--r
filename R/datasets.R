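#' Assemble the regression datasets
#'
#' Pairs each phantom's measurement quadruple with its per-slice
#' zero-crossing times: replicate r (1--3) is paired with slice r's T0 (the
#' last slice is reused when fewer slices were imaged), and the fourth
#' (mean) row is paired with the slice-average T0. Four tables are built:
#' `De` (permittivity from T0), and the conductivity tables `Ds1`
#' (sodium-containing phantoms), `Ds2` (potassium-containing) and `Ds3`
#' (all phantoms), each predicting conductivity from permittivity and T0.
#'
#' @param measurements [emulate_dak()] tibble (4 rows per phantom).
#' @param t0_values Tibble with `id`, `slice`, `t0_ms` — per-phantom
#'   per-slice zero-crossing times, from [extract_phantom_t0()] joined to
#'   phantom ids, or from [truth_t0_table()] for tabular studies.
#' @param cohort [build_cohort()] tibble (solute columns define the subsets).
#' @return Named list of tibbles `De`, `Ds1`, `Ds2`, `Ds3`; each carries
#'   `features` and `target` attributes used by [train_cv_model()] and
#'   [train_nnf()].
#' @examples
#' syn <- synthesize_cohort(seed = 1)
#' ds <- build_datasets(syn$measurements, truth_t0_table(syn$truth), syn$truth)
#' nrow(ds$De)  # 560
#' @export
build_datasets <- function(measurements, t0_values, cohort) {
  stopifnot(all(c("id", "replicate", "eps_meas", "sigma_meas") %in%
                  names(measurements)),
            all(c("id", "slice", "t0_ms") %in% names(t0_values)),
            all(c("id", "sodium_pct", "potassium_pct") %in% names(cohort)))

  missing_ids <- setdiff(unique(measurements$id), unique(t0_values$id))
  if (length(missing_ids)) {
    stop("missing T0 for phantom id(s): ",
         paste(head(missing_ids, 5), collapse = ", "))
  }

  n_slice <- max(t0_values$slice)
  slice_t0 <- tidyr::pivot_wider(t0_values, id_cols = "id",
                                 names_from = "slice", values_from = "t0_ms",
                                 names_prefix = "s")
  if (anyNA(slice_t0)) stop("missing T0 for some phantom/slice pairs")
  slice_mat <- as.matrix(slice_t0[, -1, drop = FALSE])

  t0_for <- function(id, replicate) {
    i <- match(id, slice_t0$id)
    ifelse(replicate <= 3,
           slice_mat[cbind(i, pmin(replicate, n_slice))],
           rowMeans(slice_mat)[i])
  }

  base <- measurements |>
    dplyr::mutate(t0_ms = t0_for(.data$id, .data$replicate)) |>
    dplyr::left_join(cohort[, c("id", "sodium_pct", "potassium_pct")], by = "id") |>
    dplyr::rename(eps = "eps_meas", sigma = "sigma_meas")

  with_attrs <- function(d, spec, features, target) {
    stopifnot(!anyNA(d[, c(features, target)]))
    attr(d, "features") <- features
    attr(d, "target") <- target
    attr(d, "spec") <- spec
    d
  }

  list(
    De = with_attrs(dplyr::select(base, "id", "replicate", "t0_ms", "eps"),
                    "De", "t0_ms", "eps"),
    Ds1 = with_attrs(
      dplyr::select(dplyr::filter(base, .data$sodium_pct > 0),
                    "id", "replicate", "eps", "t0_ms", "sigma"),
      "Ds1", c("eps", "t0_ms"), "sigma"),
    Ds2 = with_attrs(
      dplyr::select(dplyr::filter(base, .data$potassium_pct > 0),
                    "id", "replicate", "eps", "t0_ms", "sigma"),
      "Ds2", c("eps", "t0_ms"), "sigma"),
    Ds3 = with_attrs(dplyr::select(base, "id", "replicate", "eps", "t0_ms", "sigma"),
                     "Ds3", c("eps", "t0_ms"), "sigma")
  )
}

#' Ground-truth T0 table for tabular studies
#'
#' Expands the cohort ground truth into the per-slice T0 layout expected by
#' [build_datasets()], for analyses that skip image simulation (every slice
#' carries the phantom's true zero-crossing time).
#'
#' @param truth Tibble with `id` and `T0_ms`.
#' @param n_slices Number of slices to emulate.
#' @return Tibble with `id`, `slice`, `t0_ms`.
#' @export
truth_t0_table <- function(truth, n_slices = 3L) {
  stopifnot(all(c("id", "T0_ms") %in% names(truth)))
  tidyr::expand_grid(id = truth$id, slice = seq_len(n_slices)) |>
    dplyr::left_join(tibble::tibble(id = truth$id, t0_ms = truth$T0_ms),
                     by = "id")
}
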