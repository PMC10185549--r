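# mask-aware k x k box average of a matrix with NAs
box_smooth <- function(mat, k) {
  if (k <= 1) return(mat)
  half_lo <- floor((k - 1) / 2)
  half_hi <- k - 1 - half_lo
  n <- nrow(mat); m <- ncol(mat)
  vals <- ifelse(is.na(mat), 0, mat)
  cnt <- (!is.na(mat)) * 1

  # (n+1) x (m+1) integral image: ii[r+1, c+1] = sum(x[1:r, 1:c])
  integral <- function(x) {
    ii <- matrix(0, n + 1, m + 1)
    ii[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
    ii
  }
  iv <- integral(vals)
  ic <- integral(cnt)

  r1 <- pmax(seq_len(n) - half_lo, 1); r2 <- pmin(seq_len(n) + half_hi, n)
  c1 <- pmax(seq_len(m) - half_lo, 1); c2 <- pmin(seq_len(m) + half_hi, m)
  R1 <- r1[row(mat)]; R2 <- r2[row(mat)]; C1 <- c1[col(mat)]; C2 <- c2[col(mat)]
  at <- function(ii, r, c) ii[cbind(r, c)]
  s <- at(iv, R2 + 1, C2 + 1) - at(iv, R1, C2 + 1) -
    at(iv, R2 + 1, C1) + at(iv, R1, C1)
  ct <- at(ic, R2 + 1, C2 + 1) - at(ic, R1, C2 + 1) -
    at(ic, R2 + 1, C1) + at(ic, R1, C1)
  out <- matrix(ifelse(ct > 0, s / ct, NA_real_), n, m)
  out[is.na(mat)] <- NA_real_
  out
}

new_property_map <- function(values, mask, property, model_kind, clipped = 0L,
                             layout = NULL) {
  structure(list(values = values, mask = mask, property = property,
                 model_kind = model_kind, clipped = clipped, layout = layout),
            class = "property_map")
}

#' @export
print.property_map <- function(x, ...) {
  cat("<property_map> ", x$property, " via ", x$model_kind, ", ",
      sum(x$mask), " pixels, ", x$clipped, " clipped\n", sep = "")
  invisible(x)
}

#' Pixel-wise permittivity map from a T0 map
#'
#' Applies a permittivity model (a Debye-type curve fit, a trained
#' regression model with the single feature `t0_ms`, or a neural fit) to
#' every unmasked pixel. Output is clipped into the physical range [1, 90].
#'
#' @param t0map [fit_t0_map()] result.
#' @param model A `permittivity_fit`, `ept_reg_model` or `nnf_model`.
#' @param clip Output range.
#' @return A `property_map` (values array matches the T0 map shape).
#' @export
permittivity_map <- function(t0map, model, clip = c(1, 90)) {
  stopifnot(inherits(t0map, "t0_map"))
  vals <- t0map$t0
  ok <- !is.na(vals)
  pred <- rep(NA_real_, length(vals))
  t0v <- vals[ok]
  pred[ok] <- if (inherits(model, "permittivity_fit")) {
    predict(model, t0v)
  } else {
    as.numeric(predict(model, matrix(t0v, ncol = 1)))
  }
  n_clip <- sum(pred[ok] < clip[1] | pred[ok] > clip[2])
  pred <- pmin(pmax(pred, clip[1]), clip[2])
  out <- array(pred, dim = dim(vals))
  new_property_map(out, t0map$mask, "permittivity",
                   class(model)[1], n_clip, t0map$layout)
}

#' Pixel-wise conductivity map from T0 and permittivity maps
#'
#' Both input maps are first smoothed with a mask-aware `smooth_px` x
#' `smooth_px` box average (conductivity models take two noisy inputs, so
#' pre-averaging suppresses speckle), then the model is applied pixel-wise.
#' Negative predictions are clipped to zero and counted.
#'
#' @param t0map [fit_t0_map()] result.
#' @param epsmap [permittivity_map()] result aligned with `t0map`.
#' @param model A `semicircle_fit`, `sodium_family_fit` (needs `na_pct`),
#'   `ept_reg_model` or `nnf_model` with features `(eps, t0_ms)`.
#' @param smooth_px Box size; 1 disables smoothing.
#' @param na_pct Sodium map/constant, only for `sodium_family_fit`.
#' @return A `property_map` with `property = "conductivity"`.
#' @export
conductivity_map <- function(t0map, epsmap, model, smooth_px = 3, na_pct = NULL) {
  stopifnot(inherits(t0map, "t0_map"), inherits(epsmap, "property_map"))
  if (!identical(dim(t0map$t0), dim(epsmap$values))) {
    stop("T0 and permittivity maps are misaligned")
  }
  d <- dim(t0map$t0)
  t0s <- array(NA_real_, d); epss <- array(NA_real_, d)
  for (s in seq_len(d[3])) {
    t0s[, , s] <- box_smooth(t0map$t0[, , s], smooth_px)
    epss[, , s] <- box_smooth(epsmap$values[, , s], smooth_px)
  }
  ok <- !is.na(t0s) & !is.na(epss)
  feats <- cbind(eps = epss[ok], t0_ms = t0s[ok])
  pred <- rep(NA_real_, length(t0s))
  pred[ok] <- if (inherits(model, "semicircle_fit")) {
    as.numeric(predict(model, eps = feats[, 1], t0_ms = feats[, 2]))
  } else if (inherits(model, "sodium_family_fit")) {
    stopifnot(!is.null(na_pct))
    as.numeric(predict(model, t0_ms = feats[, 2], na_pct = na_pct))
  } else {
    as.numeric(predict(model, feats))
  }
  n_clip <- sum(pred[ok] < 0)
  pred <- pmax(pred, 0)
  out <- array(pred, dim = d)
  new_property_map(out, ok, "conductivity", class(model)[1], n_clip,
                   t0map$layout)
}
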