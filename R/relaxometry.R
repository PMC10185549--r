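#' Inversion-recovery signal model
#'
#' @param ti_ms Inversion times (ms).
#' @param a Amplitude (proton density scale).
#' @param b Inversion coefficient (2 for an ideal 90 degree readout after a
#'   perfect inversion).
#' @param T1_ms Longitudinal relaxation time (ms).
#' @return Signal values `a * (1 - b * exp(-ti/T1))`.
#' @export
ir_signal <- function(ti_ms, a, b, T1_ms) a * (1 - b * exp(-ti_ms / T1_ms))

ir_bounds <- function(smax) {
  list(lower = c(a = 1e-12, b = 1, T1 = 50),
       upper = c(a = 10 * smax, b = 2.5, T1 = 10000))
}

ir_start <- function(signal, ti_ms) {
  smax <- max(abs(signal))
  m <- length(signal)
  neg <- signal < 0
  if (any(neg) && !all(neg) && max(which(neg)) < m) {
    # interpolate the observed sign change: the zero crossing sits at
    # T1 ln b, so dividing by ln 2 seeds T1 for a near-ideal inversion
    i <- max(which(neg))
    t0e <- ti_ms[i] + (ti_ms[i + 1] - ti_ms[i]) *
      (0 - signal[i]) / (signal[i + 1] - signal[i])
  } else {
    t0e <- ti_ms[which.min(signal)]
  }
  c(a = smax, b = 2, T1 = min(max(t0e / log(2), 60), 9000))
}

#' Fit the IR signal model to one multi-TI signal
#'
#' Nonlinear least-squares fit of \eqn{S = a(1 - b e^{-TI/T1})} by
#' Levenberg--Marquardt. Starting values: `a0 = max(S)`, `b0 = 2`, and
#' `T10 = TI_min / ln 2` where `TI_min` is the inversion time of the
#' minimum-signal sample (the zero crossing of an ideal-inversion curve sits
#' at `T1 ln 2`). Bounds: `a` in (0, 10 max|S|], `b` in [1, 2.5], `T1` in
#' [50, 10000] ms. Degenerate inputs (all-zero or constant signals,
#' non-convergence) are flagged, never raised, so that map fitting can
#' proceed.
#'
#' @param signal Numeric vector of pixel values, one per inversion time.
#' @param ti_ms Strictly increasing inversion times (ms), length >= 4.
#' @return One-row tibble: `a`, `b`, `T1_ms`, `rss`, `converged`.
#' @examples
#' ti <- c(200, 500, 700, 1000, 2000, 3000, 4000)
#' fit_ir_signal(ir_signal(ti, 1, 2, 1000), ti)
#' @export
fit_ir_signal <- function(signal, ti_ms) {
  stopifnot(length(signal) == length(ti_ms), length(ti_ms) >= 4,
            all(diff(ti_ms) > 0))
  failed <- tibble::tibble(a = NA_real_, b = NA_real_, T1_ms = NA_real_,
                           rss = NA_real_, converged = FALSE)
  if (all(signal == 0) || !all(is.finite(signal))) return(failed)

  start <- ir_start(signal, ti_ms)
  bounds <- ir_bounds(max(abs(signal)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      s ~ a * (1 - b * exp(-ti / T1)),
      data = list(s = signal, ti = ti_ms),
      start = as.list(start),
      lower = bounds$lower, upper = bounds$upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  on_boundary_b <- cf[["b"]] <= bounds$lower[["b"]] + 1e-9
  tibble::tibble(a = cf[["a"]], b = cf[["b"]], T1_ms = cf[["T1"]],
                 rss = sum(stats::resid(fit)^2),
                 converged = !on_boundary_b)
}

#' Vectorised IR model fit over many signals
#'
#' Levenberg--Marquardt with the same model, start and bounds as
#' [fit_ir_signal()], run simultaneously on every row of a signal matrix.
#' The per-pixel 3x3 normal equations are assembled and solved in closed form
#' across all pixels, which makes whole-slice relaxometry tractable. Damping
#' is adapted per pixel (steps that do not reduce the residual are rejected
#' and retried with a heavier diagonal).
#'
#' @param signals Matrix, one row per pixel, one column per inversion time.
#' @param ti_ms Inversion times (ms).
#' @param max_iter Maximum LM iterations.
#' @param tol Relative RSS improvement below which a pixel is converged.
#' @return Tibble with one row per signal row: `a`, `b`, `T1_ms`, `rss`,
#'   `converged`.
#' @export
fit_ir_field <- function(signals, ti_ms, max_iter = 200, tol = 1e-14) {
  stopifnot(is.matrix(signals), ncol(signals) == length(ti_ms))
  n <- nrow(signals)
  m <- length(ti_ms)
  smax <- pmax(apply(abs(signals), 1, max), 1e-12)

  # start values (vectorised ir_start): seed T1 from the interpolated sign
  # change where one is observed, else from the minimum-signal TI
  a <- smax
  b <- rep(2, n)
  neg_cnt <- rowSums(signals < 0)
  t0e <- ti_ms[pmax(apply(signals, 1, which.min), 1)]
  has_cross <- neg_cnt > 0 & neg_cnt < m
  if (any(has_cross)) {
    i <- pmin(pmax(neg_cnt[has_cross], 1), m - 1)
    rows <- which(has_cross)
    s_lo <- signals[cbind(rows, i)]
    s_hi <- signals[cbind(rows, i + 1)]
    frac <- ifelse(s_hi != s_lo, (0 - s_lo) / (s_hi - s_lo), 0.5)
    frac <- pmin(pmax(frac, 0), 1)
    t0e[rows] <- ti_ms[i] + (ti_ms[i + 1] - ti_ms[i]) * frac
  }
  t1 <- pmin(pmax(t0e / log(2), 60), 9000)

  lo_a <- 1e-12; hi_a <- 10 * smax
  lo_b <- 1; hi_b <- 2.5
  lo_t <- 50; hi_t <- 10000

  ti_mat <- matrix(ti_ms, n, m, byrow = TRUE)
  rss_of <- function(a, b, t1) {
    e <- exp(-ti_mat / t1)
    rowSums((signals - a * (1 - b * e))^2)
  }
  rss <- rss_of(a, b, t1)
  lambda <- rep(1e-3, n)
  active <- rowSums(abs(signals)) > 0 & apply(is.finite(signals), 1, all)

  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    e <- exp(-ti_mat / t1)
    model <- a * (1 - b * e)
    r <- signals - model
    # Jacobian of the model wrt (a, b, T1)
    ja <- 1 - b * e
    jb <- -a * e
    jt <- -a * b * e * ti_mat / t1^2

    g1 <- rowSums(ja * r); g2 <- rowSums(jb * r); g3 <- rowSums(jt * r)
    h11 <- rowSums(ja * ja); h12 <- rowSums(ja * jb); h13 <- rowSums(ja * jt)
    h22 <- rowSums(jb * jb); h23 <- rowSums(jb * jt); h33 <- rowSums(jt * jt)

    improved <- rep(FALSE, n)
    trial <- active
    for (k in 1:8) {  # inner damping retries
      if (!any(trial)) break
      d11 <- h11 + lambda * pmax(h11, 1e-12)
      d22 <- h22 + lambda * pmax(h22, 1e-12)
      d33 <- h33 + lambda * pmax(h33, 1e-12)
      # closed-form solve of the damped 3x3 system via cofactors
      c11 <- d22 * d33 - h23 * h23
      c12 <- h13 * h23 - h12 * d33
      c13 <- h12 * h23 - h13 * d22
      det <- d11 * c11 + h12 * c12 + h13 * c13
      det[abs(det) < 1e-300] <- NA
      da <- (c11 * g1 + c12 * g2 + c13 * g3) / det
      db <- (c12 * g1 + (d11 * d33 - h13 * h13) * g2 +
               (h12 * h13 - d11 * h23) * g3) / det
      dt <- (c13 * g1 + (h13 * h12 - d11 * h23) * g2 +
               (d11 * d22 - h12 * h12) * g3) / det

      a_new <- pmin(pmax(a + ifelse(trial, da, 0), lo_a), hi_a)
      b_new <- pmin(pmax(b + ifelse(trial, db, 0), lo_b), hi_b)
      t_new <- pmin(pmax(t1 + ifelse(trial, dt, 0), lo_t), hi_t)
      bad <- !is.finite(a_new) | !is.finite(b_new) | !is.finite(t_new)
      a_new[bad] <- a[bad]; b_new[bad] <- b[bad]; t_new[bad] <- t1[bad]

      rss_new <- rss_of(a_new, b_new, t_new)
      acc <- trial & is.finite(rss_new) & (rss_new <= rss)
      a[acc] <- a_new[acc]; b[acc] <- b_new[acc]; t1[acc] <- t_new[acc]
      improved[acc] <- (rss[acc] - rss_new[acc]) > tol * (rss[acc] + 1e-300)
      rss[acc] <- rss_new[acc]
      lambda[acc] <- pmax(lambda[acc] / 3, 1e-12)
      rej <- trial & !acc
      lambda[rej] <- pmin(lambda[rej] * 10, 1e10)
      trial <- rej
    }
    active <- active & improved
  }

  conv <- rowSums(abs(signals)) > 0 & b > lo_b + 1e-9
  tibble::tibble(a = a, b = b, T1_ms = t1, rss = rss, converged = conv)
}

#' Zero-crossing time of a fitted IR curve
#'
#' The fitted curve \eqn{a(1 - b e^{-TI/T1})} crosses zero at
#' \eqn{T0 = T1 \ln b} (natural logarithm: solving `1 - b exp(-T0/T1) = 0`
#' forces `ln`). T0 is used to normalise T1 maps for transmit-field
#' inhomogeneity, since `b` absorbs the local inversion efficiency.
#'
#' @param T1_ms Fitted relaxation time (ms).
#' @param b Fitted inversion coefficient, must exceed 1.
#' @param log_base Base of the logarithm; the default `exp(1)` is the
#'   zero-crossing normalisation, other bases are provided for comparison
#'   runs only.
#' @return Zero-crossing time in ms.
#' @examples
#' t0_from_fit(1000, 2)  # 693.15
#' @export
t0_from_fit <- function(T1_ms, b, log_base = exp(1)) {
  if (any(b <= 1, na.rm = TRUE)) {
    stop("b must exceed 1: the IR curve has no zero crossing otherwise")
  }
  T1_ms * log(b, base = log_base)
}

#' Pixel-wise T0 mapping of an IR stack
#'
#' Fits every pixel of every slice with the IR model ([fit_ir_field()]) and
#' converts the fits to zero-crossing maps. Background pixels are masked:
#' a pixel is kept when its fit converged and its fitted amplitude exceeds
#' `mask_k` times the noise SD (estimated from the median absolute deviation
#' of the first-TI image unless supplied). Masked pixels carry `NA`.
#'
#' @param stack [simulate_ir_stack()] result (or an object with the same
#'   structure read from disk).
#' @param mask_k Amplitude threshold in units of the noise SD.
#' @param noise_sd Optional known noise SD; estimated when `NULL`.
#' @param polarity_restore Restore the sign of magnitude data by flipping
#'   samples up to the minimum-signal TI before fitting.
#' @return Object of class `t0_map`: list of arrays `t0`, `a`, `b`, `T1`
#'   (`grid x grid x n_slices`, `NA` where masked), logical array `mask`,
#'   plus `ti_list_ms` and the `layout`.
#' @export
fit_t0_map <- function(stack, mask_k = 3, noise_sd = NULL,
                       polarity_restore = stack$magnitude) {
  stopifnot(inherits(stack, "ir_stack") || is.list(stack))
  ti <- stack$ti_list_ms
  stopifnot(length(ti) >= 4)
  d <- dim(stack$images)
  grid <- d[1]; n_ti <- d[3]; n_slice <- d[4]

  shape <- function(x) array(x, dim = c(grid, grid, n_slice))
  t0_arr <- shape(NA_real_); a_arr <- shape(NA_real_)
  b_arr <- shape(NA_real_); t1_arr <- shape(NA_real_)
  mask_arr <- array(FALSE, dim = c(grid, grid, n_slice))

  for (s in seq_len(n_slice)) {
    sig <- matrix(stack$images[, , , s], nrow = grid * grid, ncol = n_ti)
    sd_hat <- if (is.null(noise_sd)) mad(stack$images[, , 1, s]) else noise_sd
    # pixels whose every sample is within the noise floor cannot pass the
    # amplitude mask; skip their fits
    candidate <- apply(abs(sig), 1, max) >= 2 * sd_hat & rowSums(abs(sig)) > 0
    sig_all <- sig
    sig <- sig[candidate, , drop = FALSE]
    if (isTRUE(polarity_restore)) {
      # the zero crossing falls between samples, so the minimum-magnitude
      # sample may lie on either side: fit both candidate restorations and
      # keep the better one per pixel
      imin <- apply(abs(sig), 1, which.min)
      sig_a <- sig; flip_a <- col(sig) <= imin; sig_a[flip_a] <- -sig_a[flip_a]
      sig_b <- sig; flip_b <- col(sig) < imin; sig_b[flip_b] <- -sig_b[flip_b]
      fit_a <- fit_ir_field(sig_a, ti)
      fit_b <- fit_ir_field(sig_b, ti)
      use_a <- !is.na(fit_a$rss) & (is.na(fit_b$rss) | fit_a$rss <= fit_b$rss)
      fits <- fit_b
      fits[use_a, ] <- fit_a[use_a, ]
      sig <- sig_b
      sig[use_a, ] <- sig_a[use_a, ]
    } else {
      fits <- fit_ir_field(sig, ti)
    }
    scale_ref <- max(abs(sig_all))
    keep_c <- fits$converged & !is.na(fits$a) &
      fits$a >= pmax(mask_k * sd_hat, 1e-6 * scale_ref)
    expand <- function(v, default = NA_real_) {
      out <- rep(default, grid * grid)
      out[candidate] <- v
      out
    }
    keep <- expand(keep_c, FALSE) > 0
    t0_arr[, , s] <- ifelse(keep, expand(fits$T1_ms) * log(expand(fits$b)),
                            NA_real_)
    a_arr[, , s] <- ifelse(keep, expand(fits$a), NA_real_)
    b_arr[, , s] <- ifelse(keep, expand(fits$b), NA_real_)
    t1_arr[, , s] <- ifelse(keep, expand(fits$T1_ms), NA_real_)
    mask_arr[, , s] <- keep
  }

  structure(list(t0 = t0_arr, a = a_arr, b = b_arr, T1 = t1_arr,
                 mask = mask_arr, ti_list_ms = ti, layout = stack$layout),
            class = "t0_map")
}

#' @export
print.t0_map <- function(x, ...) {
  d <- dim(x$t0)
  cat("<t0_map> ", d[1], "x", d[2], " px, ", d[3], " slice(s), ",
      sum(x$mask), " fitted pixels\n", sep = "")
  invisible(x)
}

roi_window <- function(center, roi_px, grid) {
  half <- floor(roi_px / 2)
  rows <- (center[1] - half):(center[1] + ceiling(roi_px / 2) - 1)
  cols <- (center[2] - half):(center[2] + ceiling(roi_px / 2) - 1)
  stopifnot(all(rows >= 1), all(rows <= grid), all(cols >= 1), all(cols <= grid))
  list(rows = rows, cols = cols)
}

#' Per-phantom T0 from a map
#'
#' Averages the unmasked T0 values in a square region of interest centred on
#' each disk (even-sized windows anchor on the top-left of the centre pixel).
#'
#' @param map [fit_t0_map()] result.
#' @param layout [phantom_layout()] of the imaged stack.
#' @param roi_px ROI side length in pixels; must fit inside the disks.
#' @return Tibble with `position`, `slice`, `t0_ms`.
#' @export
extract_phantom_t0 <- function(map, layout = map$layout, roi_px = 20) {
  stopifnot(inherits(map, "t0_map"), roi_px >= 1,
            roi_px <= floor(sqrt(2) * layout$radius_px))
  grid <- dim(map$t0)[1]
  n_slice <- dim(map$t0)[3]
  out <- tidyr::expand_grid(position = layout$centers$position,
                            slice = seq_len(n_slice))
  out$t0_ms <- purrr::pmap_dbl(out, function(position, slice) {
    ctr <- layout$centers[layout$centers$position == position, ]
    w <- roi_window(c(ctr$row, ctr$col), roi_px, grid)
    vals <- map$t0[w$rows, w$cols, slice]
    if (all(is.na(vals))) {
      stop("ROI of position ", position, ", slice ", slice, " is fully masked")
    }
    mean(vals, na.rm = TRUE)
  })
  out
}
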