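#' @keywords internal
#' @noRd
nls_ci95 <- function(fit) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  df <- stats::df.residual(fit)
  q <- qt(0.975, df)
  tibble::tibble(term = names(cf), estimate = unname(cf),
                 std_error = unname(se),
                 conf_low = unname(cf - q * se),
                 conf_high = unname(cf + q * se))
}

new_curve_fit <- function(class, coefficients, ci95, obs, pred, extra = list()) {
  m <- regression_metrics(obs, pred)
  structure(c(list(coefficients = coefficients, ci95 = ci95,
                   rmse = m$rmse, r2 = m$r2, n = m$n), extra),
            class = c(class, "t1ept_curve_fit"))
}

#' @export
print.t1ept_curve_fit <- function(x, ...) {
  cat("<", class(x)[1], "> n = ", x$n, ", RMSE = ", format(x$rmse, digits = 4),
      ", R2 = ", format(x$r2, digits = 4), "\n", sep = "")
  print(x$ci95 %||% tibble::enframe(x$coefficients, "term", "estimate"))
  invisible(x)
}

#' @method glance t1ept_curve_fit
#' @export
glance.t1ept_curve_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, r2 = x$r2, n = x$n)
}

#' @method tidy t1ept_curve_fit
#' @export
tidy.t1ept_curve_fit <- function(x, ...) {
  x$ci95 %||% tibble::enframe(x$coefficients, "term", "estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nlsLM with tight tolerances, falling back to default control when the
# post-fit model construction rejects a badly scaled but converged solution
nlslm_robust <- function(formula, data, start, lower) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) {
      minpack.lm::nlsLM(formula, data = data, start = start, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  )
}

#' Fit the Debye-type permittivity--T0 model
#'
#' Nonlinear least-squares fit of
#' \eqn{\epsilon = e_1 + (e_2 - e_1) / (1 + (c\,T0)^2)}: `e1` is the
#' long-T0 asymptote (dilute, water-like materials), `e2` the T0 -> 0 limit
#' and `1/c` the zero-crossing time at which the curve passes the midpoint
#' permittivity. 95\% confidence intervals come from the first-order
#' (Jacobian) covariance of the NLLS solution.
#'
#' @param data Tibble with columns `t0_ms` and `eps` (>= 10 rows spanning
#'   the T0 range).
#' @param start Optional named start values (`e1`, `e2`, `c`).
#' @return Object of class `permittivity_fit` with `coefficients`, `ci95`,
#'   `rmse`, `r2`, `n`; supports [predict()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_permittivity_curve <- function(data, start = NULL) {
  stopifnot(all(c("t0_ms", "eps") %in% names(data)), nrow(data) >= 10)
  if (stats::var(data$eps) == 0) {
    stop("degenerate input: permittivity is constant")
  }
  if (is.null(start)) {
    start <- list(e1 = max(data$eps), e2 = min(data$eps),
                  c = 1 / stats::median(data$t0_ms))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      eps ~ e1 + (e2 - e1) / (1 + (c * t0)^2),
      data = list(eps = data$eps, t0 = data$t0_ms),
      start = start,
      lower = c(e1 = 1, e2 = 1, c = 1e-6),
      upper = c(e1 = 120, e2 = 120, c = 1),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) stop("permittivity curve fit failed: ",
                             conditionMessage(e))
  )
  cf <- coef(fit)
  if (cf[["e1"]] <= cf[["e2"]]) {
    warning("fitted e1 <= e2: curve is increasing in T0")
  }
  new_curve_fit("permittivity_fit", cf, nls_ci95(fit),
                data$eps, stats::fitted(fit))
}

#' Predict permittivity from T0
#'
#' @param object A `permittivity_fit`.
#' @param t0_ms Zero-crossing times (ms).
#' @param ... Unused.
#' @return Predicted relative permittivity, bounded in `[e2, e1)` and
#'   strictly increasing in T0 for `e1 > e2` (longer zero crossings mean
#'   more water, hence higher permittivity).
#' @export
predict.permittivity_fit <- function(object, t0_ms, ...) {
  cf <- object$coefficients
  debye_eps(t0_ms, cf[["e1"]], cf[["e2"]], cf[["c"]])
}

#' Fit the sodium-scaled conductivity--T0 model
#'
#' Nonlinear least-squares fit of
#' \eqn{\sigma = \omega \epsilon_0 s_1 f T0 / (1 + (s_2 f T0)^2)} over
#' `(s1, s2)` at a fixed sodium fraction `f = na_pct / na_max`. The curve is
#' zero at T0 = 0, unimodal with its maximum where `s2 f T0 = 1`, and the
#' peak value is `w eps0 s1 / (2 s2)`.
#'
#' @param data Tibble with `t0_ms` and `sigma` columns sharing one sodium
#'   level.
#' @param na_pct Sodium concentration (percent) of the rows.
#' @param na_max Concentration mapped to `f = 1`.
#' @param constants [physical_constants()].
#' @return Object of class `conductivity_t0_fit`.
#' @export
fit_conductivity_t0 <- function(data, na_pct, na_max = 2.4,
                                constants = physical_constants()) {
  stopifnot(all(c("t0_ms", "sigma") %in% names(data)), na_pct >= 0)
  if (all(data$sigma == 0)) stop("all conductivities are zero")
  f <- na_pct / na_max
  we0 <- constants$w * constants$eps0
  # the curve peaks where s2 f T0 = 1, with peak value w eps0 s1 / (2 s2)
  s2_0 <- 1 / (f * data$t0_ms[which.max(data$sigma)])
  s1_0 <- 2 * s2_0 * max(data$sigma) / we0
  fit <- nlslm_robust(
    sigma ~ we0 * s1 * f * t0 / (1 + (s2 * f * t0)^2),
    data = list(sigma = data$sigma, t0 = data$t0_ms, f = f, we0 = we0),
    start = list(s1 = max(s1_0, 1e-8), s2 = max(s2_0, 1e-8)),
    lower = c(s1 = 1e-12, s2 = 1e-12)
  )
  new_curve_fit("conductivity_t0_fit", coef(fit), nls_ci95(fit),
                data$sigma, stats::fitted(fit),
                extra = list(f = f, na_pct = na_pct, na_max = na_max,
                             constants = constants))
}

#' @export
predict.conductivity_t0_fit <- function(object, t0_ms, ...) {
  cf <- object$coefficients
  we0 <- object$constants$w * object$constants$eps0
  we0 * cf[["s1"]] * object$f * t0_ms / (1 + (cf[["s2"]] * object$f * t0_ms)^2)
}

#' Fit the per-sodium-level conductivity family
#'
#' For each sodium level, fits \eqn{\sigma = s_1 T0 / (1 + (s_2 T0)^2)} to
#' the level's `(T0, sigma)` rows, then summarises how the coefficients move
#' with concentration: `s1(Na)` by a linear fit, `s2(Na)` by a quadratic.
#'
#' @param data Tibble with `t0_ms`, `sigma`, `na_pct` columns (>= 4 sodium
#'   levels, >= 3 rows each).
#' @return Object of class `sodium_family_fit`: `levels` tibble
#'   (`na_pct`, `s1`, `s2`, `rmse`, `r2`, `n`), plus `meta_s1`, `meta_s2`
#'   ([stats::lm] fits of the coefficient trends).
#' @export
fit_sodium_family <- function(data) {
  stopifnot(all(c("t0_ms", "sigma", "na_pct") %in% names(data)))
  levels <- sort(unique(data$na_pct))
  if (length(levels) < 4) stop("need at least 4 sodium levels")

  fit_one <- function(na) {
    d <- data[data$na_pct == na, ]
    if (nrow(d) < 3) stop("fewer than 3 rows for sodium level ", na)
    s2_0 <- 1 / d$t0_ms[which.max(d$sigma)]
    fit <- nlslm_robust(
      sigma ~ s1 * t0 / (1 + (s2 * t0)^2),
      data = list(sigma = d$sigma, t0 = d$t0_ms),
      start = list(s1 = max(2 * s2_0 * max(d$sigma), 1e-10), s2 = s2_0),
      lower = c(s1 = 1e-12, s2 = 1e-12)
    )
    m <- regression_metrics(d$sigma, stats::fitted(fit))
    tibble::tibble(na_pct = na, s1 = coef(fit)[["s1"]], s2 = coef(fit)[["s2"]],
                   rmse = m$rmse, r2 = m$r2, n = m$n)
  }
  lv <- dplyr::bind_rows(lapply(levels, fit_one))

  meta_s1 <- lm(s1 ~ na_pct, data = lv)
  meta_s2 <- lm(s2 ~ poly(na_pct, 2, raw = TRUE), data = lv)
  structure(list(levels = lv, meta_s1 = meta_s1, meta_s2 = meta_s2),
            class = "sodium_family_fit")
}

#' @export
print.sodium_family_fit <- function(x, ...) {
  cat("<sodium_family_fit> ", nrow(x$levels), " sodium levels\n", sep = "")
  print(x$levels)
  invisible(x)
}

#' @method tidy sodium_family_fit
#' @export
tidy.sodium_family_fit <- function(x, ...) x$levels

#' Predict conductivity from the sodium family
#'
#' Evaluates \eqn{s_1(Na) T0 / (1 + (s_2(Na) T0)^2)} with coefficients from
#' the meta-fits, so prediction works at sodium levels between the fitted
#' ones.
#'
#' @param object A `sodium_family_fit`.
#' @param t0_ms,na_pct Vectors (recycled to common length).
#' @param ... Unused.
#' @export
predict.sodium_family_fit <- function(object, t0_ms, na_pct, ...) {
  k <- vctrs_recycle2(t0_ms, na_pct)
  s1 <- predict(object$meta_s1, newdata = data.frame(na_pct = k$y))
  s2 <- pmax(predict(object$meta_s2, newdata = data.frame(na_pct = k$y)), 1e-12)
  pmax(s1 * k$x / (1 + (s2 * k$x)^2), 0)
}

vctrs_recycle2 <- function(x, y) {
  n <- max(length(x), length(y))
  list(x = rep_len(x, n), y = rep_len(y, n))
}

#' Fit semicircle conductivity--permittivity models per T0 bin
#'
#' Within bins of T0, conductivity and permittivity lie near a circular arc:
#' \eqn{\sigma = \omega\epsilon_0 \sqrt{k^2 - (\epsilon - cr)^2}\, sc}, with
#' radius `k`, centre `cr` and the sodium-fraction scale `sc`. Bins are
#' equal-count T0 quantile bins; degenerate bins (too few rows or a failed
#' fit) are skipped with a warning.
#'
#' @param data Tibble with `eps`, `sigma`, `t0_ms`.
#' @param t0_bins Number of equal-count bins.
#' @param constants [physical_constants()].
#' @return Object of class `semicircle_fit`: `bins` tibble with `t0_lo`,
#'   `t0_hi`, `t0_mid`, `k`, `cr`, `sc`, `rmse`, `r2`, `n`.
#' @export
fit_semicircle <- function(data, t0_bins = 4, constants = physical_constants()) {
  stopifnot(all(c("eps", "sigma", "t0_ms") %in% names(data)))
  br <- quantile(data$t0_ms, probs = seq(0, 1, length.out = t0_bins + 1))
  br <- unique(br)
  if (length(br) < 2) br <- br + c(-0.5, 0.5)  # constant T0: one bin
  bin <- cut(data$t0_ms, breaks = br, include.lowest = TRUE, labels = FALSE)
  we0 <- constants$w * constants$eps0

  fit_bin <- function(i) {
    d <- data[bin == i, ]
    if (nrow(d) < 5) {
      warning("T0 bin ", i, " has fewer than 5 rows; skipped")
      return(NULL)
    }
    half_span <- max(diff(range(d$eps)) / 2, 0.5)
    k0 <- half_span * 1.1
    fit <- tryCatch(
      nlslm_robust(
        sigma ~ we0 * sqrt(pmax(k^2 - (eps - cr)^2, 1e-12)) * sc,
        data = list(sigma = d$sigma, eps = d$eps, we0 = we0),
        start = list(k = k0, cr = mean(range(d$eps)),
                     sc = max(d$sigma) / (we0 * k0)),
        lower = c(k = 1e-3, cr = 0, sc = 1e-9)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warning("semicircle fit degenerate in T0 bin ", i, "; skipped")
      return(NULL)
    }
    m <- regression_metrics(d$sigma, stats::fitted(fit))
    tibble::tibble(bin = i, t0_lo = br[i], t0_hi = br[i + 1],
                   t0_mid = stats::median(d$t0_ms),
                   k = coef(fit)[["k"]], cr = coef(fit)[["cr"]],
                   sc = coef(fit)[["sc"]], rmse = m$rmse, r2 = m$r2, n = m$n)
  }
  bins <- dplyr::bind_rows(lapply(seq_len(length(br) - 1), fit_bin))
  if (nrow(bins) == 0) stop("no T0 bin could be fitted")
  structure(list(bins = bins, constants = constants), class = "semicircle_fit")
}

#' @export
print.semicircle_fit <- function(x, ...) {
  cat("<semicircle_fit> ", nrow(x$bins), " T0 bins\n", sep = "")
  print(x$bins)
  invisible(x)
}

#' @method tidy semicircle_fit
#' @export
tidy.semicircle_fit <- function(x, ...) x$bins

#' Predict conductivity from a semicircle family
#'
#' Uses the bin whose median T0 is nearest to each pixel's T0. Predictions
#' where the permittivity falls outside the fitted circle (`|eps - cr| > k`)
#' are clipped to zero and counted in the `clipped` attribute.
#'
#' @param object A `semicircle_fit`.
#' @param eps,t0_ms Vectors (recycled).
#' @param ... Unused.
#' @export
predict.semicircle_fit <- function(object, eps, t0_ms, ...) {
  k <- vctrs_recycle2(eps, t0_ms)
  bi <- vapply(k$y, function(t) which.min(abs(object$bins$t0_mid - t)), 1L)
  b <- object$bins[bi, ]
  we0 <- object$constants$w * object$constants$eps0
  inside <- abs(k$x - b$cr) <= b$k
  out <- ifelse(inside,
                we0 * sqrt(pmax(b$k^2 - (k$x - b$cr)^2, 0)) * b$sc,
                0)
  attr(out, "clipped") <- sum(!inside & !is.na(inside))
  out
}

#' Fit the single-solute concentration models
#'
#' Ordinary least squares fits of the measured dielectric properties of the
#' single-solute panels against concentration: quadratic in sucrose for both
#' properties, linear in sodium and in potassium.
#'
#' @param measurements Tibble with recipe columns (`sucrose_pct`,
#'   `sodium_pct`, `potassium_pct`) and measured `eps_meas`, `sigma_meas`
#'   (e.g. [emulate_dak()] joined to [build_cohort()]).
#' @return Tibble of class `concentration_fits`: one row per model
#'   (`model`, `response`, `solute`, `degree`, `coefficients` list-column in
#'   ascending power order, `rmse`, `r2`, `n`).
#' @export
fit_concentration_models <- function(measurements) {
  need <- c("sucrose_pct", "sodium_pct", "potassium_pct", "eps_meas", "sigma_meas")
  stopifnot(all(need %in% names(measurements)))

  single <- function(solute) {
    others <- setdiff(c("sucrose_pct", "sodium_pct", "potassium_pct"), solute)
    keep <- measurements[[others[1]]] == 0 & measurements[[others[2]]] == 0
    # water-only rows belong to the sucrose series (its zero point)
    if (solute != "sucrose_pct") keep <- keep & measurements[[solute]] > 0
    measurements[keep, ]
  }

  fit_one <- function(model, response, solute, degree) {
    d <- single(solute)
    if (nrow(d) < 6) stop("fewer than 6 rows for ", model)
    x <- d[[solute]]
    y <- d[[response]]
    fit <- lm(y ~ poly(x, degree, raw = TRUE))
    if (any(!is.finite(coef(fit)))) stop("rank-deficient design for ", model)
    m <- regression_metrics(y, stats::fitted(fit))
    tibble::tibble(model = model, response = response, solute = solute,
                   degree = degree,
                   coefficients = list(unname(coef(fit))),
                   rmse = m$rmse, r2 = m$r2, n = m$n)
  }

  out <- dplyr::bind_rows(
    fit_one("eps_sucrose", "eps_meas", "sucrose_pct", 2),
    fit_one("sigma_sucrose", "sigma_meas", "sucrose_pct", 2),
    fit_one("eps_sodium", "eps_meas", "sodium_pct", 1),
    fit_one("eps_potassium", "eps_meas", "potassium_pct", 1),
    fit_one("sigma_sodium", "sigma_meas", "sodium_pct", 1),
    fit_one("sigma_potassium", "sigma_meas", "potassium_pct", 1)
  )
  class(out) <- c("concentration_fits", class(out))
  out
}

#' Evaluate a polynomial concentration model
#'
#' @param coefficients Numeric coefficients in ascending power order
#'   (intercept first), e.g. a row of [fit_concentration_models()] or
#'   published linear-model coefficients.
#' @param x Concentration (percent).
#' @return Predicted property value.
#' @examples
#' # a linear water-sodium conductivity model, evaluated at 5% NaCl
#' concentration_predict(c(0.33, 1.48), 5)
#' @export
concentration_predict <- function(coefficients, x) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1)
  drop(outer(x, seq_along(coefficients) - 1, `^`) %*% coefficients)
}
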