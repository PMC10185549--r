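test_that("Debye-type permittivity fit recovers exact coefficients", {
  t0 <- seq(200, 1500, length.out = 40)
  eps <- 79.01 + (16.97 - 79.01) / (1 + (0.0044 * t0)^2)
  fit <- fit_permittivity_curve(tibble::tibble(t0_ms = t0, eps = eps))
  expect_equal(unname(fit$coefficients),
               c(79.01, 16.97, 0.0044), tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(fit$r2, 1)
  expect_equal(nrow(tidy(fit)), 3)
  expect_true(all(c("conf_low", "conf_high") %in% names(tidy(fit))))
  expect_error(fit_permittivity_curve(
    tibble::tibble(t0_ms = t0, eps = rep(50, 40))), "degenerate")
})

test_that("permittivity predictions respect the model limits", {
  t0 <- seq(200, 1500, length.out = 30)
  fit <- fit_permittivity_curve(tibble::tibble(
    t0_ms = t0, eps = 79.01 + (16.97 - 79.01) / (1 + (0.0044 * t0)^2)))
  expect_equal(predict(fit, 0), 16.97, tolerance = 1e-4)
  expect_equal(predict(fit, 1e9), 79.01, tolerance = 1e-4)
  expect_equal(predict(fit, 1 / 0.0044), (79.01 + 16.97) / 2, tolerance = 1e-4)

  # property: bounded in [e2, e1) and monotone increasing in T0 (longer
  # zero crossings mean more water, hence higher permittivity) for random
  # admissible coefficient sets
  set.seed(11)
  for (i in 1:25) {
    e1 <- runif(1, 60, 90); e2 <- runif(1, 5, 40); cc <- runif(1, 1e-3, 1e-2)
    f <- structure(list(coefficients = c(e1 = e1, e2 = e2, c = cc)),
                   class = c("permittivity_fit", "t1ept_curve_fit"))
    grid <- seq(0, 3000, length.out = 200)
    p <- predict(f, grid)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= e2 & p < e1))
  }
})

test_that("sodium-scaled conductivity curve behaves per its closed form", {
  k <- physical_constants()
  we0 <- k$w * k$eps0
  s1 <- 40; s2 <- 9e-4; f <- 2 / 2.4
  t0 <- seq(100, 1500, length.out = 40)
  sig <- we0 * s1 * f * t0 / (1 + (s2 * f * t0)^2)
  fit <- fit_conductivity_t0(tibble::tibble(t0_ms = t0, sigma = sig),
                             na_pct = 2)
  expect_equal(fit$coefficients[["s1"]], s1, tolerance = 1e-6)
  expect_equal(fit$coefficients[["s2"]], s2, tolerance = 1e-6)
  # zero at the origin
  expect_equal(predict(fit, 0), 0)
  # unimodal with the documented peak value at s2 f T0 = 1
  tt <- seq(1, 20000, by = 1)
  curve <- predict(fit, tt)
  expect_equal(max(curve), we0 * s1 / (2 * s2), tolerance = 1e-3)
  expect_equal(tt[which.max(curve)], 1 / (s2 * f), tolerance = 1)
  ds <- diff(curve)
  expect_equal(sum(diff(sign(ds[ds != 0])) != 0), 1)  # one sign change
  expect_error(fit_conductivity_t0(
    tibble::tibble(t0_ms = t0, sigma = 0 * t0), na_pct = 2), "zero")
})

test_that("sodium family recovers per-level coefficients and their trends", {
  na_levels <- c(0.5, 1, 1.5, 2)
  alpha <- 1.9e-3   # s1 = alpha * Na
  s2_of <- function(na) 4e-4 + 1e-4 * na + 2e-5 * na^2
  data <- purrr::map_dfr(na_levels, function(na) {
    t0 <- seq(250, 1480, length.out = 12)
    tibble::tibble(na_pct = na, t0_ms = t0,
                   sigma = (alpha * na) * t0 / (1 + (s2_of(na) * t0)^2))
  })
  fam <- fit_sodium_family(data)
  expect_equal(fam$levels$s1, alpha * na_levels, tolerance = 1e-6)
  expect_equal(unname(coef(fam$meta_s1)[2]), alpha, tolerance = 1e-6)
  expect_equal(unname(coef(fam$meta_s2)), c(4e-4, 1e-4, 2e-5), tolerance = 1e-4)
  expect_true(all(diff(fam$levels$s1) > 0))

  # higher sodium level dominates pointwise over the fitted T0 range
  t0 <- seq(300, 1400, length.out = 50)
  curves <- sapply(na_levels, function(na) predict(fam, t0, na))
  expect_true(all(apply(curves, 1, diff) > 0))

  expect_error(fit_sodium_family(data[data$na_pct < 1.4, ]), "4 sodium levels")
})

test_that("semicircle fits recover exact arcs and clip outside the circle", {
  k <- physical_constants()
  we0 <- k$w * k$eps0
  kk <- 25; cr <- 55; sc <- 0.6
  eps <- seq(32, 78, length.out = 30)
  data <- tibble::tibble(eps = eps,
                         sigma = we0 * sqrt(kk^2 - (eps - cr)^2) * sc,
                         t0_ms = 700)
  fit <- fit_semicircle(data, t0_bins = 1)
  expect_equal(fit$bins$k, kk, tolerance = 1e-6)
  expect_equal(fit$bins$cr, cr, tolerance = 1e-6)
  expect_equal(fit$bins$sc, sc, tolerance = 1e-6)
  # apex and root of the arc
  expect_equal(as.numeric(predict(fit, cr, 700)), we0 * kk * sc,
               tolerance = 1e-6)
  expect_equal(as.numeric(predict(fit, cr + kk, 700)), 0, tolerance = 1e-9)
  out <- predict(fit, cr + kk + 10, 700)
  expect_equal(as.numeric(out), 0)
  expect_equal(attr(out, "clipped"), 1L)
  expect_warning(
    expect_error(fit_semicircle(data[1:4, ], t0_bins = 1), "no T0 bin"),
    "fewer than 5")
})

test_that("concentration fits are exact on their own polynomial families", {
  na <- seq(0.25, 5, by = 0.25)
  meas <- tibble::tibble(
    sucrose_pct = 0, sodium_pct = na, potassium_pct = 0,
    eps_meas = -2.15 * na + 80.39,
    sigma_meas = 1.48 * na + 0.33
  )
  s <- seq(0, 70, length.out = 20)
  suc <- tibble::tibble(
    sucrose_pct = s, sodium_pct = 0, potassium_pct = 0,
    eps_meas = -0.0088 * s^2 + 0.169 * s + 80.09,
    sigma_meas = 4.11e-5 * s^2 + 0.000129 * s + 0.022
  )
  kk <- tibble::tibble(
    sucrose_pct = 0, sodium_pct = 0, potassium_pct = na,
    eps_meas = 0.59 * na + 80.49,
    sigma_meas = 0.52 * na + 0.13
  )
  fits <- fit_concentration_models(dplyr::bind_rows(meas, suc, kk))
  get <- function(m) fits$coefficients[[which(fits$model == m)]]
  expect_equal(get("sigma_sodium"), c(0.33, 1.48), tolerance = 1e-9)
  expect_equal(get("sigma_potassium"), c(0.13, 0.52), tolerance = 1e-9)
  expect_equal(get("eps_sodium"), c(80.39, -2.15), tolerance = 1e-9)
  expect_equal(get("eps_sucrose"), c(80.09, 0.169, -0.0088), tolerance = 1e-8)
  expect_true(all(fits$r2 > 1 - 1e-9))
})

test_that("published linear sodium model evaluates near the rounded 8 S/m", {
  pred <- concentration_predict(c(0.33, 1.48), 5)
  expect_equal(pred, 7.73)
  expect_lt(abs(pred - 8) / 8, 0.05)
})

test_that("R2 is at most 1 and reaches 1 only with zero residuals", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(30)
    noisy <- regression_metrics(y, y + rnorm(30, 0, 0.1))
    expect_lte(noisy$r2, 1)
    expect_lt(noisy$r2, 1)
  }
  expect_equal(regression_metrics(1:10, 1:10)$r2, 1)
})
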