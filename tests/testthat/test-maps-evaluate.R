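box_smooth_ref <- function(mat, k) {
  # brute-force reference for the integral-image smoother
  n <- nrow(mat); m <- ncol(mat); half <- floor((k - 1) / 2)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (is.na(mat[i, j])) next
    rs <- max(1, i - half):min(n, i + (k - 1 - half))
    cs <- max(1, j - half):min(m, j + (k - 1 - half))
    out[i, j] <- mean(mat[rs, cs], na.rm = TRUE)
  }
  out
}

test_that("mask-aware box smoothing matches a brute-force reference", {
  set.seed(8)
  mat <- matrix(rnorm(30 * 25), 30, 25)
  mat[sample(length(mat), 60)] <- NA
  expect_equal(t1ept:::box_smooth(mat, 1), mat)
  expect_equal(t1ept:::box_smooth(mat, 3), box_smooth_ref(mat, 3))
  expect_equal(t1ept:::box_smooth(mat, 5), box_smooth_ref(mat, 5))

  # uniform input is a fixed point
  u <- matrix(4.2, 12, 12)
  expect_equal(t1ept:::box_smooth(u, 3), u)

  # checkerboard interior smooths to the midpoint
  cb <- outer(1:10, 1:10, function(i, j) ifelse((i + j) %% 2 == 0, 10, 12))
  sm <- t1ept:::box_smooth(cb, 3)
  inner <- sm[2:9, 2:9]
  expect_true(all(abs(inner - 11) <= 2 / 9 + 1e-9))
  cb5 <- t1ept:::box_smooth(matrix(rep_len(c(10, 12), 121), 11, 11), 3)
  expect_true(all(abs(cb5[2:10, 2:10] - 11) < 1))
})

test_that("permittivity maps apply models pixel-wise and respect masks", {
  layout <- small_layout(3, grid = 64)
  t0 <- array(NA_real_, c(64, 64, 1))
  t0[, , 1][layout$assignment == 1] <- 400
  t0[, , 1][layout$assignment == 2] <- 900
  t0[, , 1][layout$assignment == 3] <- 1400
  tmap <- structure(list(t0 = t0, mask = !is.na(t0),
                         ti_list_ms = protocol_ti, layout = layout),
                    class = "t0_map")
  fit <- structure(list(coefficients = c(e1 = 79.01, e2 = 16.97, c = 0.0044)),
                   class = c("permittivity_fit", "t1ept_curve_fit"))
  emap <- permittivity_map(tmap, fit)
  for (k in 1:3) {
    vals <- emap$values[, , 1][layout$assignment == k]
    expect_equal(vals, rep(predict(fit, c(400, 900, 1400)[k]), length(vals)))
  }
  expect_true(all(is.na(emap$values[, , 1][layout$assignment == 0])))
  expect_equal(emap$clipped, 0L)
})

test_that("noiseless truth round-trips through imaging and mapping", {
  # phantoms on the permittivity-T0 curve, imaged without noise, mapped with
  # the true-coefficient model, must reproduce their dielectric truth
  p <- relaxation_params()
  t0_true <- c(350, 700, 1100, 1450)
  eps_true <- 79.01 + (16.97 - 79.01) / (1 + (0.0044 * t0_true)^2)
  truth <- dielectric_to_relaxation(
    tibble::tibble(id = 1:4, permittivity = eps_true, conductivity = 0.3), p)
  layout <- small_layout(4)
  stack <- simulate_ir_stack(truth, layout, noise_sd = 0, seed = 1)
  tmap <- fit_t0_map(stack, noise_sd = 0)
  fit <- structure(list(coefficients = c(e1 = 79.01, e2 = 16.97, c = 0.0044)),
                   class = c("permittivity_fit", "t1ept_curve_fit"))
  emap <- permittivity_map(tmap, fit)
  ref <- tibble::tibble(position = 1:4, value = eps_true)
  rep_out <- roi_compare(emap, layout, ref, roi_px = 5)
  expect_lt(max(rep_out$abs_pct_error), 1e-4)
})

test_that("conductivity maps smooth, clip and check alignment", {
  layout <- small_layout(2, grid = 64)
  t0 <- array(NA_real_, c(64, 64, 1))
  t0[, , 1][layout$assignment > 0] <- 800
  tmap <- structure(list(t0 = t0, mask = !is.na(t0),
                         ti_list_ms = protocol_ti, layout = layout),
                    class = "t0_map")
  emap <- structure(list(values = ifelse(is.na(t0), NA, 60), mask = !is.na(t0),
                         property = "permittivity", model_kind = "test",
                         clipped = 0L, layout = layout),
                    class = "property_map")
  # a linear model that predicts negative conductivity everywhere
  neg <- structure(list(kind = "linear",
                        model = list(coefficients = c(-5, 0, 0)),
                        features = c("eps", "t0_ms"), target = "sigma",
                        metrics = list(), folds = 5, grouped = FALSE,
                        cv = NULL), class = "ept_reg_model")
  smap <- conductivity_map(tmap, emap, neg, smooth_px = 3)
  vals <- smap$values[, , 1][layout$assignment > 0]
  expect_true(all(vals == 0))
  expect_gt(smap$clipped, 0)

  bad <- emap; bad$values <- array(60, c(32, 32, 1))
  expect_error(conductivity_map(tmap, bad, neg), "misaligned")
})

test_that("ROI comparison computes exact percent errors and summaries", {
  layout <- small_layout(2, grid = 64)
  vals <- array(NA_real_, c(64, 64, 1))
  vals[, , 1][layout$assignment == 1] <- 50
  vals[, , 1][layout$assignment == 2] <- 77
  map <- structure(list(values = vals, mask = !is.na(vals),
                        property = "permittivity", model_kind = "test",
                        clipped = 0L, layout = layout),
                   class = "property_map")
  exact <- roi_compare(map, layout,
                       tibble::tibble(position = 1:2, value = c(50, 77)))
  expect_equal(exact$pct_error, c(0, 0))
  g <- glance(exact)
  expect_equal(g$mape, 0)
  expect_equal(g$r2, 1)

  off <- roi_compare(map, layout,
                     tibble::tibble(position = 1:2, value = c(50 / 1.1, 77)))
  expect_equal(off$pct_error[1], 10, tolerance = 1e-9)

  # summary is recomputable from the per-phantom rows
  g2 <- glance(off)
  expect_equal(g2$mape, mean(abs(off$pct_error)))
  expect_equal(g2$mean_signed_error, mean(off$pct_error))
  expect_equal(g2$max_abs_error, max(abs(off$pct_error)))

  expect_error(roi_compare(map, layout,
                           tibble::tibble(position = 1:2, value = c(0, 77))),
               "percent error undefined")
})
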