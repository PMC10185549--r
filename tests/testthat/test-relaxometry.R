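# independent oracle: profile grid search over (b, T1) with the amplitude
# solved in closed form per candidate
grid_search_ir <- function(signal, ti, b_grid, t1_grid) {
  best <- list(rss = Inf)
  for (b in b_grid) for (t1 in t1_grid) {
    m <- 1 - b * exp(-ti / t1)
    a <- sum(signal * m) / sum(m^2)
    rss <- sum((signal - a * m)^2)
    if (rss < best$rss) best <- list(a = a, b = b, T1 = t1, rss = rss)
  }
  best
}

test_that("IR fitter recovers noiseless parameters exactly", {
  sig <- ir_signal(protocol_ti, 1, 2, 1000)
  fit <- fit_ir_signal(sig, protocol_ti)
  expect_true(fit$converged)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$T1_ms, 1000, tolerance = 1e-6)
})

test_that("IR fitter agrees with a grid-search oracle on a slow phantom", {
  sig <- ir_signal(protocol_ti, 1, 1.5, 3600)
  fit <- fit_ir_signal(sig, protocol_ti)
  expect_equal(fit$b, 1.5, tolerance = 1e-5)
  expect_equal(fit$T1_ms, 3600, tolerance = 1e-5 * 3600)
  oracle <- grid_search_ir(sig, protocol_ti,
                           b_grid = seq(1.4, 1.6, by = 0.002),
                           t1_grid = seq(3300, 3900, by = 5))
  expect_equal(fit$b, oracle$b, tolerance = 2e-3)
  expect_equal(fit$T1_ms, oracle$T1, tolerance = 5)
})

test_that("degenerate signals are flagged, not raised", {
  expect_false(fit_ir_signal(rep(0, 7), protocol_ti)$converged)
  const <- fit_ir_signal(rep(2, 7), protocol_ti)
  expect_true(!const$converged || const$b <= 1 + 1e-6)
  expect_error(fit_ir_signal(1:3, c(100, 200, 300)))
})

test_that("zero-crossing conversion uses the natural logarithm", {
  expect_equal(t0_from_fit(1000, 2), 1000 * log(2))
  expect_equal(t0_from_fit(1000, exp(1)), 1000)
  # a slow salt-like phantom lands in the 1400-1500 ms band
  expect_equal(t0_from_fit(3600, 1.496), 3600 * log(1.496))
  expect_true(dplyr::between(t0_from_fit(3600, 1.496), 1400, 1500))
  expect_error(t0_from_fit(1000, 1), "zero crossing")
  # base-10 comparison mode is available but not the default
  expect_equal(t0_from_fit(1000, 2, log_base = 10), 1000 * log10(2))
})

test_that("vectorised field fitter matches the single-signal fitter", {
  set.seed(42)
  pars <- tibble::tibble(a = runif(25, 0.5, 2), b = runif(25, 1.25, 2.2),
                         T1 = runif(25, 300, 4000))
  sig <- t(apply(pars, 1, function(p) {
    ir_signal(protocol_ti, p[1], p[2], p[3]) + rnorm(7, 0, 0.01)
  }))
  field <- fit_ir_field(sig, protocol_ti)
  single <- dplyr::bind_rows(
    lapply(seq_len(nrow(sig)), function(i) fit_ir_signal(sig[i, ], protocol_ti)))
  expect_equal(field$a, single$a, tolerance = 1e-4)
  expect_equal(field$b, single$b, tolerance = 1e-4)
  expect_equal(field$T1_ms, single$T1_ms, tolerance = 1e-3)
})

test_that("whole-cohort noiseless round trip recovers the ground truth", {
  truth <- cohort_relaxation(composition_to_dielectric(build_cohort()))
  sig <- t(sapply(seq_len(nrow(truth)), function(i) {
    ir_signal(protocol_ti, truth$a[i], truth$b[i], truth$T1_ms[i])
  }))
  fits <- fit_ir_field(sig, protocol_ti)
  expect_true(all(fits$converged))
  expect_equal(fits$a, truth$a, tolerance = 1e-6)
  expect_equal(fits$b, truth$b, tolerance = 1e-6)
  expect_equal(fits$T1_ms, truth$T1_ms, tolerance = 1e-6 * max(truth$T1_ms))

  # fitted T0 equals the empirical zero crossing of the fitted curve
  t0 <- fits$T1_ms * log(fits$b)
  s_at_t0 <- ir_signal(t0, fits$a, fits$b, fits$T1_ms)
  expect_true(all(abs(s_at_t0) < 1e-9 * fits$a))
})

test_that("T0 estimate is invariant to positive rescaling of the signal", {
  sig <- ir_signal(protocol_ti, 1, 1.8, 1200) + c(0.01, -0.01, 0, 0.02, 0, 0, -0.02)
  f1 <- fit_ir_signal(sig, protocol_ti)
  f2 <- fit_ir_signal(sig * 37.5, protocol_ti)
  expect_equal(f1$T1_ms * log(f1$b), f2$T1_ms * log(f2$b), tolerance = 1e-6)
  expect_equal(f2$a / f1$a, 37.5, tolerance = 1e-6)
})

test_that("T0 maps round-trip truth inside disks and mask the background", {
  layout <- small_layout(4)
  truth <- small_truth(4)
  stack <- simulate_ir_stack(truth, layout, noise_sd = 0, seed = 1)
  map <- fit_t0_map(stack, noise_sd = 0)
  asg <- layout$assignment
  for (k in 1:4) {
    vals <- map$t0[, , 1][asg == k]
    expect_true(all(abs(vals - truth$T0_ms[k]) < 1e-5 * truth$T0_ms[k]))
  }
  expect_true(all(is.na(map$t0[, , 1][asg == 0])))
  expect_true(all(!map$mask[, , 1][asg == 0]))
})

test_that("per-disk T0 scatter stays below 3% at 2% image noise", {
  layout <- small_layout(4)
  truth <- small_truth(4)
  rel_sd <- sapply(1:10, function(s) {
    stack <- simulate_ir_stack(truth, layout, noise_sd = 0.02, seed = s)
    map <- fit_t0_map(stack)
    sapply(1:4, function(k) {
      vals <- map$t0[, , 1][layout$assignment == k]
      sd(vals, na.rm = TRUE) / mean(vals, na.rm = TRUE)
    })
  })
  expect_true(all(apply(rel_sd, 1, median) < 0.03))
})

test_that("ROI extraction averages unmasked values only", {
  layout <- small_layout(2, grid = 64)
  map <- structure(list(
    t0 = array(NA_real_, c(64, 64, 1)),
    mask = array(FALSE, c(64, 64, 1)),
    ti_list_ms = protocol_ti, layout = layout), class = "t0_map")
  ctr <- layout$centers
  # uniform disk value is returned as-is
  map$t0[, , 1][layout$assignment == 1] <- 740
  # half-masked disk averages the unmasked half
  rows2 <- layout$assignment == 2
  map$t0[, , 1][rows2] <- 500
  half <- which(rows2, arr.ind = TRUE)
  top <- half[half[, 1] < ctr$row[2], ]
  for (i in seq_len(nrow(top))) map$t0[top[i, 1], top[i, 2], 1] <- NA
  out <- extract_phantom_t0(map, layout, roi_px = 5)
  expect_equal(out$t0_ms[1], 740)
  expect_equal(out$t0_ms[2], 500)

  map$t0[, , 1][rows2] <- NA
  expect_error(extract_phantom_t0(map, layout, roi_px = 5), "fully masked")
})
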