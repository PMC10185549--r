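test_that("cohort design has the documented structure", {
  cohort <- build_cohort()
  expect_equal(nrow(cohort), 140)
  expect_equal(unname(table(cohort$panel)), rep(20L, 7),
               ignore_attr = TRUE)

  n_solutes <- (cohort$sucrose_pct > 0) + (cohort$sodium_pct > 0) +
    (cohort$potassium_pct > 0)
  # the water-only phantom anchors the sucrose series
  expect_true(all(n_solutes[cohort$group == "single"] <= 1))
  expect_true(all(n_solutes[cohort$group == "double"] == 2))
  expect_true(all(n_solutes[cohort$group == "triple"] == 3))
  expect_true(all(cohort$sucrose_pct >= 0 & cohort$sucrose_pct <= 76))
  expect_true(all(cohort$sodium_pct >= 0 & cohort$sodium_pct <= 5))
  expect_true(all(cohort$potassium_pct >= 0 & cohort$potassium_pct <= 5))

  # first water-sucrose recipe is plain water
  first_a <- cohort[cohort$panel == "a", ][1, ]
  expect_equal(first_a$sodium_pct, 0)
  expect_equal(first_a$potassium_pct, 0)

  # sucrose-sodium doubles form the full 5 x 4 grid
  d <- cohort[cohort$panel == "d", ]
  expect_setequal(unique(d$sucrose_pct), c(12, 24, 36, 48, 60))
  expect_setequal(unique(d$sodium_pct), c(0.5, 1, 1.5, 2))
  expect_equal(nrow(dplyr::distinct(d, sucrose_pct, sodium_pct)), 20)
})

test_that("composition model reproduces the single-solute fits", {
  probe <- tibble::tibble(
    sucrose_pct = c(0, 70, 0, 0),
    sodium_pct = c(0, 0, 5, 0),
    potassium_pct = c(0, 0, 0, 5)
  )
  d <- composition_to_dielectric(probe)
  expect_equal(d$eps_true[1], 80.09)
  expect_equal(d$sigma_true[1], 0.022)
  # quadratic sucrose model evaluated at 70%
  expect_equal(d$eps_true[2], -0.0088 * 70^2 + 0.169 * 70 + 80.09)
  expect_equal(d$eps_true[2], 48.8, tolerance = 1e-3)
  # 5% NaCl on the deviation model (the published fit with its own
  # intercept of 0.33 would give 7.73, rounded to ~8 S/m)
  expect_equal(d$sigma_true[3], 0.022 + 1.48 * 5)
  expect_true(d$eps_true[4] <= 90)

  # loss index identity sigma = w eps0 eps''
  k <- physical_constants()
  expect_equal(d$loss_index * k$w * k$eps0, d$sigma_true, tolerance = 1e-9)
})

test_that("conductivity is nondecreasing in each salt and eps(S) is concave", {
  grid <- tidyr::expand_grid(sucrose_pct = c(0, 20, 50),
                             sodium_pct = seq(0, 5, by = 0.5),
                             potassium_pct = c(0, 1, 3))
  d <- composition_to_dielectric(grid) |>
    dplyr::arrange(sucrose_pct, potassium_pct, sodium_pct)
  by_na <- dplyr::group_by(d, sucrose_pct, potassium_pct) |>
    dplyr::summarise(mono = all(diff(sigma_true) >= 0), .groups = "drop")
  expect_true(all(by_na$mono))

  by_k <- composition_to_dielectric(
    tidyr::expand_grid(sucrose_pct = c(0, 40), sodium_pct = c(0, 2),
                       potassium_pct = seq(0, 5, by = 0.5))) |>
    dplyr::group_by(sucrose_pct, sodium_pct) |>
    dplyr::summarise(mono = all(diff(sigma_true) >= 0), .groups = "drop")
  expect_true(all(by_k$mono))

  # eps(S) is concave (negative quadratic) and lower at 70% than at 0%
  s <- seq(0, 70, length.out = 30)
  eps <- composition_to_dielectric(
    tibble::tibble(sucrose_pct = s, sodium_pct = 0, potassium_pct = 0))$eps_true
  expect_true(all(diff(diff(eps)) < 0 | abs(diff(diff(eps))) < 1e-9))
  expect_lt(eps[30], eps[1])
})

test_that("relaxation ground truth satisfies the zero-crossing identity", {
  truth <- cohort_relaxation(composition_to_dielectric(build_cohort()))
  expect_true(all(abs(truth$T0_ms - truth$T1_ms * log(truth$b)) <
                    1e-9 * truth$T0_ms))
  expect_true(all(truth$b > 1 & truth$b <= 2))
  expect_true(all(truth$T0_ms >= 200 & truth$T0_ms <= 1500))
})

test_that("salt-only phantoms sit in the high-T0 band with spread T1", {
  truth <- cohort_relaxation(composition_to_dielectric(build_cohort()))
  salt <- dplyr::filter(truth, sucrose_pct == 0,
                        sodium_pct > 0 | potassium_pct > 0)
  expect_true(all(salt$T0_ms >= 1400 & salt$T0_ms <= 1500))
  expect_true(all(salt$T1_ms >= 1500 & salt$T1_ms <= 3600))
})

test_that("dielectric_to_relaxation matches its closed-form limits", {
  p <- relaxation_params()
  # midpoint permittivity maps to T0 = 1/c
  mid <- dielectric_to_relaxation(
    tibble::tibble(permittivity = (p$e1 + p$e2) / 2, conductivity = 0), p)
  expect_equal(mid$T0_ms, 1 / p$c, tolerance = 1e-9)
  # permittivity above the admissible band clips to the T0 cap
  hi <- dielectric_to_relaxation(
    tibble::tibble(permittivity = 80.4, conductivity = 0.02), p)
  expect_equal(hi$T0_ms, 1500)
  # lossless material keeps the ideal inversion coefficient
  expect_equal(mid$b, 2)
  expect_equal(mid$T1_ms, mid$T0_ms / log(2))
})

test_that("probe emulation preserves the replicate-mean identity exactly", {
  truth <- cohort_relaxation(composition_to_dielectric(build_cohort()))
  m <- emulate_dak(truth, seed = 7)
  expect_equal(nrow(m), 560)
  agg <- m |>
    dplyr::filter(!is_mean) |>
    dplyr::group_by(id) |>
    dplyr::summarise(eps = mean(eps_meas), sigma = mean(sigma_meas),
                     .groups = "drop")
  means <- dplyr::filter(m, is_mean)
  expect_identical(agg$eps, means$eps_meas)
  expect_identical(agg$sigma, means$sigma_meas)
  expect_true(all(m$sigma_meas >= 0))
})

test_that("probe noise is zero-noise exact and two-level otherwise", {
  truth <- cohort_relaxation(composition_to_dielectric(build_cohort()))
  clean <- emulate_dak(truth, dak_noise(0, 0, 0, 0), seed = 1)
  expect_equal(dplyr::filter(clean, !is_mean)$eps_meas,
               rep(truth$eps_true, each = 3))
  expect_equal(dplyr::filter(clean, !is_mean)$sigma_meas,
               rep(truth$sigma_true, each = 3))

  # between-phantom deviation is shared: with zero within-noise the three
  # replicates coincide but phantoms still scatter
  shared <- emulate_dak(truth, dak_noise(2, 0, 0.1, 0), seed = 2) |>
    dplyr::filter(!is_mean) |>
    dplyr::group_by(id) |>
    dplyr::summarise(spread = diff(range(eps_meas)), .groups = "drop")
  expect_true(all(shared$spread == 0))

  # total scatter of replicate measurements matches the declared noise SDs
  nz <- dak_noise()
  expect_gt(nz$eps_between + nz$eps_within, 0)
  devs <- unlist(lapply(1:20, function(s) {
    m <- emulate_dak(truth, nz, seed = s)
    dplyr::filter(m, !is_mean)$eps_meas - rep(truth$eps_true, each = 3)
  }))
  expect_equal(sd(devs), sqrt(nz$eps_between^2 + nz$eps_within^2),
               tolerance = 0.05)
})
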