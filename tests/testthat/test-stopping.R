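# Stopping-power physics: threshold energies, ranges, inversions, Qeff.

test_that("printed threshold correspondences are reproduced", {
  e3 <- energy_at_let(3, "water")
  e7 <- energy_at_let(7, "water")
  expect_equal(e3, 16.8, tolerance = 0.5 / 16.8)
  expect_equal(e7, 5.8, tolerance = 0.3 / 5.8)
  expect_equal(proton_stopping_power(16.8, "water"), 3, tolerance = 0.05)
  expect_equal(proton_stopping_power(5.8, "water"), 7, tolerance = 0.05)
  # residual-range ladder at the 3/7/10/15 keV/um thresholds
  expect_equal(residual_range(e3), 3.1, tolerance = 0.10)
  expect_equal(residual_range(e7), 0.5, tolerance = 0.20)
  expect_equal(residual_range(energy_at_let(10)), 0.2, tolerance = 0.25)
  expect_lt(residual_range(energy_at_let(15)), 0.1)
})

test_that("stopping powers and ranges match an independent reference table", {
  # published tabulated values for protons in liquid water:
  # electronic mass stopping power (MeV cm2/g) and CSDA range (g/cm2)
  ref_s <- c("1" = 260.8, "10" = 45.67, "100" = 7.289)
  for (e in names(ref_s)) {
    expect_equal(proton_stopping_power(as.numeric(e), "water") * 10,
                 unname(ref_s[e]), tolerance = 0.02)
  }
  expect_equal(residual_range(10) / 10, 0.1230, tolerance = 0.02)
  expect_equal(residual_range(100) / 10, 7.718, tolerance = 0.02)
})

test_that("LET inversion round-trips and curves are monotone", {
  for (e in c(1, 5, 20, 100)) {
    expect_equal(energy_at_let(proton_stopping_power(e, "water"), "water"),
                 e, tolerance = 1e-3)
  }
  e_grid <- 10^seq(log10(0.2), log10(250), length.out = 200)
  s <- proton_stopping_power(e_grid, "water")
  expect_true(all(diff(s) < 0))  # Bragg-regime branch strictly decreasing
  r <- residual_range(e_grid)
  expect_true(all(diff(r) > 0))
  expect_equal(residual_range(0), 0)
  expect_lt(residual_range(0.05), 0.005)  # range vanishes with energy
  expect_error(energy_at_let(0.01, "water"), "branch")
  expect_error(proton_stopping_power(500, "water"), "grid")
})

test_that("range and stopping power are mutually consistent", {
  # d(range)/dE = 1/S within 2 % by central finite differences
  e <- c(1, 3, 10, 30, 79.7, 150)
  h <- e * 1e-3
  drde <- (residual_range(e + h) - residual_range(e - h)) / (2 * h)
  s_mev_mm <- proton_stopping_power(e, "water")  # 1 keV/um == 1 MeV/mm
  expect_equal(drde, 1 / s_mev_mm, tolerance = 0.02)
  # tabulated csda range equals the integral of dE/S within 1 %
  e_fine <- 10^seq(log10(0.02), log10(30), length.out = 5000)
  s_fine <- proton_stopping_power(e_fine, "water")  # MeV/mm
  integral <- sum(diff(e_fine) * (1 / s_fine[-1] + 1 / s_fine[-5000]) / 2)
  expect_equal(integral, residual_range(30), tolerance = 0.01)
})

test_that("effective-charge quality follows relativistic kinematics", {
  expect_equal(qeff(938.272), 4 / 3, tolerance = 5e-4)  # gamma = 2 limit
  e_grid <- 10^seq(0, log10(250), length.out = 100)
  expect_true(all(diff(qeff(e_grid)) < 0))
  # direct substitution into the Barkas parametrization at 1 MeV
  gamma <- 1 + 1 / 938.27208816
  beta2 <- 1 - 1 / gamma^2
  zstar2 <- (1 - exp(-125 * sqrt(beta2)))^2
  expect_equal(qeff(1), zstar2 / beta2, tolerance = 1e-12)
  expect_error(qeff(-1), "positive")
})

test_that("threshold pairs give gamma_ddk in (0,1), 0.35 for (3,7)", {
  tp <- threshold_pair(3, 7)
  expect_gt(tp$e_low, tp$e_high)          # lower LET -> higher energy
  expect_equal(tp$gamma_ddk, 0.35, tolerance = 0.02 / 0.35)
  for (pair in list(c(1, 2), c(3, 10), c(7, 15))) {
    tp <- threshold_pair(pair[1], pair[2])
    expect_true(tp$gamma_ddk > 0 && tp$gamma_ddk < 1)
  }
})

test_that("physical range in PMMA is shorter than in water", {
  for (e in c(5, 20, 79.7, 200)) {
    expect_lt(residual_range(e, "pmma"), residual_range(e, "water"))
  }
})
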