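# DDK and comparator RBE models: alpha formulas, survival, isoeffect RBE.

cell4 <- cell_line("toy", alpha_x = 0.4, beta_x = 0.1)  # abr = 4 Gy

test_that("RBEmax is 1 + f xi and matches the low-dose alpha ratio", {
  expect_equal(rbe_max(0, 2.3), 1)
  expect_equal(rbe_max(1, 0.5), 1.5)
  # alpha_single with r0 = 1 and rhat_d/abr = 1 + xi reproduces RBEmax
  xi <- 0.8; f <- 0.37
  params <- model_params("ddk_single", r0 = 1,
                         rhat_d = (1 + xi) * cell4$abr, thresholds = 7)
  expect_equal(alpha_single(f, cell4, params) / cell4$alpha_x,
               rbe_max(f, xi), tolerance = 1e-12)
})

test_that("single-threshold alpha follows the dirty-dose mixing rule", {
  params <- model_params("ddk_single", r0 = 1, rhat_d = 14, thresholds = 7)
  expect_equal(alpha_single(0, cell4, params), cell4$alpha_x)  # clean only
  # direct substitution: alpha/alpha_x = 0.5 + (14/4) * 0.5 = 2.25
  expect_equal(alpha_single(0.5, cell4, params) / cell4$alpha_x, 2.25)
  # survival at 2 Gy reproduces the LQ definition
  a <- alpha_single(0.5, cell4, params)
  expect_equal(lq_survival(2, a, cell4$beta_x),
               exp(-a * 2 - cell4$beta_x * 4))
})

test_that("dual-threshold alpha reduces and sums correctly", {
  dual <- model_params("ddk_dual", r0 = 1, rhat_1 = 2.87, rhat_2 = 13.8,
                       thresholds = c(3, 7))
  # hand sum: 1*0.6 + (2.87/4)*0.1 + (13.8/4)*0.3 = 1.70675
  expect_equal(alpha_dual(0.4, 0.3, cell4, dual) / cell4$alpha_x, 1.70675)
  expect_equal(alpha_dual(0, 0, cell4, dual), cell4$alpha_x)
  # f_low = f_high collapses to the single model with rhat_d := rhat_2
  single <- model_params("ddk_single", r0 = 1, rhat_d = 13.8, thresholds = 7)
  expect_equal(alpha_dual(0.25, 0.25, cell4, dual),
               alpha_single(0.25, cell4, single))
  expect_error(alpha_dual(0.2, 0.5, cell4, dual), "f_high")
})

test_that("xi-based formulation is self-consistent with the compartments", {
  tp <- threshold_pair(3, 7)
  g <- tp$gamma_ddk
  # direct substitution: xi = 1, R2 = 2.5 -> R1 = (2 - 2.5 g) / (1 - g)
  expect_equal(r1_from_xi(1, 2.5, 0.35), (2 - 2.5 * 0.35) / 0.65)
  # identity: 1 + xi = R1 (1 - g) + R2 g for any xi, R2
  for (xi in c(0.2, 1, 3)) {
    for (r2 in c(1, 2, 6)) {
      r1 <- r1_from_xi(xi, r2, g)
      expect_equal(r1 * (1 - g) + r2 * g, 1 + xi, tolerance = 1e-12)
    }
  }
  # uniform RBE over the stopping tail: R2 = 1 + xi gives R1 = 1 + xi
  expect_equal(r1_from_xi(0.7, 1.7, g), 1.7, tolerance = 1e-12)
  cell <- cell_line("x", 0.4, 0.1, xi = 1.2)
  # under the DDK condition (q_let = 1) with f = 1, r0 = 1: alpha = ax (1+xi)
  expect_equal(alpha_ddk_condition(1, 1, cell, tp, r2 = 2.5) / cell$alpha_x,
               1 + cell$xi, tolerance = 1e-12)
  expect_error(r1_from_xi(1, 2, 1), "degenerate")
})

test_that("linear averaged-metric alpha matches direct substitution", {
  params <- table1_params("letd_table1")
  expect_equal(alpha_linear_metric(0, cell4, params), cell4$alpha_x)
  # alpha/alpha_x = 1 + 0.478 * 2 / 4 = 1.239
  expect_equal(alpha_linear_metric(2, cell4, params) / cell4$alpha_x, 1.239)
  q <- seq(0, 20, by = 2.5)
  expect_true(all(diff(alpha_linear_metric(q, cell4, params)) > 0))
})

test_that("isoeffect RBE solves the LQ matching equation", {
  # identical radiation quality: RBE = 1 at any dose
  expect_equal(rbe(c(0.5, 2, 8), cell4$alpha_x, cell4$beta_x, cell4),
               rep(1, 3), tolerance = 1e-12)
  # low-dose limit equals alpha/alpha_x
  expect_equal(rbe(1e-6, 2 * cell4$alpha_x, cell4$beta_x, cell4),
               2, tolerance = 1e-6)
  expect_equal(rbe(0, 1.7 * cell4$alpha_x, cell4$beta_x, cell4), 1.7)
  # root-finding oracle on the isoeffect equation at finite dose
  cell <- cell_line("o", 0.2, 0.05)
  alpha <- 0.4; d <- 2
  effect <- alpha * d + cell$beta_x * d^2
  oracle <- uniroot(function(r) cell$alpha_x * r * d + cell$beta_x * r^2 * d^2 -
                      effect, c(0.1, 10), tol = 1e-12)$root
  expect_equal(rbe(d, alpha, cell$beta_x, cell), oracle, tolerance = 1e-9)
})

test_that("alpha is monotone in the dirty-dose fractions under eq-ordering", {
  params <- model_params("ddk_single", r0 = 1.1, rhat_d = 9, thresholds = 7)
  f <- seq(0, 1, by = 0.1)
  expect_true(all(diff(alpha_single(f, cell4, params)) > 0))
  dual <- model_params("ddk_dual", r0 = 1, rhat_1 = 5, rhat_2 = 12,
                       thresholds = c(3, 7))
  fh <- seq(0, 0.5, by = 0.1)
  expect_true(all(diff(alpha_dual(0.5, fh, cell4, dual)) > 0))
})

test_that("single and dual models coincide when rhat_1 is pinned to r0*abr", {
  # the dual model with R1 = R0 adds exactly nothing for the (f_low - f_high)
  # band: predictions equal the single high-threshold model's
  dual <- model_params("ddk_dual", r0 = 1, rhat_1 = cell4$abr, rhat_2 = 14,
                       thresholds = c(3, 7))
  single <- model_params("ddk_single", r0 = 1, rhat_d = 14, thresholds = 7)
  fl <- runif(20); fh <- fl * runif(20)
  expect_equal(alpha_dual(fl, fh, cell4, dual),
               alpha_single(fh, cell4, single), tolerance = 1e-12)
})

test_that("RBE-weighted profiles behave in the entry region and under uniform f", {
  q <- fix_pristine_scored()
  cell <- default_cell_a()
  rwp <- rbe_weighted_profile(q, table1_params("dd7"), cell,
                              dose_per_fraction = 2)
  entry <- rwp$rbe[q$depth_mm < 10]
  expect_true(all(abs(entry - 1) < 1e-6))  # f(7) = 0 at entry, r0 = 1
  expect_equal(attr(rwp, "assumptions")$dose_per_fraction, 2)
  # uniform f across voxels implies uniform RBE at uniform dose
  fake <- q[1:5, ]
  fake$dose <- rep(1, 5); fake$f_7 <- rep(0.3, 5)
  class(fake) <- class(q)
  rwp2 <- rbe_weighted_profile(fake, table1_params("dd7"), cell, 2,
                               normalize = 1)
  expect_equal(diff(range(rwp2$rbe)), 0, tolerance = 1e-12)
})
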