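# Global survival fitting: recovery, constraints, weighting, benchmarking.

noiseless_records <- function(truth = NULL, cells = default_cell_lines(),
                              seed = 11) {
  cfg <- jig_config(noise_sigma_lnsf = 0, cells = cells, seed = seed,
                    truth_model = truth)
  generate_jig_dataset(cfg, jig = fix_jig())
}

test_that("noiseless generate-then-refit recovers the truth exactly", {
  rec <- noiseless_records()
  fit <- fit_global(rec, "dd7", seed = 1, de_iters = 80)
  expect_equal(fit$params$rhat_d, 14, tolerance = 1e-4)
  expect_equal(fit$params$r0, 1, tolerance = 1e-4)
  expect_lt(fit$rmse_weighted, 1e-6)
})

test_that("the optimiser agrees with an unconstrained linear-algebra oracle", {
  # the objective is linear in (r0, rhat_d); with an interior-point truth the
  # constrained optimum equals the unconstrained weighted lm() solution
  truth <- model_params("ddk_single", r0 = 1.25, rhat_d = 10, thresholds = 7)
  rec <- generate_jig_dataset(jig_config(noise_sigma_lnsf = 0.15, seed = 21,
                                         truth_model = truth),
                              jig = fix_jig())
  fit <- fit_global(rec, "dd7", seed = 3, de_iters = 150)
  y <- log(rec$sf) + rec$beta_x * rec$dose^2     # = -alpha * D
  x1 <- -rec$alpha_x * (1 - rec$f_7) * rec$dose  # multiplies r0
  x2 <- -rec$beta_x * rec$f_7 * rec$dose         # multiplies rhat_d
  ols <- stats::lm(y ~ 0 + x1 + x2, weights = rec$replicates)
  expect_false(any(c(coef(ols)[1] < 1)))         # truth is interior
  expect_equal(fit$params$r0, unname(coef(ols)[1]), tolerance = 1e-4)
  expect_equal(fit$params$rhat_d, unname(coef(ols)[2]), tolerance = 1e-4)
})

test_that("photon-like data pins r0 at its lower bound of 1", {
  truth <- model_params("letd_linear", r0 = 1, t = 0)  # RBE == 1 everywhere
  rec <- generate_jig_dataset(jig_config(noise_sigma_lnsf = 0.2, seed = 31,
                                         truth_model = truth),
                              jig = fix_jig())
  fit <- fit_global(rec, "letd", seed = 2, de_iters = 80)
  expect_true("r0" %in% fit$active_bounds)
  expect_equal(fit$params$r0, 1, tolerance = 1e-5)
})

test_that("scaling all replicate counts leaves the solution unchanged", {
  rec <- generate_jig_dataset(jig_config(seed = 41), jig = fix_jig())
  rec5 <- rec
  rec5$replicates <- rec5$replicates * 5L
  f1 <- fit_global(rec, "dd7", seed = 5, de_iters = 60)
  f2 <- fit_global(rec5, "dd7", seed = 5, de_iters = 60)
  expect_identical(f1$theta, f2$theta)
})

test_that("RMSE reduces to the root mean squared residual", {
  params <- model_params("ddk_single", r0 = 1, rhat_d = 14, thresholds = 7)
  cell <- default_cell_a()
  rec <- tibble::tibble(cell_line = cell$cell_line, alpha_x = cell$alpha_x,
                        beta_x = cell$beta_x, dose = c(1, 2, 3),
                        f_7 = c(0.1, 0.2, 0.3), replicates = 1L)
  pred <- -alpha_single(rec$f_7, cell, params) * rec$dose -
    rec$beta_x * rec$dose^2
  rec$sf <- exp(pred + c(0.1, -0.2, 0.2))
  fake_fit <- structure(list(params = params, model_kind = "dd7",
                             records = rec), class = "ddk_fit")
  expect_equal(fit_rmse(fake_fit), sqrt(0.09 / 3), tolerance = 1e-12)
  rec$sf <- exp(pred)
  fake_fit$records <- rec
  expect_equal(fit_rmse(fake_fit), 0)
})

test_that("dual fit on single-high-threshold truth pins rhat_1 at its bound", {
  rec <- noiseless_records(cells = default_cell_lines()[1, ])
  fit <- fit_global(rec, "dd3_7", seed = 7, de_iters = 150)
  expect_true("rhat_1" %in% fit$active_bounds)
  expect_equal(fit$params$rhat_1, fit$params$r0 * fit$ab_min, tolerance = 1e-4)
  expect_equal(fit$params$rhat_2, 14, tolerance = 1e-3)
})

test_that("benchmarking ranks the generating model first, dd3 behind dd7", {
  rec <- generate_jig_dataset(jig_config(seed = 51), jig = fix_jig())
  bm <- benchmark_models(rec, c("dd3", "dd7", "dd10", "letd", "qeffd"),
                         seed = 2, de_iters = 60)
  expect_equal(bm$model[1], "dd7")
  r <- tibble::deframe(tibble::as_tibble(bm)[, c("model", "rmse_weighted")])
  expect_gt(r[["dd3"]], r[["dd7"]])
  bm2 <- benchmark_models(rec, c("dd3", "dd7", "dd10", "letd", "qeffd"),
                          seed = 2, de_iters = 60)
  expect_identical(tibble::as_tibble(bm)[, 1:4], tibble::as_tibble(bm2)[, 1:4])
})

test_that("data errors are reported with the offending records", {
  rec <- generate_jig_dataset(jig_config(seed = 61), jig = fix_jig())
  expect_error(fit_global(rec[0, ], "dd7"), "no survival records")
  bad <- rec
  bad$sf[3] <- -1
  expect_error(fit_global(bad, "dd7"), "record")
  expect_error(fit_global(dplyr::select(rec, -"f_7"), "dd7"), "f_7")
})
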