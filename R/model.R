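# Linear-quadratic survival and RBE under the dirty-dose kill (DDK) models
# and the averaged-metric (LETd / Qeff,d) linear comparator models.
#
# All models elevate only the LQ alpha parameter; the proton beta is set
# equal to the photon beta_x. Clean dose is photon-like up to a constant
# factor R0 >= 1; dirty-dose compartments carry per-threshold RBE parameters
# which scale inversely with the cell line's alpha_x/beta_x.

#' Define a cell line
#'
#' @param name cell line label.
#' @param alpha_x,beta_x photon-reference LQ parameters (1/Gy, 1/Gy^2), > 0.
#' @param xi optional cell-line constant: average alpha elevation of dose
#'   delivered below the low-threshold energy down to rest
#'   (`alpha_D = alpha_x (1 + xi)`).
#' @param xi_prime as `xi` but for the high threshold (`R2 = 1 + xi_prime`).
#' @return One-row tibble with the parameters and `abr = alpha_x / beta_x`.
#' @examples
#' cell_line("lung_a", alpha_x = 0.2, beta_x = 0.05)
#' @export
cell_line <- function(name, alpha_x, beta_x, xi = NA_real_, xi_prime = NA_real_) {
  stopifnot(alpha_x > 0, beta_x > 0)
  tibble::tibble(cell_line = name, alpha_x = alpha_x, beta_x = beta_x,
                 abr = alpha_x / beta_x, xi = xi, xi_prime = xi_prime)
}

MODEL_KINDS <- c("ddk_single", "ddk_dual", "letd_linear", "qeffd_linear",
                 "ddk_condition")

#' RBE-model parameters
#'
#' @param kind one of `"ddk_single"`, `"ddk_dual"`, `"letd_linear"`,
#'   `"qeffd_linear"`, `"ddk_condition"`.
#' @param r0 clean-dose (low-LET) RBE, constrained `>= 1`.
#' @param rhat_d single-threshold dirty-dose parameter (Gy);
#'   `R_D = rhat_d / (alpha_x/beta_x)`.
#' @param rhat_1,rhat_2 dual-threshold parameters (Gy).
#' @param t slope of the linear averaged-metric models (per keV/um x Gy for
#'   LETd, Gy for Qeff,d).
#' @param thresholds dirty-dose LET threshold(s) in keV/um: one value for
#'   single-threshold models, `c(low, high)` for dual/condition models.
#' @return A `ddk_params` list.
#' @seealso [table1_params()] for the fitted parameter presets.
#' @export
model_params <- function(kind, r0 = 1, rhat_d = NULL, rhat_1 = NULL,
                         rhat_2 = NULL, t = NULL, thresholds = NULL) {
  kind <- match.arg(kind, MODEL_KINDS)
  if (r0 < 1) stop("r0 is constrained to be >= 1", call. = FALSE)
  structure(list(kind = kind, r0 = r0, rhat_d = rhat_d, rhat_1 = rhat_1,
                 rhat_2 = rhat_2, t = t, thresholds = thresholds),
            class = "ddk_params")
}

#' @export
print.ddk_params <- function(x, ...) {
  vals <- c(r0 = x$r0, rhat_d = x$rhat_d, rhat_1 = x$rhat_1,
            rhat_2 = x$rhat_2, t = x$t)
  cat(sprintf("<ddk_params: %s [%s] %s>\n", x$kind,
              paste(x$thresholds, collapse = ", "),
              paste(names(vals), signif(unlist(vals), 4),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Fitted parameter presets
#'
#' Published global-fit parameters for the models benchmarked on the
#' H460/H1437 PMMA-jig survival dataset: LETd and Qeff,d linear models and
#' single/dual-threshold dirty-dose models.
#'
#' @param name one of `"letd_table1"`, `"qeffd_table1"`, `"dd3"`, `"dd7"`,
#'   `"dd10"`, `"dd3_7"`, `"dd3_10"`.
#' @return A `ddk_params` object.
#' @examples
#' table1_params("dd7")
#' @export
table1_params <- function(name = c("letd_table1", "qeffd_table1", "dd3", "dd7",
                                   "dd10", "dd3_7", "dd3_10")) {
  name <- match.arg(name)
  switch(name,
    letd_table1  = model_params("letd_linear", r0 = 1, t = 4.78e-1),
    qeffd_table1 = model_params("qeffd_linear", r0 = 1, t = 2.64e-2),
    dd3  = model_params("ddk_single", r0 = 1, rhat_d = 6.73, thresholds = 3),
    dd7  = model_params("ddk_single", r0 = 1, rhat_d = 14.0, thresholds = 7),
    dd10 = model_params("ddk_single", r0 = 1, rhat_d = 20.3, thresholds = 10),
    dd3_7  = model_params("ddk_dual", r0 = 1, rhat_1 = 2.87, rhat_2 = 13.8,
                          thresholds = c(3, 7)),
    dd3_10 = model_params("ddk_dual", r0 = 1, rhat_1 = 2.87, rhat_2 = 19.8,
                          thresholds = c(3, 10))
  )
}

#' Low-dose RBE limit of the single-threshold DDK foundation
#'
#' `RBEmax = 1 + f * xi`: in the limit of low dose the RBE of a voxel with
#' dirty-dose fraction `f` is set by the single cell-line constant `xi`.
#'
#' @param f dirty-dose fraction in `[0, 1]`.
#' @param xi cell-line constant.
#' @return RBEmax.
#' @export
rbe_max <- function(f, xi) {
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE))
  1 + f * xi
}

#' Proton alpha under the single-threshold DDK model
#'
#' `alpha = alpha_x * (R0 (1 - f) + (rhat_d / (alpha_x/beta_x)) * f)`.
#'
#' @param f dirty-dose fraction(s) in `[0, 1]`.
#' @param cell a [cell_line()] row.
#' @param params `ddk_params` with kind `"ddk_single"`.
#' @return alpha in 1/Gy.
#' @export
alpha_single <- function(f, cell, params) {
  stopifnot(params$kind == "ddk_single", all(f >= 0 & f <= 1, na.rm = TRUE))
  cell$alpha_x * (params$r0 * (1 - f) + params$rhat_d / cell$abr * f)
}

#' Proton alpha under the dual-threshold DDK model
#'
#' `alpha = alpha_x * (R0 (1 - f_low) + R1 (f_low - f_high) + R2 f_high)`
#' with `R1 = rhat_1 / abr`, `R2 = rhat_2 / abr`.
#'
#' @param f_low,f_high dirty-dose fractions at the low/high threshold,
#'   `0 <= f_high <= f_low <= 1`.
#' @inheritParams alpha_single
#' @param params `ddk_params` with kind `"ddk_dual"`.
#' @return alpha in 1/Gy.
#' @export
alpha_dual <- function(f_low, f_high, cell, params) {
  stopifnot(params$kind == "ddk_dual")
  if (any(f_high > f_low + 1e-12, na.rm = TRUE)) {
    stop("f_high cannot exceed f_low (threshold monotonicity)", call. = FALSE)
  }
  cell$alpha_x * (params$r0 * (1 - f_low) +
                    params$rhat_1 / cell$abr * (f_low - f_high) +
                    params$rhat_2 / cell$abr * f_high)
}

#' R1 implied by xi, R2 and the threshold pair
#'
#' Under the DDK condition the compartment RBEs satisfy
#' `1 + xi = R1 (1 - gamma_ddk) + R2 gamma_ddk`, giving
#' `R1 = ((1 + xi) - R2 gamma_ddk) / (1 - gamma_ddk)`.
#'
#' @param xi cell-line constant.
#' @param r2 high-threshold compartment RBE (`1 + xi_prime`).
#' @param gamma_ddk threshold-pair constant in (0, 1).
#' @return R1.
#' @export
r1_from_xi <- function(xi, r2, gamma_ddk) {
  if (any(gamma_ddk >= 1) || any(gamma_ddk <= 0)) {
    stop("gamma_ddk must lie in (0, 1): degenerate threshold pair", call. = FALSE)
  }
  ((1 + xi) - r2 * gamma_ddk) / (1 - gamma_ddk)
}

#' Proton alpha under the xi-based DDK-condition formulation
#'
#' Distributes the dirty dose between the two compartment RBEs `R1`, `R2`
#' according to the voxel's LET quality `q_let` (1 under the ideal DDK
#' condition): `alpha/alpha_x = R0 (1 - f) + R1 (1 - g q) f + R2 g q f`
#' with `g = gamma_ddk` and `R1` from [r1_from_xi()].
#'
#' @param f dirty-dose fraction(s) at the low threshold.
#' @param qlet voxel LET quality in `[0, 1/gamma_ddk]` (see [q_let()]).
#' @param cell a [cell_line()] row with `xi` set.
#' @param pair a [threshold_pair()] row.
#' @param r2 high-threshold compartment RBE.
#' @param r0 clean-dose RBE (default 1).
#' @return alpha in 1/Gy.
#' @export
alpha_ddk_condition <- function(f, qlet, cell, pair, r2, r0 = 1) {
  stopifnot(!is.na(cell$xi))
  g <- pair$gamma_ddk
  if (any(qlet < 0 | qlet > 1 / g + 1e-9, na.rm = TRUE)) {
    stop("q_let outside [0, 1/gamma_ddk]", call. = FALSE)
  }
  r1 <- r1_from_xi(cell$xi, r2, g)
  cell$alpha_x * (r0 * (1 - f) + r1 * (1 - g * qlet) * f + r2 * g * qlet * f)
}

#' Proton alpha under a linear averaged-metric model
#'
#' `alpha = alpha_x * (R0 + t * q / (alpha_x/beta_x))` where `q` is the
#' radiation quality metric (LETd or Qeff,d).
#'
#' @param q_value metric value(s), >= 0.
#' @inheritParams alpha_single
#' @param params `ddk_params` with kind `"letd_linear"` or `"qeffd_linear"`.
#' @return alpha in 1/Gy.
#' @export
alpha_linear_metric <- function(q_value, cell, params) {
  stopifnot(params$kind %in% c("letd_linear", "qeffd_linear"),
            all(q_value >= 0, na.rm = TRUE))
  cell$alpha_x * (params$r0 + params$t * q_value / cell$abr)
}

#' Linear-quadratic surviving fraction
#'
#' @param dose dose in Gy.
#' @param alpha,beta LQ parameters (1/Gy, 1/Gy^2).
#' @return `exp(-alpha * D - beta * D^2)`.
#' @export
lq_survival <- function(dose, alpha, beta) {
  stopifnot(all(dose >= 0))
  exp(-alpha * dose - beta * dose^2)
}

#' RBE at finite dose (isoeffect definition)
#'
#' Solves `alpha_x R D + beta_x R^2 D^2 = alpha D + beta D^2` for `R` (the
#' positive root), i.e. the ratio of the photon dose producing the same
#' effect to the proton dose `D`. At `D = 0` the low-dose limit
#' `alpha/alpha_x` is returned.
#'
#' @param dose proton dose in Gy (vectorised).
#' @param alpha,beta proton LQ parameters.
#' @param cell a [cell_line()] row supplying `alpha_x`, `beta_x`.
#' @return RBE.
#' @export
rbe <- function(dose, alpha, beta, cell) {
  ax <- cell$alpha_x; bx <- cell$beta_x
  effect <- alpha * dose + beta * dose^2
  out <- ifelse(dose > 0,
                (-ax + sqrt(ax^2 + 4 * bx * effect)) / (2 * bx * dose),
                alpha / ax)
  out
}

# alpha per record/voxel for any fitted model kind, from a metric table with
# columns f_<thr>, letd, qeffd
predict_alpha <- function(params, cell, metrics) {
  switch(params$kind,
    ddk_single = {
      f <- metrics[[metric_col("f", params$thresholds[1])]]
      alpha_single(f, cell, params)
    },
    ddk_dual = {
      fl <- metrics[[metric_col("f", params$thresholds[1])]]
      fh <- metrics[[metric_col("f", params$thresholds[2])]]
      alpha_dual(fl, fh, cell, params)
    },
    letd_linear = alpha_linear_metric(metrics$letd, cell, params),
    qeffd_linear = alpha_linear_metric(metrics$qeffd, cell, params),
    stop("unsupported model kind for prediction: ", params$kind, call. = FALSE)
  )
}

#' RBE-weighted depth profile
#'
#' Evaluates a model voxel-by-voxel on a quality-scored profile and returns
#' RBE and RBE-weighted dose along depth. The relative simulated dose is
#' scaled so that the reference voxel receives `dose_per_fraction` Gy.
#' Voxels with absent quality metrics (zero dose) carry `RBE = R0`.
#'
#' @param scored a `ddk_quality` table from [score_quality()].
#' @param params a `ddk_params` model.
#' @param cell a [cell_line()] row.
#' @param dose_per_fraction physical dose (Gy) at the reference voxel.
#' @param normalize `"max"` (default: peak dose voxel), `"midplane"` (centre
#'   voxel), or a voxel index.
#' @return Tibble: `voxel`, `depth_mm`, `dose_gy`, `alpha`, `rbe`,
#'   `rbe_dose_gy`; assumptions recorded in `attr(, "assumptions")`.
#' @export
rbe_weighted_profile <- function(scored, params, cell, dose_per_fraction = 2,
                                 normalize = "max") {
  stopifnot(inherits(scored, "ddk_quality"))
  ref <- if (is.numeric(normalize)) {
    normalize
  } else if (normalize == "max") {
    which.max(scored$dose)
  } else if (normalize == "midplane") {
    (nrow(scored) + 1L) %/% 2L
  } else {
    stop("unknown normalization: ", normalize, call. = FALSE)
  }
  dose_gy <- scored$dose / scored$dose[ref] * dose_per_fraction
  alpha <- predict_alpha(params, cell, scored)
  alpha[is.na(alpha)] <- cell$alpha_x * params$r0
  r <- rbe(dose_gy, alpha, cell$beta_x, cell)
  out <- tibble::tibble(voxel = scored$voxel, depth_mm = scored$depth_mm,
                        dose_gy = dose_gy, alpha = alpha, rbe = r,
                        rbe_dose_gy = r * dose_gy)
  attr(out, "assumptions") <- list(dose_per_fraction = dose_per_fraction,
                                   normalize = normalize,
                                   cell = cell, params = params)
  out
}
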