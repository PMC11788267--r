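# Synthetic PMMA-jig survival datasets with known ground truth. The
# generator reconstructs the jig geometry once (79.7 MeV pristine beam, 12
# PMMA thicknesses spanning primary-proton LETd ~0.9-21.4 keV/um, 8
# replicates per thickness, doses 0.04-9.1 Gy), computes the true LQ alpha
# per record from a chosen truth model, and samples lognormal noise on SF.

#' Default synthetic cell lines
#'
#' Two lung-carcinoma-like lines with declared photon LQ constants
#' (`alpha_x/beta_x` of 3 and 6 Gy). Synthetic stand-ins: the published jig
#' experiments never print their cell lines' photon constants.
#'
#' @return Tibble of [cell_line()] rows.
#' @export
default_cell_lines <- function() {
  dplyr::bind_rows(
    cell_line("lung_a", alpha_x = 0.50, beta_x = 0.50 / 3),
    cell_line("lung_b", alpha_x = 0.30, beta_x = 0.05)
  )
}

#' Configuration of a synthetic jig experiment
#'
#' @param beam_energy pristine beam energy (MeV), default 79.7.
#' @param n_thicknesses number of PMMA thicknesses (default 12), chosen so
#'   the reported primary-proton LETd spans `letd_range`.
#' @param replicates repetitions per thickness (default 8).
#' @param dose_levels doses in Gy; default six log-spaced levels spanning
#'   0.04-9.1 Gy.
#' @param cells tibble of [cell_line()] rows.
#' @param truth_model `ddk_params` generating the true alpha per record
#'   (default: single-threshold dirty-dose model at 7 keV/um with
#'   `rhat_d = 14` Gy, `r0 = 1`).
#' @param noise_sigma_lnsf standard deviation of the Gaussian noise on
#'   ln(SF) per individual sample (default 0.2).
#' @param letd_range achievable span of reported primary LETd (keV/um).
#' @param seed integer seed.
#' @return A `jig_config` list.
#' @export
jig_config <- function(beam_energy = 79.7, n_thicknesses = 12L,
                       replicates = 8L, dose_levels = NULL,
                       cells = default_cell_lines(), truth_model = NULL,
                       noise_sigma_lnsf = 0.2, letd_range = c(0.9, 21.4),
                       seed = 1L) {
  stopifnot(n_thicknesses >= 1, replicates >= 1)
  dose_levels <- dose_levels %||%
    exp(seq(log(0.04), log(9.1), length.out = 6))
  truth_model <- truth_model %||%
    model_params("ddk_single", r0 = 1, rhat_d = 14, thresholds = 7)
  structure(list(beam_energy = beam_energy,
                 n_thicknesses = as.integer(n_thicknesses),
                 replicates = as.integer(replicates),
                 dose_levels = dose_levels, cells = cells,
                 truth_model = truth_model,
                 noise_sigma_lnsf = noise_sigma_lnsf,
                 letd_range = letd_range, seed = as.integer(seed)),
            class = "jig_config")
}

#' Sample a surviving fraction under lognormal noise
#'
#' `SF = exp(-alpha D - beta D^2 + eps)`, `eps ~ N(0, sigma)`; always > 0,
#' exact LQ survival at `sigma = 0`.
#'
#' @param true_alpha,beta_x LQ parameters (1/Gy, 1/Gy^2).
#' @param dose dose in Gy (vectorised).
#' @param noise_sigma sd of the noise on ln SF.
#' @param seed optional integer seed.
#' @return Surviving fraction(s).
#' @export
sample_survival <- function(true_alpha, beta_x, dose, noise_sigma = 0,
                            seed = NULL) {
  stopifnot(all(dose >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(true_alpha), length(dose))
  eps <- if (noise_sigma > 0) stats::rnorm(n, 0, noise_sigma) else 0
  exp(-true_alpha * dose - beta_x * dose^2 + eps)
}

#' Generate a synthetic jig survival dataset
#'
#' Simulates the jig beam once, selects PMMA thicknesses hitting a geometric
#' grid of reported primary-proton LETd values, attaches the reconstructed
#' quality metrics, computes the true alpha per record from the truth model
#' and samples noisy surviving fractions. Reproducible by seed.
#'
#' @param config a [jig_config()].
#' @param expand if `TRUE`, return one row per individual replicate sample
#'   (`replicates = 1` each, full noise sigma); if `FALSE` (default), one
#'   row per dose-cell-LETd combination with `replicates` as recorded count
#'   and SF the geometric mean over the replicates (noise sigma scaled by
#'   `1/sqrt(replicates)`).
#' @param jig optionally a precomputed [jig_profile()] table.
#' @return Tibble of survival records (columns `cell_line`, `alpha_x`,
#'   `beta_x`, `dose`, `letd_primary_reported`, `sf`, `replicates`, attached
#'   metrics, `true_alpha`); ground truth and seed in `attr(, "truth")`.
#' @examples
#' \donttest{
#' rec <- generate_jig_dataset(jig_config(dose_levels = 2, seed = 7))
#' nrow(rec)  # 12 LETd x 2 cell lines
#' }
#' @export
generate_jig_dataset <- function(config = jig_config(), expand = FALSE,
                                 jig = NULL) {
  stopifnot(inherits(config, "jig_config"))
  jig <- jig %||% jig_profile(beam_energy = config$beam_energy)
  br <- jig_branch(jig)
  lo <- max(config$letd_range[1], min(br$let))
  hi <- min(config$letd_range[2], max(br$let))
  if (lo > hi) stop("requested LETd range not achievable by this beam",
                    call. = FALSE)
  let_grid <- exp(seq(log(lo), log(hi), length.out = config$n_thicknesses))
  grid <- tidyr::expand_grid(
    cell_line = config$cells$cell_line,
    letd_primary_reported = let_grid,
    dose = config$dose_levels
  )
  records <- dplyr::left_join(grid, config$cells, by = "cell_line")
  records <- attach_quality_metrics(records, jig)
  records$true_alpha <- predict_alpha(config$truth_model, records, records)
  records$replicates <- config$replicates
  if (expand) {
    records <- tidyr::uncount(records, weights = config$replicates)
    records$replicates <- 1L
    sigma <- config$noise_sigma_lnsf
  } else {
    sigma <- config$noise_sigma_lnsf / sqrt(config$replicates)
  }
  set.seed(config$seed)
  records$sf <- sample_survival(records$true_alpha, records$beta_x,
                                records$dose, noise_sigma = sigma)
  attr(records, "truth") <- list(model = config$truth_model,
                                 noise_sigma_lnsf = config$noise_sigma_lnsf,
                                 seed = config$seed)
  records
}

#' Full-scale emulation preset
#'
#' Reproduces the scale of the published jig dataset: 24 reported LETd
#' values across two cell lines with per-line dose ladders giving 474
#' dose-cell-LETd combinations in total (8 replicates each).
#'
#' @inheritParams generate_jig_dataset
#' @param seed integer seed.
#' @param noise_sigma_lnsf noise level on ln SF.
#' @return Tibble of 474 survival records.
#' @export
generate_full_emulation <- function(seed = 1L, noise_sigma_lnsf = 0.2,
                                    jig = NULL) {
  jig <- jig %||% jig_profile()
  cells <- default_cell_lines()
  br <- jig_branch(jig)
  let_grid <- exp(seq(log(max(0.9, min(br$let))), log(min(21.4, max(br$let))),
                      length.out = 24))
  doses_a <- exp(seq(log(0.04), log(9.1), length.out = 12))
  doses_b <- exp(seq(log(0.04), log(9.1), length.out = 8))
  grid_a <- tidyr::expand_grid(cell_line = cells$cell_line[1],
                               letd_primary_reported = let_grid,
                               dose = doses_a)                       # 288
  grid_b <- dplyr::bind_rows(
    tidyr::expand_grid(cell_line = cells$cell_line[2],
                       letd_primary_reported = let_grid[1:18],
                       dose = doses_b),                              # 144
    tidyr::expand_grid(cell_line = cells$cell_line[2],
                       letd_primary_reported = let_grid[19:24],
                       dose = doses_b[1:7])                          # 42
  )
  records <- dplyr::left_join(dplyr::bind_rows(grid_a, grid_b), cells,
                              by = "cell_line")
  records <- attach_quality_metrics(records, jig)
  truth <- model_params("ddk_single", r0 = 1, rhat_d = 14, thresholds = 7)
  records$true_alpha <- predict_alpha(truth, records, records)
  records$replicates <- 8L
  set.seed(seed)
  records$sf <- sample_survival(records$true_alpha, records$beta_x,
                                records$dose,
                                noise_sigma = noise_sigma_lnsf / sqrt(8))
  attr(records, "truth") <- list(model = truth,
                                 noise_sigma_lnsf = noise_sigma_lnsf,
                                 seed = seed)
  records
}
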