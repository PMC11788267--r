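# Proton stopping power, CSDA range and effective-charge quality for the
# media of interest (liquid water and PMMA). All LET / stopping values are
# reported at unit density (keV/um in 1.0 g/cm3 material); ranges are CSDA
# path lengths. Tables ship with the package as plain-text resources.

PROTON_MASS_MEV <- 938.27208816
ELECTRON_MASS_MEV <- 0.51099895
# switch-over and log-step grid used by the spectrum-averaging integrator
LET_INTEGRATION_E_MAX <- 16     # MeV: two-point formula above this energy
LET_INTEGRATION_E_MIN <- 0.02   # MeV: low-energy cutoff (20 keV)
LET_INTEGRATION_STEPS <- 90L    # log steps spanning the [0.02, 16] MeV window

.stopping_cache <- new.env(parent = emptyenv())

#' Proton stopping model for a medium
#'
#' Loads the embedded proton electronic stopping-power and CSDA range table
#' for a medium and returns an interpolating model. Stopping power is
#' interpolated log-log with a monotone cubic spline; the CSDA range and its
#' inverse likewise. Models are cached per medium.
#'
#' @param medium `"water"` or `"pmma"`.
#' @return An object of class `stopping_model`: a list with the tabulated
#'   grid (`table`, a tibble), the medium density (g/cm3) and interpolation
#'   functions used by [proton_stopping_power()] and friends.
#' @examples
#' m <- stopping_model("water")
#' head(m$table)
#' @export
stopping_model <- function(medium = c("water", "pmma")) {
  medium <- tolower(medium)
  medium <- match.arg(medium)
  if (!is.null(.stopping_cache[[medium]])) {
    return(.stopping_cache[[medium]])
  }
  path <- system.file("extdata", paste0("stopping_", medium, ".tsv"),
                      package = "dirtydose", mustWork = TRUE)
  header <- readLines(path, n = 2L)
  density <- as.numeric(sub(".*density = ([0-9.]+) g/cm3.*", "\\1", header[2]))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  loge <- log(tab$energy_mev)
  s_fun <- stats::splinefun(loge, log(tab$stopping_mev_cm2_g), method = "monoH.FC")
  ok <- tab$csda_g_cm2 > 0
  r_fun <- stats::splinefun(loge[ok], log(tab$csda_g_cm2[ok]), method = "monoH.FC")
  rinv_fun <- stats::splinefun(log(tab$csda_g_cm2[ok]), loge[ok], method = "monoH.FC")
  ipk <- which.max(tab$stopping_mev_cm2_g)
  model <- structure(list(
    medium = medium,
    density = density,
    table = tibble::as_tibble(tab),
    e_min = tab$energy_mev[1],
    e_max = tab$energy_mev[nrow(tab)],
    e_peak = tab$energy_mev[ipk],       # electronic stopping maximum
    s_max_branch = tab$stopping_mev_cm2_g[ipk],
    s_min_branch = tab$stopping_mev_cm2_g[nrow(tab)],
    s_fun = s_fun, r_fun = r_fun, rinv_fun = rinv_fun
  ), class = "stopping_model")
  .stopping_cache[[medium]] <- model
  model
}

#' @export
print.stopping_model <- function(x, ...) {
  cat(sprintf("<stopping_model: %s, density %.3f g/cm3, %d grid points %.3g-%.4g MeV>\n",
              x$medium, x$density, nrow(x$table), x$e_min, x$e_max))
  invisible(x)
}

as_stopping_model <- function(medium) {
  if (inherits(medium, "stopping_model")) medium else stopping_model(medium)
}

#' Proton electronic stopping power (unrestricted LET)
#'
#' @param energy Proton kinetic energy in MeV (vectorised).
#' @param medium `"water"`, `"pmma"`, or a [stopping_model()].
#' @return LET in keV/um at unit density.
#' @examples
#' proton_stopping_power(c(5.8, 16.8), "water")
#' @export
proton_stopping_power <- function(energy, medium = "water") {
  m <- as_stopping_model(medium)
  stopifnot(all(is.finite(energy)), all(energy > 0))
  if (any(energy < m$e_min | energy > m$e_max)) {
    stop(sprintf("energy outside tabulated grid [%g, %g] MeV for %s",
                 m$e_min, m$e_max, m$medium), call. = FALSE)
  }
  exp(m$s_fun(log(energy))) / 10  # MeV cm2/g at rho = 1 -> keV/um
}

# mass stopping in MeV cm2/g, no unit conversion (internal fast path)
mass_stopping <- function(energy, m) exp(m$s_fun(log(energy)))

#' Proton energy at a given LET (Bragg-regime branch)
#'
#' Inverts the stopping-power curve on its single-valued branch above the
#' electronic-stopping maximum. This is the energy a proton has when its
#' individual LET equals the dirty-dose threshold.
#'
#' @param let LET in keV/um at unit density (vectorised).
#' @inheritParams proton_stopping_power
#' @return Energy in MeV.
#' @examples
#' energy_at_let(c(3, 7), "water")
#' @export
energy_at_let <- function(let, medium = "water") {
  m <- as_stopping_model(medium)
  s_target <- let * 10
  if (any(s_target <= m$s_min_branch) || any(s_target >= m$s_max_branch)) {
    stop(sprintf(
      "LET %s keV/um outside the invertible branch (%.3g, %.3g) keV/um for %s",
      paste(signif(let, 4), collapse = ", "),
      m$s_min_branch / 10, m$s_max_branch / 10, m$medium), call. = FALSE)
  }
  vapply(s_target, function(s) {
    stats::uniroot(function(e) m$s_fun(log(e)) - log(s),
                   lower = m$e_peak, upper = m$e_max, tol = 1e-12)$root
  }, numeric(1))
}

#' CSDA residual range
#'
#' Continuous-slowing-down range of a proton, integrated from a 20 keV
#' cutoff. Returned in mm of the physical medium (for water, unit density,
#' this equals the mass range in g/cm2 times ten).
#'
#' @inheritParams proton_stopping_power
#' @param physical if `TRUE` (default) divide the unit-density range by the
#'   medium density, giving physical mm; for water the two coincide.
#' @return Range in mm; `residual_range(0, .) == 0`.
#' @examples
#' residual_range(energy_at_let(3, "water"), "water")  # ~3.1 mm
#' @export
residual_range <- function(energy, medium = "water", physical = TRUE) {
  m <- as_stopping_model(medium)
  out <- numeric(length(energy))
  pos <- energy > 0
  if (any(energy[pos] > m$e_max)) {
    stop(sprintf("energy above tabulated grid (%g MeV) for %s", m$e_max, m$medium),
         call. = FALSE)
  }
  e <- pmax(energy[pos], m$e_min)
  out[pos] <- exp(m$r_fun(log(e))) * 10  # g/cm2 -> mm at unit density
  if (physical) out <- out / m$density
  out
}

#' Proton energy with a given CSDA residual range
#'
#' Inverse of [residual_range()]; ranges at or below the table floor give 0.
#'
#' @param range_mm residual range in mm (physical mm of the medium unless
#'   `physical = FALSE`).
#' @inheritParams residual_range
#' @return Energy in MeV (0 for non-positive range).
#' @export
energy_at_range <- function(range_mm, medium = "water", physical = TRUE) {
  m <- as_stopping_model(medium)
  r <- if (physical) range_mm * m$density else range_mm
  r <- r / 10  # mm -> g/cm2 at unit density
  out <- numeric(length(r))
  r_floor <- exp(m$r_fun(log(m$e_min)))
  pos <- r > r_floor
  out[pos] <- exp(m$rinv_fun(log(r[pos])))
  out
}

#' Effective-charge radiation quality Qeff
#'
#' Qeff = z*^2 / beta^2, with the Barkas effective charge
#' z* = Z (1 - exp(-125 beta Z^(-2/3))) (Z = 1 for protons) and beta the
#' proton speed relative to light. Proportional to the number of electrons
#' emitted per track length.
#'
#' @param energy proton kinetic energy in MeV (vectorised), > 0.
#' @return Dimensionless Qeff.
#' @examples
#' qeff(938.272)  # gamma = 2: beta^2 = 3/4, z* ~ 1 -> ~4/3
#' @export
qeff <- function(energy) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("energy must be positive", call. = FALSE)
  }
  gamma <- 1 + energy / PROTON_MASS_MEV
  beta2 <- 1 - 1 / gamma^2
  zstar <- 1 - exp(-125 * sqrt(beta2))
  zstar^2 / beta2
}

#' Dirty-dose threshold pair
#'
#' Converts a low/high LET threshold pair into the corresponding proton
#' energies and the DDK-condition dirty-dose ratio
#' `Gamma_DDK = E(high LET) / E(low LET)`. Under the DDK condition (a voxel
#' fed only by protons entering at the low-threshold energy and stopping
#' inside it) the high-threshold dirty dose is exactly this fraction of the
#' low-threshold dirty dose.
#'
#' @param let_low,let_high thresholds in keV/um, `let_low < let_high`.
#' @inheritParams proton_stopping_power
#' @return A one-row tibble: `let_low`, `let_high`, `e_low`, `e_high` (MeV),
#'   `gamma_ddk`.
#' @examples
#' threshold_pair(3, 7)  # gamma_ddk ~ 0.35
#' @export
threshold_pair <- function(let_low, let_high, medium = "water") {
  stopifnot(length(let_low) == 1, length(let_high) == 1, let_low < let_high)
  e <- energy_at_let(c(let_low, let_high), medium)
  tibble::tibble(let_low = let_low, let_high = let_high,
                 e_low = e[1], e_high = e[2], gamma_ddk = e[2] / e[1])
}
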