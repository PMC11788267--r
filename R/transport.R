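# 1-D voxelised proton transport under the continuous-slowing-down
# approximation (CSDA), with Gaussian beamline energy spread and Bortfeld-type
# range straggling. Lateral charged-particle equilibrium is assumed, so a
# depth profile fully characterises the field. Every voxel traversal
# (entry/exit energy, fluence weight) is recorded; the quality-scoring layer
# consumes those records.

#' Beam configuration
#'
#' @param energy nominal initial proton kinetic energy (MeV).
#' @param energy_sigma Gaussian beamline energy spread (MeV, 1 sd).
#' @param layers tibble with columns `medium` ("water"/"pmma") and
#'   `thickness_mm`; `NULL` means a single water layer long enough to stop the
#'   beam. Thicknesses are snapped to whole voxels.
#' @param voxel_mm voxel size along depth (default 0.5 mm).
#' @param mode `"quadrature"` (deterministic Gauss-Hermite nodes over the
#'   range-spread distribution; fast and smooth) or `"mc"` (Monte Carlo
#'   sampling of the same distribution).
#' @param n_nodes quadrature order (quadrature mode).
#' @param n_histories number of sampled protons (mc mode).
#' @param straggling include range straggling (sigma_R = 0.012 R^0.935, R in
#'   cm) in the range-spread model.
#' @param nuclear if `TRUE`, apply exponential primary-fluence attenuation
#'   (1.2 %/cm in water-equivalent depth) with the lost protons' energy
#'   deposited locally. Secondary-particle transport is not modelled.
#' @param seed integer seed for mc mode.
#' @return A `beam_config` list.
#' @export
beam_config <- function(energy, energy_sigma = 0, layers = NULL,
                        voxel_mm = 0.5, mode = c("quadrature", "mc"),
                        n_nodes = 32L, n_histories = 10000L,
                        straggling = TRUE, nuclear = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(energy > 0, energy_sigma >= 0, voxel_mm > 0)
  if (!is.null(layers)) {
    stopifnot(is.data.frame(layers), all(c("medium", "thickness_mm") %in% names(layers)),
              all(layers$thickness_mm >= 0))
  }
  structure(list(energy = energy, energy_sigma = energy_sigma, layers = layers,
                 voxel_mm = voxel_mm, mode = mode, n_nodes = as.integer(n_nodes),
                 n_histories = as.integer(n_histories), straggling = straggling,
                 nuclear = nuclear, seed = as.integer(seed)),
            class = "beam_config")
}

# 1-sd of the CSDA range distribution (mm) for nominal energy in water terms
range_spread_sigma <- function(energy, energy_sigma, straggling, medium = "water") {
  m <- as_stopping_model(medium)
  r_mm <- residual_range(energy, m)
  sig2 <- 0
  if (straggling) {
    sig2 <- sig2 + (0.12 * (r_mm / 10)^0.935)^2  # Bortfeld-type, mm
  }
  if (energy_sigma > 0) {
    drde <- (residual_range(energy + 0.5, m) - residual_range(energy - 0.5, m)) / 1
    sig2 <- sig2 + (drde * energy_sigma)^2
  }
  sqrt(sig2)
}

# effective initial energies + weights realising the range-spread model
beam_spectrum <- function(config) {
  m <- stopping_model("water")
  r0 <- residual_range(config$energy, m)
  sigma <- range_spread_sigma(config$energy, config$energy_sigma, config$straggling)
  if (sigma <= 0) {
    return(list(energy = config$energy, weight = 1))
  }
  if (config$mode == "quadrature") {
    gh <- pracma::gaussHermite(config$n_nodes)
    delta <- sqrt(2) * sigma * gh$x
    w <- gh$w / sqrt(pi)
  } else {
    set.seed(config$seed)
    delta <- stats::rnorm(config$n_histories, 0, sigma)
    w <- rep(1 / config$n_histories, config$n_histories)
  }
  # truncate the spread at 6 sigma (weight < 1e-9 beyond; keeps the grid
  # margin finite for high quadrature orders)
  delta <- pmin(pmax(delta, -6 * sigma), 6 * sigma)
  r_eff <- pmax(r0 + delta, 0.05)
  list(energy = energy_at_range(r_eff, m), weight = w)
}

default_layers <- function(config) {
  m <- stopping_model("water")
  sigma <- range_spread_sigma(config$energy, config$energy_sigma, config$straggling)
  len <- residual_range(config$energy, m) + 6 * sigma + 2
  len <- ceiling(len / config$voxel_mm) * config$voxel_mm
  tibble::tibble(medium = "water", thickness_mm = len)
}

#' Simulate a pristine Bragg peak
#'
#' Transports the beam through the layer stack by CSDA stepping on the voxel
#' grid, recording every voxel traversal (entry energy E1, exit energy E2,
#' fluence weight). Deposited energy in a traversal is E1 - E2 exactly.
#'
#' @param config a [beam_config()].
#' @return A `ddk_profile`: tibble with one row per voxel (`voxel`,
#'   `depth_mm` at voxel centre, `medium`, `dose` in MeV x fluence weight per
#'   unit fluence, `track_ends`), carrying the traversal records in
#'   `attr(, "traversals")` and the configuration in `attr(, "config")`.
#' @examples
#' p <- simulate_pristine(beam_config(79.7, n_nodes = 8))
#' p[which.max(p$dose), ]
#' @export
simulate_pristine <- function(config) {
  stopifnot(inherits(config, "beam_config"))
  layers <- config$layers %||% default_layers(config)
  dz <- config$voxel_mm
  nvox_layer <- round(layers$thickness_mm / dz)
  if (any(abs(nvox_layer * dz - layers$thickness_mm) > 1e-9)) {
    layers$thickness_mm <- nvox_layer * dz
  }
  layers <- layers[nvox_layer > 0, , drop = FALSE]
  nvox_layer <- nvox_layer[nvox_layer > 0]
  spec <- beam_spectrum(config)
  n <- length(spec$energy)
  e_cur <- spec$energy
  voxel_offset <- 0L
  trav <- vector("list", length(nvox_layer))
  media <- character(0)
  for (li in seq_along(nvox_layer)) {
    m <- stopping_model(layers$medium[li])
    J <- nvox_layer[li]
    media <- c(media, rep(layers$medium[li], J))
    r_in <- ifelse(e_cur > 0, residual_range(e_cur, m), 0)      # physical mm
    d_bound <- seq(0, J) * dz
    r_mat <- outer(r_in, d_bound, "-")                          # n x (J+1)
    e_mat <- matrix(0, n, J + 1L)
    pos <- r_mat > 0 & r_in > 0
    e_mat[pos] <- energy_at_range(r_mat[pos], m)
    e_mat[, 1] <- e_cur
    e1 <- e_mat[, -(J + 1L), drop = FALSE]
    e2 <- e_mat[, -1L, drop = FALSE]
    keep <- which(e1 > 0)
    vox <- ((keep - 1L) %/% n) + 1L
    part <- ((keep - 1L) %% n) + 1L
    trav[[li]] <- tibble::tibble(
      voxel = voxel_offset + vox,
      e1 = e1[keep], e2 = e2[keep], weight = spec$weight[part]
    )
    e_cur <- e_mat[, J + 1L]
    voxel_offset <- voxel_offset + J
  }
  if (any(e_cur > 0)) {
    stop("voxel grid shorter than the maximum proton range: ",
         "extend the layer stack so all primaries stop inside it", call. = FALSE)
  }
  traversals <- dplyr::bind_rows(trav)
  if (config$nuclear) {
    # exponential primary-fluence attenuation, lost energy deposited locally
    lambda <- 0.0012  # per mm water-equivalent
    att_in <- exp(-lambda * (traversals$voxel - 1L) * dz)
    att_out <- exp(-lambda * traversals$voxel * dz)
    extra <- traversals$weight * (att_in - att_out) * (traversals$e1 + traversals$e2) / 2
    traversals$weight <- traversals$weight * att_in
    nuclear_dose <- tapply(extra, traversals$voxel, sum)
  }
  nvox <- voxel_offset
  dose <- numeric(nvox)
  dep <- tapply(traversals$weight * (traversals$e1 - traversals$e2),
                traversals$voxel, sum)
  dose[as.integer(names(dep))] <- dep
  if (config$nuclear) {
    dose[as.integer(names(nuclear_dose))] <-
      dose[as.integer(names(nuclear_dose))] + nuclear_dose
  }
  ends <- tapply(traversals$weight[traversals$e2 <= 0],
                 traversals$voxel[traversals$e2 <= 0], sum)
  track_ends <- numeric(nvox)
  track_ends[as.integer(names(ends))] <- ends
  out <- tibble::tibble(
    voxel = seq_len(nvox),
    depth_mm = (seq_len(nvox) - 0.5) * dz,
    medium = media,
    dose = dose,
    track_ends = track_ends
  )
  new_ddk_profile(out, traversals, config,
                  meta = list(kind = "pristine", energy = config$energy))
}

new_ddk_profile <- function(tbl, traversals, config, meta = list()) {
  attr(tbl, "traversals") <- traversals
  attr(tbl, "config") <- config
  attr(tbl, "meta") <- meta
  class(tbl) <- c("ddk_profile", class(tbl))
  tbl
}

#' Traversal records of a depth profile
#'
#' @param profile a `ddk_profile`.
#' @return Tibble with columns `voxel`, `e1`, `e2`, `weight`.
#' @export
traversals <- function(profile) {
  attr(profile, "traversals")
}

#' Build a spread-out Bragg peak (SOBP)
#'
#' Superposes pristine beams whose peaks span the modulation width, with
#' non-negative weights chosen by least squares so the physical-dose plateau
#' is flat. Traversal records of all components are retained (weighted), so
#' quality metrics can be scored on the combined field.
#'
#' @param max_energy energy of the deepest component (MeV).
#' @param modulation_width extent of the flat plateau (mm), must be smaller
#'   than the range of `max_energy`.
#' @param medium transport medium (default water).
#' @param voxel_mm voxel size (mm).
#' @param n_components number of pristine components across the modulation;
#'   default one per ~3 mm of modulation (at least 16), which keeps plateau
#'   ripple below the flatness tolerance.
#' @param grid_length_mm total simulated depth; default extends past the
#'   deepest range plus straggling tail.
#' @param n_nodes quadrature order per component.
#' @param flat_tol plateau max/min dose ratio above which a warning with the
#'   achieved flatness is issued (default 1.02).
#' @return A `ddk_profile` of the combined field (plateau dose normalised
#'   to 1), with component energies/weights in `attr(, "meta")`.
#' @export
build_sobp <- function(max_energy, modulation_width, medium = "water",
                       voxel_mm = 0.5, n_components = NULL,
                       grid_length_mm = NULL, n_nodes = 64L, flat_tol = 1.02) {
  m <- stopping_model(medium)
  r_max <- residual_range(max_energy, m)
  stopifnot(modulation_width > 0, modulation_width < r_max)
  n_components <- n_components %||% max(16L, ceiling(modulation_width / 3) + 1L)
  peak_depths <- seq(r_max, r_max - modulation_width, length.out = n_components)
  energies <- energy_at_range(peak_depths, m)
  sigma <- range_spread_sigma(max_energy, 0, TRUE)
  len <- grid_length_mm %||% (ceiling((r_max + 6 * sigma + 2) / voxel_mm) * voxel_mm)
  layers <- tibble::tibble(medium = m$medium, thickness_mm = len)
  comps <- lapply(energies, function(e) {
    simulate_pristine(beam_config(e, layers = layers, voxel_mm = voxel_mm,
                                  n_nodes = n_nodes))
  })
  dose_mat <- vapply(comps, function(p) p$dose, numeric(nrow(comps[[1]])))
  depth <- comps[[1]]$depth_mm
  plateau <- depth >= (r_max - modulation_width + 2) & depth <= (r_max - 2)
  w <- pracma::lsqnonneg(dose_mat[plateau, , drop = FALSE],
                         rep(1, sum(plateau)))$x
  total <- as.numeric(dose_mat %*% w)
  flat <- max(total[plateau]) / min(total[plateau])
  if (flat > flat_tol) {
    warning(sprintf("SOBP plateau flatness %.4f exceeds tolerance %.3f",
                    flat, flat_tol), call. = FALSE)
  }
  trav <- dplyr::bind_rows(lapply(seq_along(comps), function(i) {
    ti <- traversals(comps[[i]])
    ti$weight <- ti$weight * w[i]
    ti
  }))
  ends <- as.numeric(
    vapply(comps, function(p) p$track_ends, numeric(length(total))) %*% w)
  out <- tibble::tibble(voxel = comps[[1]]$voxel, depth_mm = depth,
                        medium = m$medium, dose = total, track_ends = ends)
  cfg <- beam_config(max_energy, layers = layers, voxel_mm = voxel_mm,
                     n_nodes = n_nodes)
  new_ddk_profile(out, trav, cfg,
                  meta = list(kind = "sobp", energies = energies, weights = w,
                              modulation_width = modulation_width,
                              plateau_flatness = flat, r_max = r_max))
}

#' Combine a profile with its mirror image (opposed beams)
#'
#' Adds an identical beam entering from the opposite face of the simulated
#' stack, i.e. mirrors voxel indices and sums doses/traversals. The combined
#' dose is symmetric about the mid-plane by construction.
#'
#' @param profile a `ddk_profile` whose grid spans the full phantom thickness.
#' @return A `ddk_profile` of the combined field.
#' @export
oppose_profile <- function(profile) {
  nvox <- nrow(profile)
  tr <- traversals(profile)
  tr2 <- tr
  tr2$voxel <- nvox + 1L - tr2$voxel
  out <- profile
  out$dose <- profile$dose + rev(profile$dose)
  out$track_ends <- profile$track_ends + rev(profile$track_ends)
  meta <- attr(profile, "meta")
  meta$kind <- paste0("opposed_", meta$kind)
  new_ddk_profile(tibble::as_tibble(out), dplyr::bind_rows(tr, tr2),
                  attr(profile, "config"), meta)
}

#' @export
print.ddk_profile <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<ddk_profile: %s, %d voxels x %.2g mm, peak dose at %.1f mm>\n",
              meta$kind %||% "profile", nrow(x),
              x$depth_mm[2] - x$depth_mm[1], x$depth_mm[which.max(x$dose)]))
  NextMethod()
}
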