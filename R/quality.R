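# Radiation-quality scoring from voxel traversal records: dirty/clean dose
# partition per LET threshold, dirty-dose fractions, LET-quality ratios, and
# dose-/track-averaged LET and Qeff via stopping-down-spectrum integration.
#
# Averaging follows the scheme used for treatment-planning LETd scoring: for
# protons stopping in the voxel or leaving it below 16 MeV the energy loss is
# divided into equidistant logarithmic steps (90 steps spanning 20 keV-16 MeV)
# and the stopping power or Qeff accumulated per step; above 16 MeV a
# two-point formula is used.

#' Split a voxel energy deposit into clean and dirty parts
#'
#' A proton crossing a voxel from energy `e1` down to `e2` deposits
#' `e1 - e2`. Energy deposited while the proton is below the threshold
#' energy (i.e. its LET is above the dirty-dose threshold) is dirty; the
#' remainder is clean. The split is exact: `clean + dirty == e1 - e2`.
#'
#' @param e1,e2 entry and exit energies (MeV), `e1 >= e2 >= 0` (vectorised).
#' @param e_threshold threshold energy (MeV), the energy at which the
#'   proton's LET equals the dirty-dose LET threshold (see [energy_at_let()]).
#' @return Tibble with columns `clean` and `dirty` (MeV).
#' @examples
#' partition_deposit(10, 5, 7)  # clean 3, dirty 2
#' @export
partition_deposit <- function(e1, e2, e_threshold) {
  if (any(e2 > e1) || any(e2 < 0)) {
    stop("require e1 >= e2 >= 0", call. = FALSE)
  }
  clean <- pmax(0, e1 - pmax(e2, e_threshold))
  dirty <- pmax(0, pmin(e1, e_threshold) - e2)
  tibble::tibble(clean = clean, dirty = dirty)
}

#' Dirty-dose fraction of a set of traversals
#'
#' @param trav data frame of traversals with columns `e1`, `e2`, `weight`.
#' @inheritParams partition_deposit
#' @return `f = sum(w * dirty) / sum(w * (e1 - e2))` in `[0, 1]`;
#'   `NA` if the total deposit is zero (flagged absent, not zero).
#' @export
dirty_fraction <- function(trav, e_threshold) {
  p <- partition_deposit(trav$e1, trav$e2, e_threshold)
  tot <- sum(trav$weight * (p$clean + p$dirty))
  if (tot <= 0) return(NA_real_)
  sum(trav$weight * p$dirty) / tot
}

# Decompose traversals into spectrum steps. Returns per-step energy deposit
# de, step edges (lo, hi), and owning traversal index. Steps cover
# [e2, e1] exactly (two-point part above 16 MeV, log grid below, one
# collective step below the 20 keV cutoff).
spectrum_steps <- function(e1, e2,
                           e_max = LET_INTEGRATION_E_MAX,
                           e_min = LET_INTEGRATION_E_MIN,
                           n_steps = LET_INTEGRATION_STEPS) {
  n <- length(e1)
  idx <- seq_len(n)
  out_de <- list(); out_lo <- list(); out_hi <- list(); out_id <- list()
  out_two <- list(); k <- 0L
  # two-point part above e_max
  hi <- e1 > e_max
  if (any(hi)) {
    lo_edge <- pmax(e2[hi], e_max)
    k <- k + 1L
    out_de[[k]] <- e1[hi] - lo_edge
    out_lo[[k]] <- lo_edge
    out_hi[[k]] <- e1[hi]
    out_id[[k]] <- idx[hi]
    out_two[[k]] <- TRUE
  }
  # logarithmic grid part within [e_min, e_max]
  g <- exp(seq(log(e_min), log(e_max), length.out = n_steps + 1L))
  lo <- pmax(e2, e_min)
  hi_e <- pmin(e1, e_max)
  need <- hi_e > lo
  if (any(need)) {
    m <- sum(need)
    u <- pmax(matrix(g[-(n_steps + 1L)], m, n_steps, byrow = TRUE), lo[need])
    v <- pmin(matrix(g[-1L], m, n_steps, byrow = TRUE), hi_e[need])
    de <- pmax(v - u, 0)
    pos <- de > 0
    k <- k + 1L
    out_de[[k]] <- de[pos]
    out_lo[[k]] <- u[pos]
    out_hi[[k]] <- v[pos]
    out_id[[k]] <- matrix(idx[need], m, n_steps)[pos]
    out_two[[k]] <- FALSE
  }
  # deposit below the integration cutoff, valued at the cutoff
  sub <- e2 < e_min
  if (any(sub)) {
    k <- k + 1L
    out_de[[k]] <- pmin(e1[sub], e_min) - e2[sub]
    out_lo[[k]] <- rep(e_min, sum(sub))
    out_hi[[k]] <- rep(e_min, sum(sub))
    out_id[[k]] <- idx[sub]
    out_two[[k]] <- TRUE
  }
  list(de = out_de, lo = out_lo, hi = out_hi, id = out_id, two = out_two)
}

# Average a per-proton quantity over the stopping-down spectrum.
# value: "let" (keV/um) or "qeff". weighting: dose (energy-deposit weights)
# or track (path-length weights, path = de / S).
spectrum_average <- function(trav, value = c("let", "qeff"),
                             weighting = c("dose", "track"),
                             medium = "water") {
  value <- match.arg(value)
  weighting <- match.arg(weighting)
  m <- as_stopping_model(medium)
  if (nrow(trav) == 0) return(NA_real_)
  st <- spectrum_steps(trav$e1, trav$e2)
  num <- 0; den <- 0
  val_fun <- function(e) if (value == "let") mass_stopping(e, m) / 10 else qeff(e)
  for (k in seq_along(st$de)) {
    de <- st$de[[k]]; id <- st$id[[k]]
    lo <- st$lo[[k]]; hi <- st$hi[[k]]
    if (st$two[[k]]) {              # two-point: mean of endpoint values
      v <- (val_fun(lo) + val_fun(hi)) / 2
      s <- (mass_stopping(lo, m) + mass_stopping(hi, m)) / 2
    } else {                        # per-step Simpson on the log grid
      gm <- sqrt(lo * hi)
      v <- (val_fun(lo) + 4 * val_fun(gm) + val_fun(hi)) / 6
      s <- (mass_stopping(lo, m) + 4 * mass_stopping(gm, m) +
              mass_stopping(hi, m)) / 6
    }
    w_step <- if (weighting == "dose") de else de / s
    w_tot <- trav$weight[id] * w_step
    num <- num + sum(w_tot * v)
    den <- den + sum(w_tot)
  }
  if (den <= 0) NA_real_ else num / den
}

#' Averaged LET of a traversal set
#'
#' Dose- or track(fluence)-averaged unrestricted LET over the stopping-down
#' spectrum of the traversals, evaluated with the stopping power of `medium`
#' (water by default, emulating scoring "for water" in a cell medium).
#'
#' @inheritParams dirty_fraction
#' @param weighting `"dose"` (energy-deposit weighted, LETd) or `"track"`
#'   (path-length weighted, LETt).
#' @param medium medium whose stopping power is averaged.
#' @return LET in keV/um at unit density.
#' @export
averaged_let <- function(trav, weighting = c("dose", "track"), medium = "water") {
  spectrum_average(trav, "let", weighting, medium)
}

#' Averaged Qeff of a traversal set
#'
#' As [averaged_let()] with the effective-charge quality [qeff()] in place of
#' the stopping power.
#'
#' @inheritParams averaged_let
#' @return Dimensionless Qeff,d or Qeff,t.
#' @export
averaged_qeff <- function(trav, weighting = c("dose", "track"), medium = "water") {
  spectrum_average(trav, "qeff", weighting, medium)
}

#' LET-quality ratio of a voxel
#'
#' `gamma_q = f_high / f_low`, the ratio of the dirty-dose fractions at the
#' high and low thresholds: a voxel-specific metric of how far the local LET
#' spectrum is skewed towards high LET.
#'
#' @param f_low,f_high dirty-dose fractions at the low/high threshold.
#' @return `gamma_q` in `[0, 1]`; `NA` when `f_low` is 0 or absent.
#' @export
gamma_q <- function(f_low, f_high) {
  dplyr::if_else(is.na(f_low) | is.na(f_high) | f_low <= 0,
                 NA_real_, f_high / f_low)
}

#' Voxel LET quality relative to the DDK condition
#'
#' `q_let = gamma_q / gamma_ddk`, in `[0, 1/gamma_ddk]`; equals 1 for a voxel
#' irradiated under the ideal DDK condition. Where the low-threshold dirty
#' dose is zero there is no dirty dose to redistribute and `q_let` is 0.
#'
#' @param gq `gamma_q` values (NA where absent).
#' @param gamma_ddk the threshold-pair constant, in (0, 1).
#' @return `q_let`.
#' @export
q_let <- function(gq, gamma_ddk) {
  stopifnot(gamma_ddk > 0, gamma_ddk < 1)
  dplyr::if_else(is.na(gq), 0, gq / gamma_ddk)
}

metric_col <- function(prefix, thr) paste0(prefix, "_", gsub("\\.", "p", format(thr)))

#' Score per-voxel radiation-quality metrics on a depth profile
#'
#' Computes, for every voxel of a simulated profile: total dose, dirty and
#' clean dose and dirty-dose fraction per LET threshold, dose- and
#' track-averaged LET and Qeff, and the LET-quality ratios `gamma_q` /
#' `q_let` for the given threshold pair. Zero-dose voxels carry `NA`
#' (flagged absent) quality metrics.
#'
#' @param profile a `ddk_profile` from [simulate_pristine()], [build_sobp()]
#'   or [oppose_profile()].
#' @param thresholds dirty-dose LET thresholds in keV/um (default 3, 7, 10).
#' @param pair low/high threshold pair for `gamma_q`/`q_let` (default (3, 7)).
#' @param eval_medium medium whose stopping power defines both the threshold
#'   energies and the averaged metrics (default water).
#' @return A tibble (class `ddk_quality`) with one row per voxel: profile
#'   columns plus `dd_<thr>` (dirty dose), `f_<thr>`, `letd`, `lett`,
#'   `qeffd`, `qefft`, `gamma_q`, `q_let`. The threshold pair constant is in
#'   `attr(, "pair")`.
#' @examples
#' p <- simulate_pristine(beam_config(79.7, n_nodes = 8))
#' q <- score_quality(p)
#' q[which.max(q$dose), c("depth_mm", "f_3", "f_7", "letd")]
#' @export
score_quality <- function(profile, thresholds = c(3, 7, 10), pair = c(3, 7),
                          eval_medium = "water") {
  stopifnot(inherits(profile, "ddk_profile"))
  if (!all(pair %in% thresholds)) thresholds <- sort(union(thresholds, pair))
  tr <- traversals(profile)
  e_thr <- energy_at_let(thresholds, eval_medium)
  names(e_thr) <- as.character(thresholds)
  dep <- tr$weight * (tr$e1 - tr$e2)
  vox <- tr$voxel
  dose <- tapply_full(dep, vox, nrow(profile))
  out <- tibble::as_tibble(profile)
  out$dose <- dose
  for (i in seq_along(thresholds)) {
    p <- partition_deposit(tr$e1, tr$e2, e_thr[i])
    dd <- tapply_full(tr$weight * p$dirty, vox, nrow(profile))
    out[[metric_col("dd", thresholds[i])]] <- dd
    out[[metric_col("f", thresholds[i])]] <- ifelse(dose > 0, dd / dose, NA_real_)
  }
  # spectrum averages, per voxel
  grp <- split(seq_len(nrow(tr)), vox)
  avg <- matrix(NA_real_, nrow(profile), 4,
                dimnames = list(NULL, c("letd", "lett", "qeffd", "qefft")))
  for (g in names(grp)) {
    ti <- tr[grp[[g]], ]
    v <- as.integer(g)
    avg[v, "letd"] <- spectrum_average(ti, "let", "dose", eval_medium)
    avg[v, "lett"] <- spectrum_average(ti, "let", "track", eval_medium)
    avg[v, "qeffd"] <- spectrum_average(ti, "qeff", "dose", eval_medium)
    avg[v, "qefft"] <- spectrum_average(ti, "qeff", "track", eval_medium)
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(avg))
  tp <- threshold_pair(pair[1], pair[2], eval_medium)
  f_low <- out[[metric_col("f", pair[1])]]
  f_high <- out[[metric_col("f", pair[2])]]
  out$gamma_q <- gamma_q(f_low, f_high)
  out$q_let <- q_let(out$gamma_q, tp$gamma_ddk)
  attr(out, "pair") <- tp
  attr(out, "thresholds") <- thresholds
  attr(out, "config") <- attr(profile, "config")
  attr(out, "meta") <- attr(profile, "meta")
  class(out) <- c("ddk_quality", class(out))
  out
}

tapply_full <- function(x, index, n) {
  s <- tapply(x, index, sum)
  out <- numeric(n)
  out[as.integer(names(s))] <- s
  out
}
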