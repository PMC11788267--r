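# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# pristine 79.7 MeV beam in water, scored at full fidelity
fix_pristine_scored <- function() {
  fixture("pristine_scored", function() {
    p <- simulate_pristine(beam_config(79.7, n_nodes = 32))
    score_quality(p, thresholds = c(3, 7, 10))
  })
}

# opposed 200 MeV SOBPs covering a central target of a 360 mm phantom;
# reconstruction assumptions recorded in the methods vignette
fix_opposed_scored <- function() {
  fixture("opposed_scored", function() {
    s <- build_sobp(200, 100, voxel_mm = 1, grid_length_mm = 360)
    score_quality(oppose_profile(s), thresholds = c(3, 7, 10))
  })
}

fix_jig <- function() jig_profile()  # cached inside the package

# deterministic pseudo-random traversal set for conservation properties
random_traversals <- function(n, seed = 1) {
  set.seed(seed)
  e1 <- stats::runif(n, 0.001, 250)
  e2 <- e1 * stats::runif(n)
  e2[sample.int(n, n %/% 5)] <- 0  # stopping protons
  tibble::tibble(voxel = 1L, e1 = e1, e2 = e2, weight = stats::runif(n))
}

# fine-step Riemann integration oracle for spectrum averages (independent of
# the log-step integrator): equidistant energy grid between e2 and e1, with
# the deposit below the 20 keV cutoff carried at the cutoff value (the same
# floor convention as the integrator, whose accuracy is what is under test)
riemann_average <- function(e1, e2, value = c("let", "qeff"),
                            weighting = c("dose", "track"), n_steps = 1e5) {
  value <- match.arg(value)
  weighting <- match.arg(weighting)
  cutoff <- 0.02
  lo <- max(e2, cutoff)
  e <- seq(lo, e1, length.out = n_steps + 1)
  emid <- (e[-1] + e[-length(e)]) / 2
  de <- diff(e)
  s_let <- proton_stopping_power(emid, "water")      # keV/um
  v <- if (value == "let") s_let else qeff(emid)
  w <- if (weighting == "dose") de else de / s_let
  num <- sum(w * v); den <- sum(w)
  if (e2 < cutoff) {
    de0 <- min(e1, cutoff) - e2
    s0 <- proton_stopping_power(cutoff, "water")
    v0 <- if (value == "let") s0 else qeff(cutoff)
    w0 <- if (weighting == "dose") de0 else de0 / s0
    num <- num + w0 * v0; den <- den + w0
  }
  num / den
}

default_cell_a <- function() default_cell_lines()[1, ]
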