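# dirtydose

Variable proton RBE modelling based on the **dirty dose** concept, for
radiotherapy physicists and radiobiology modellers.

Clinical proton plans assume a constant relative biological effectiveness
(RBE) of 1.1, but in-vitro survival data show the RBE climbing near the end
of the proton range where LET rises steeply. Instead of averaging LET over
the local particle spectrum, the dirty-dose approach classifies every energy
deposit by the LET of the *individual* proton at the moment of deposition:
dose deposited above a threshold `LET_DD` is "dirty" (`D_D`), the rest is
"clean" (`D_C`), and `D = D_D + D_C` holds exactly per voxel. Since a
proton's LET is a function of its kinetic energy alone, the classification
reduces to comparing deposit energies with one threshold energy (16.8 MeV
for 3 keV/μm, 5.8 MeV for 7 keV/μm in water).

The survival model is linear-quadratic with all RBE elevation in α
(proton β = photon β_x). For the single-threshold dirty-dose-kill (DDK)
model with dirty-dose fraction `f = D_D/D`:

    ln S = -α_x [ R0 (1 - f) + R̂_D f / (α_x/β_x) ] D  -  β_x D²

with `R0 ≥ 1` the clean-dose RBE and `R̂_D` (Gy) the free parameter, shared
across cell lines via the inverse α_x/β_x scaling. A dual-threshold variant
(`R̂_1`, `R̂_2` with the ordering `1 ≤ R0 ≤ R̂_1/(α/β) ≤ R̂_2/(α/β)`) and
linear comparator models in dose-averaged LET or Qeff,d
(`R0 + t q/(α_x/β_x)`) are included, as are the low-dose identities
`RBE_max = 1 + f ξ` and the Γ_DDK / Q_LET machinery of the ξ-based
formulation.

The package provides, end to end:

- embedded Bethe-based proton stopping-power/range tables for water and
  PMMA (plain text, no downloads);
- a 1-D voxelised CSDA transport simulator (pristine beams, SOBPs, opposed
  fields) with range straggling, recording every voxel traversal;
- per-voxel scoring of dirty/clean dose, dirty-dose fractions, dose- and
  track-averaged LET and Qeff via stopping-down-spectrum integration;
- the DDK / LETd / Qeff,d survival and RBE models with the published fitted
  parameters as presets;
- replicate-weighted constrained global fitting (differential evolution)
  and RMSE benchmarking of model families;
- a synthetic generator emulating the PMMA-jig clonogenic experiments
  (12 thicknesses × 8 replicates, LETd 0.9–21.4 keV/μm, doses 0.04–9.1 Gy)
  with known ground truth;
- tidyverse-native interfaces: tibbles in and out, `tidy()`/`glance()` on
  fits, `autoplot()` on profiles and benchmarks, plus a thin command-line
  wrapper (`inst/cli/ddk.R`).

## A worked example

```r
library(dirtydose)

threshold_pair(3, 7, "water")
#>   let_low let_high e_low e_high gamma_ddk
#> 1       3        7  16.8   5.87     0.350

# the jig beam: 79.7 MeV pristine protons, 0.5 mm voxels
p <- simulate_pristine(beam_config(79.7))
q <- score_quality(p, thresholds = c(3, 7, 10))
q[which.max(q$dose), c("depth_mm", "dose", "f_3", "f_7", "letd", "qeffd")]
#>   depth_mm  dose   f_3   f_7  letd qeffd
#> 1     51.2  3.01 1.000 0.565  10.5  185.

# synthetic jig experiment (truth: dd7 model, R̂_D = 14 Gy) and a global fit
rec <- generate_jig_dataset(jig_config(seed = 1))
fit <- fit_global(rec, "dd7", seed = 1)
fit
#> <ddk_fit: dd7, n = 144, RMSE(lnSF) = 0.0621 (weighted)>
#> <ddk_params: ddk_single [7] r0=1.001 rhat_d=14.02>

benchmark_models(rec, c("dd3", "dd7", "letd", "qeffd"), seed = 1)[, 1:3]
#>   model rmse_weighted rmse_unweighted
#> 1 dd7          0.0621          0.0621
#> 2 qeffd        0.399           0.399
#> 3 letd         0.525           0.525
#> 4 dd3          1.36            1.36
```

The first block reproduces the threshold physics: at 3 and 7 keV/μm the
corresponding proton energies in water are 16.8 and 5.9 MeV, so the
DDK-condition constant is Γ_DDK = 5.87/16.76 ≈ 0.35. The peak-voxel row
shows the low-threshold dirty-dose fraction already saturated at 1 while
f(7 keV/μm) is not. The fit recovers the generating parameters
(R̂_D = 14.02 Gy vs truth 14, R0 at its bound of 1), and the benchmark
reproduces the qualitative finding that a 3 keV/μm threshold performs far
worse than 7 keV/μm — its dirty-dose fraction saturates too early in the
distal edge — while averaged-metric models sit in between on
dd7-generated data.

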