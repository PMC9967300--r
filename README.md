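# sqdimer

Trajectory analysis of excitonically coupled squaraine (SQ) dye dimers
templated on DNA Holliday junctions.

DNA-templated dye aggregates are a route to engineered exciton
delocalization: two dyes held face-to-face by a DNA scaffold couple through
their optical transition dipoles, and the strength and sign of that coupling
is fixed by the dimer geometry. `sqdimer` takes multi-frame all-atom
coordinates of a two-dye/DNA system (multi-model PDB, GRO, XYZ, or a reader
plug-in) and computes, per frame and as ensemble summaries:

- **Exciton hopping parameter `J_mn`** in the extended dipole approximation.
  Each transition dipole is replaced by opposite point charges at the ends
  of the dye's π-conjugation bridge (the terminal benzene ring centers
  `r_i`, `s_i`), and the four Coulomb terms are summed:

  `J_mn = J_o (1/|r1−r2| − 1/|r1−s2| − 1/|s1−r2| + 1/|s1−s2|)`,
  `J_o = μ_m μ_n / (4π ε0 n² l_m l_n)`

  with `l_i = |r_i − s_i|` the bridge lengths and `n` the medium's
  refractive index. A point-dipole reference (`point_dipole_coupling()`)
  provides the `l/R → 0` cross-check.
- **Dimer orientation metrics**: center distance `R` (between the
  squarate-carbon centers of mass), oblique angle `α = arccos(μ̂_m·μ̂_n)`,
  slip angles `θ_i = arccos(R̂·μ̂_i)`, orientation factor
  `κ² = (μ̂_m·μ̂_n − 3(μ̂_m·R̂)(μ̂_n·R̂))²` (≈1 face-to-face H-aggregate,
  ≈4 head-to-tail J-aggregate), and the packing factor `κ′ = μ̂_m·μ̂_n`
  whose sign diagnoses parallel (AA) vs antiparallel (AB) stacking.
- **Residue contact maps**: the fraction of frames in which two residues'
  centers of mass lie within a cutoff (default 1.2 nm, the nonbonded
  electrostatic cutoff of typical production MD).
- **Ensemble summaries** two ways: time-series mean ± sd over frames, and
  greedy **GROMOS clustering** of frames (RMSD cutoff 0.05 nm over the dye
  atoms, clusters below 5% of frames discarded as transition states) with
  metrics evaluated on each cluster's average geometry.

Because production MD trajectories of these systems are rarely shareable,
the package ships a **synthetic trajectory generator**
(`generate_dimer_trajectory()`, `generate_mock_hj()`) that emulates a
fluctuating H-aggregate dimer on a mock four-arm junction with known ground
truth, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(sqdimer)

cfg <- generator_config(n_frames = 2000, seed = 42)   # AA-packed H-aggregate,
sim <- generate_dimer_trajectory(cfg)                 # mean R 0.6 nm, sd 0.1 nm

geom <- dimer_geometry(sim$trajectory, sim$selections)
cpl  <- coupling_series(sim$trajectory, sim$selections)
summarize_time_series(geom, cpl)
#> # A tibble: 7 × 4
#>   method      metric         mean       sd
#>   <chr>       <chr>         <dbl>    <dbl>
#> 1 time_series R             0.598   0.102
#> 2 time_series alpha         9.56    6.33
#> 3 time_series theta_m      43.1    41.3
#> 4 time_series theta_n      45.3    41.4
#> 5 time_series kappa_sq      0.961   0.0562
#> 6 time_series kappa_prime   0.980   0.0257
#> 7 time_series J_mn        535.    173.
```

The recovered mean separation (0.598 nm) matches the generator's 0.6 nm
target; `κ²` near 1 with `κ′` near +1 says the ensemble stays a parallel
H-aggregate under the 10° orientation jitter, and the positive coupling
(~535 cm⁻¹ at `n = 1.33`) is the cofacial sign expected for that geometry.
The large spread in the folded slip angles is an artifact of the reporting
fold `|θ−90|` applied near θ ≈ 90° (see the methods vignette).

Higher-level front ends write the same results to disk as CSV tables,
figures and a YAML manifest: `run_simulate()`, `run_analyze()`,
`run_contact_map()`, plus a thin CLI at `inst/cli/sqdimer.R` with
`simulate` / `analyze` / `contact-map` subcommands.

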