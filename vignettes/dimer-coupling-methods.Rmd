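---
title: "Methods: excitonic coupling and geometry of DNA-templated dye dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excitonic coupling and geometry of DNA-templated dye dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Two dyes held close by a DNA scaffold couple through their optical
transition dipoles. `sqdimer` quantifies that coupling frame by frame from
an all-atom trajectory, under the **extended dipole approximation**: each
dye's transition dipole `μ_i = |μ_i| μ̂_i` is replaced by two opposite point
charges `±q_i = |μ_i| / l_i` placed at the termini `r_i`, `s_i` of its
π-conjugation bridge, and the exciton hopping parameter is the screened
Coulomb interaction of the two charge pairs,

$$J_{mn} = J_o\left(\frac{1}{|r_1-r_2|} - \frac{1}{|r_1-s_2|}
  - \frac{1}{|s_1-r_2|} + \frac{1}{|s_1-s_2|}\right),\qquad
J_o = \frac{\mu_m\,\mu_n}{4\pi\varepsilon_0\, n^2\, l_m l_n},$$

with `l_i = |r_i − s_i|` and `n` the refractive index of the medium. The
geometric conventions are those used for squaraine dyes:

- the dye **center** `c` is the mass-weighted center of the four squarate
  carbons;
- `μ̂` points from `c` toward the unweighted geometric center of the
  terminal benzene ring **furthest from the linker** (the dye long axis);
- the bridge termini `r`, `s` are the two terminal benzene ring centers,
  `r` being the one `μ̂` points toward.

Which ring is "far" is declared once in the selection configuration rather
than inferred per frame: the covalent topology is fixed, and per-frame
inference could flip `μ̂` spuriously and corrupt the packing diagnostic
`κ′`. Note that `μ̂` (anchored at `c`) and the `r−s` axis are retained
separately — they nearly coincide but are not constrained to; the coupling
uses the endpoints directly, the orientation metrics use `μ̂`.

Per-frame orientation is summarized by the center distance `R = |c_n − c_m|`
with direction `R̂`, the oblique angle `α = arccos(μ̂_m·μ̂_n)`, the slip
angles `θ_i = arccos(R̂·μ̂_i)`, the orientation factor
`κ² = (μ̂_m·μ̂_n − 3(μ̂_m·R̂)(μ̂_n·R̂))²` and the packing factor
`κ′ = μ̂_m·μ̂_n`. `κ² ≈ 1` marks a face-to-face H-aggregate, `κ² ≈ 4` a
head-to-tail J-aggregate; the sign of `κ′` distinguishes parallel (AA) from
antiparallel (AB) packing because the dipole always points along the same
direction of the dye.

## Assumptions

- Inputs are solvent-stripped, whole-molecule coordinates; no periodic
  boundary unwrapping is attempted.
- The transition dipole magnitudes `|μ|` are consumed as constants
  (packaged defaults for the three squaraine variants: SQ-H2 12.99 D,
  SQ-Cl2 13.41 D, SQ-Me2 13.73 D); no quantum chemistry is performed.
- The medium enters only as the scalar screening `n⁻²`; no transition
  charges or explicit polarization.

# Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| contact cutoff | nm | 1.2 | matches the nonbonded electrostatic cutoff of typical production MD, beyond which no direct interaction exists |
| GROMOS RMSD cutoff | nm | 0.05 | tight enough to separate discrete stacking geometries of a ~1.9 nm dye |
| min. cluster fraction | — | 0.05 (strictly greater) | clusters at or below 5% of frames are treated as transition states |
| equilibration skip | fraction | 0.05 | the leading 5% of frames; expressed as a fraction so the rule scales to any trajectory length (0.1 μs of a 2 μs run) |
| stride | frames | 50 (pipeline front end) | decorrelates frames and keeps the O(n²) clustering tractable |
| refractive index `n` | — | 1.33 | aqueous buffer; configurable since couplings scale as `n⁻²` |
| energy unit | — | cm⁻¹ | `K` = 1 D²/nm³ ≈ 5.0341 cm⁻¹, recomputed from CODATA constants at load, never hard-coded; meV available |
| fold convention | — | `as_printed` | see below |

Internally every length is in nm; readers convert on the way in (PDB and
XYZ are Å). Atom indices in all configuration files are 1-based.

# Design choices where the design was open

**Angle folding.** Angles are reported in [0°, 90°]. The default rule,
`as_printed`, maps `x → |x − 90|` for `x > 90°` — the rule used when these
angles are compared with experiment-derived values. It is discontinuous at
90° and maps 180° to 90°, which is physically odd for antiparallel dipoles,
so the conventional reflection `min(x, 180 − x)` is available as
`reflect_180`. Near-cofacial ensembles have raw slip angles fluctuating
about 90°, and under `as_printed` the folded values oscillate between ~0°
and ~90°; the large sd of folded `θ` in summaries is an artifact of this
rule, which is why raw angles are always carried alongside.

**Which slip angle.** `θ` is computed for both dyes and both are exported;
the headline value is dye n (the second dye in configuration order), since
the defining expression names only `μ̂_n`.

**Heterodimer prefactor.** `J_o` uses the product `μ_m μ_n`, which reduces
exactly to the `|μ|²` homodimer form when the magnitudes are equal.

**Standard deviations.** Time-series summaries use the population sd
(divisor n); with thousands of frames the distinction from the sample sd is
negligible, but the choice is fixed and documented. GROMOS summaries report
the unweighted mean and sd across cluster values, with fraction-weighted
versions exported alongside.

**GROMOS details.** Ties in the neighbor-count maximization break toward
the lowest frame index, making the greedy procedure deterministic.
"More than 5% of the total" is interpreted as a fraction of *frames*
(strictly greater than), the only reading under which the discarded
clusters are sensibly "transition states". Frames are rigid-superposed
(Kabsch) onto each other over the same dye-atom selection before the RMSD
is measured — the common clustering practice — with `superpose = FALSE`
available to cluster raw coordinates. Cluster-average dipole directions are
renormalized means; a cluster whose mean direction collapses below 1e-6 is
flagged rather than silently normalized.

**Contact maps.** The boundary is inclusive (`≤ cutoff`; a measure-zero
choice, fixed and documented), the diagonal is kept at 1, and residue
centers of mass use all atoms present in the file, hydrogens included — a
switchable default, since solvent-stripped MD output retains solute
hydrogens.

# Numerical choices

- Dot products are clamped to [−1, 1] before `arccos`, so parallel and
  antiparallel geometries cannot produce NaN from round-off.
- Coupling evaluation refuses endpoint pairs closer than 1e-4 nm and names
  the offending pair; dye centers closer than 1e-6 nm are rejected.
- The pairwise RMSD kernel is compiled (RcppArmadillo); after centering,
  the superposed RMSD is obtained from the singular values of the 3×3
  cross-covariance with the usual determinant sign correction, clamped at
  zero before the square root.
- 2D histograms use right-closed bins including the lowest edge, so the
  total count always equals the number of observations.

# The synthetic generator: what it emulates, and what it does not

`generate_dimer_trajectory()` produces two rigid template dyes (squarate
square, two hexagonal rings 1.4 nm apart, a linker-side marker) fluctuating
about an ideal cofacial stack: separations are drawn from
`Normal(mean_R, sd_R)` truncated below at 0.3 nm (which guarantees the
coupling preconditions can never fail), each dye receives an independent
small random rotation (axis uniform, angle `Normal(0, jitter)`), AB packing
rotates dye 2 by 180° about the stacking normal, and an optional conformer
switch re-bases a contiguous trailing block of frames on a second geometry.
`generate_mock_hj()` adds four arms of single-pseudo-atom residues (unit
mass — only their centers matter for contact maps) in a planar X, with
AC-like (`junction_core`) or BC-like (`displaced`, 1.5 nm outward) dye
placement and 0.05 nm Gaussian positional noise on the arm residues.

The defaults — 10,000 frames, mean `R` 0.6 nm, sd 0.1 nm, 10° jitter, seed
1234 — are the package's reference ensemble: a separation distribution and
orientation spread typical of a stacked squaraine dimer on a junction.

All randomness flows from a single stream seeded from the configuration,
drawn in frame-major order, so outputs are bit-reproducible; analysis
stages consume no randomness at all.

What the generator does **not** emulate: force-field energetics, solvent,
kinetics, correlated dye-DNA motion, DNA breathing, or any realistic
free-energy landscape. Passing tests on synthetic data therefore validate
the *measurement machinery* — geometry extraction, coupling evaluation,
clustering, counting — not the physics of any real dye-DNA system. In
particular, recovering the planted `mean_R` says nothing about whether a
real dimer sits at 0.6 nm.

# Problem sizes in the test suite

The suite exercises the statistical contracts at sizes chosen to make the
sampling bounds sharp while keeping a full run under a minute of compute:
10,000 frames for distance-distribution recovery (3-standard-error bound
and a Kolmogorov–Smirnov check against the truncated normal at α = 0.01),
2,000 frames for planted 60/40 and 96/4 conformer-recovery through the full
RMSD-clustering path, 1,000 frames for the time-series vs GROMOS agreement
check, and 1,000 random geometries for the four-point-charge Coulomb oracle
at 1e-12 relative to the magnitude of the Coulomb terms.

# Known limitations

- Absolute `J` values depend on the unknown refractive index of the local
  environment; only trends and limits are meaningful without fixing `n`.
- The extended dipole approximation itself degrades at separations
  comparable to the charge spacing; no transition-charge (TrESP) option is
  provided.
- GROMOS clustering is O(n²) in frames; stride before clustering.
- Binary trajectory formats (XTC/DCD) are supported only through the reader
  plug-in contract, not natively.
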