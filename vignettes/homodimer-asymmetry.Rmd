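---
title: "Quantifying protomer asymmetry in homodimer ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protomer asymmetry in homodimer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerdyn)
```

## The problem

Homodimeric enzymes are built from two chemically identical protomers, yet
their dynamics need not be identical. For PLP-dependent enzymes of the
5-aminolevulinate synthase family, the catalytically decisive element is a
mobile active site loop that can transiently fold into a beta strand
pairing with the conserved beta13 strand; the erythroid isoform
additionally carries a 35-residue intrinsically disordered C-terminal tail
whose mutations cause gain-of-function disease. The question `dimerdyn`
operationalizes: is the motion of the tail anti-correlated with the motion
of the loop, and is that anti-correlation distributed asymmetrically
between the two protomers — one protomer's tail fluctuating more and
anti-correlating more strongly, the partner staying quiet?

`dimerdyn` does not run molecular dynamics. It analyses coordinate
ensembles (multi-model PDB, or ensembles built in code) and provides a
synthetic generator whose statistical ground truth is known exactly, so
that every stage of the analysis can be verified end to end.

## The analysis chain

The stages run in the conventional order (all distances in nm, times in
ps):

1. **Superposition.** Every frame is superposed on a reference by a
   weighted Kabsch fit over the conserved-region backbone; the SVD
   reflection branch is corrected so the rotation is always proper. The
   fitted transform of each frame applies to all atoms of that frame.
2. **RMSD.** Per-region, per-frame RMSD against the reference in two
   variants: fitted-coordinate RMSD, and the fit-free distance-matrix RMSD
   (root-mean-square deviation of all intra-selection atom-pair distances,
   invariant under rigid motion). The distance variant is the default,
   matching the fit-free deviation measure conventional in trajectory
   analysis tools; every output is labeled with the mode so the two are
   never silently conflated. Two RMSD series can be histogrammed into a 2D
   landscape with a shifted `-ln(count/F)` surface; empty bins are flagged
   explicitly, never set to infinity.
3. **RMSF.** Per-atom root-mean-square fluctuation about the time-mean
   position (fluctuation about a fixed reference is available as an
   option), aggregated per residue as the unweighted mean over the
   backbone N, CA, C atoms. For an atom with independent per-axis Gaussian
   displacement of standard deviation sigma, the expected RMSF is
   `sqrt(3) * sigma` — the analytic limit the tests check.
4. **Hydrogen bonds.** Geometric criterion: donor-acceptor distance at
   most 0.35 nm and H-donor-acceptor angle at most 30 degrees (boundary
   equality counts). These thresholds are the conventional geometric
   definition; because published analyses often leave them implicit, they
   are mandatory configuration here and echoed into every output header.
   Backbone N-H donors and carbonyl O acceptors are always typed; a small
   documented side-chain table can be toggled off.
5. **Secondary structure.** A reduced Kabsch-Sander assignment over
   {H, E, B, C}: hydrogen bonds by the electrostatic model
   `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
   (distances in Angstrom internally; bond if `E < -0.5`), alpha helices
   from two consecutive i to i+4 turns, strands from parallel/antiparallel
   bridge patterns, with a ladder of at least two consecutive bridges
   required for `E` — an isolated bridge stays `B`. 3-10 and pi helices,
   turns and bends are deliberately collapsed to `C`: the downstream
   consumer is the count of beta-strand-forming loop residues, which by
   default counts `E` only (`count_bridge = TRUE` includes `B`). Amide
   hydrogens are used when present and otherwise placed deterministically
   1.0 Angstrom from N opposite the bisector of the N-CA and N-C(prev)
   directions.
6. **DCCM.** Pearson cross-correlation of Calpha displacement vectors
   about their time means on the fitted ensemble. The time mean (not the
   reference structure) is the displacement center, matching the standard
   covariance-to-correlation construction. Displacement variances below
   1e-15 nm^2 raise an explicit error rather than produce NaN.
7. **Asymmetry regression.** For each tail residue, the mean correlation
   with the 15 loop residues (unweighted mean; a max-magnitude aggregate
   exists but is not the default), differenced chain B minus chain A, and
   regressed on the tail RMSF difference by ordinary least squares
   (`stats::lm`). Inference is the two-sided t test on the slope with
   n - 2 degrees of freedom and the adjusted R-squared; p-values are not
   multiplicity-corrected, as the regressions for different systems or
   temperatures are reported independently. An exact fit (zero residual
   variance) is reported as `p_value = 0` with an `exact_fit` flag instead
   of a numerical failure.
8. **Clustering.** Single-linkage at a distance cutoff, computed via
   `stats::hclust`/`cutree`: clusters are exactly the connected components
   of the graph whose edges are pairwise distances at most the cutoff.
   Ids are ordered by descending size (ties: earliest member frame);
   representatives minimize the mean distance to the other members (ties:
   smallest frame index). No universal cutoff exists, so the cutoff is
   mandatory configuration, echoed in results; 0.1 nm is a conventional
   starting point.

`run_pipeline()` orchestrates all stages from a `run_config()`, writes
every table as delimited text with a header echoing seed, criteria, mode
and cutoff, skips the asymmetry stage with a logged notice for
single-protomer input, and surfaces (rather than crashes on) the degenerate
constant-x regression of two identical protomers.

## The synthetic generator

The generator emulates the statistical structure of a homodimer
trajectory, not its physics: no force field, no integrator, no solvent.

`generate_correlated_ensemble()` draws per-residue Calpha displacements
independently per Cartesian axis from a zero-mean Gaussian with a
residue-level correlation matrix (Cholesky factorization; a
non-positive-definite target is an error reporting the smallest
eigenvalue, with diagonal-jitter repair strictly opt-in) and per-residue
standard deviations, adding them to a fixed mean chain. Because the three
axes share the residue-level correlation, `<dr_i . dr_j> = 3 rho_ij
sigma_i sigma_j` and `<|dr_i|^2> = 3 sigma_i^2`, so the expected DCCM
equals the target matrix exactly and the expected RMSF is
`sqrt(3) * sigma_i` — an analytically checkable contract. Optional
rigid-body contamination (rotations uniform over SO(3) via unit
quaternions, translations uniform in a 1 nm box) stresses the fitting
stage. All generators are pure functions of their parameters and seed; the
global RNG state is saved and restored.

Two geometric choices matter and were made once:

- **Compact mean structure.** The mean chain is a compact 3D Lissajous
  curve a few nm across, like a folded domain, rather than an extended
  chain. On a long extended chain, a collective mode whose amplitude
  varies along the chain is well approximated by a rigid rotation with
  long lever arms, so least-squares superposition absorbs part of the
  planted correlation; a compact mean structure keeps lever arms short
  and the post-fit DCCM equal to the planted matrix within sampling
  error.
- **Scaffold fit region.** In the dimer scenario the conserved (fit)
  region is the rigid scaffold flanking the loop (spans 441-499 and
  515-552 in the scenario's author numbering), excluding the loaded loop
  500-514. Superposing on residues that themselves carry the planted
  collective mode would subtract its fit-region mean from every residue
  and bias the loop-tail correlations; in a real protein the loop is a
  small fraction of the conserved core and the same bias is negligible,
  but in a compact synthetic protomer it is not, so the scaffold is the
  honest fit region.

`dimer_scenario()` fixes the study-like conditions once: 1001 frames at
100 ps spacing (the conventional 100 ns trajectory sampling), a compact
protomer carrying a 15-residue loop, the beta13 strand and a 35-residue
tail in author numbering, loop factor loading 0.9 (within-loop correlation
0.81), conserved/loop/tail-A amplitudes 0.05/0.08/0.10 nm with tail B
ramping 0.11 to 0.17 nm, protomer A loop-tail correlation -0.25, and
rigid contamination on. Correlations are built from a single latent
factor: loop residues load 0.9, tail residue j loads `rho_j / 0.9`, so the
loop-tail correlation is exactly `rho_j` and positive definiteness holds
by construction. Given a planted line, protomer B's correlations are set
to `rho_A + intercept + slope * sqrt(3) (sigma_B - sigma_A)`, so the
noise-free (delta RMSF, delta C) pairs lie exactly on the line; the exact
planted profile is returned alongside the ensembles. The default planted
line (intercept -0.04, slope -1.10) is a representative strong-asymmetry
condition.

What the generator does *not* emulate — and hence what passing tests do
not show about real trajectories: non-Gaussian and time-correlated
dynamics, side chains and solvent, conformational substates (each
protomer is a single Gaussian basin), and any coupling between secondary
structure and the correlation structure. The hydrogen-bond and
secondary-structure stages are instead validated on ideal-geometry
fixtures: `build_ideal_helix()` chains residues by internal coordinates
(phi = -57, psi = -47, omega = 180 degrees, standard bond lengths and
angles), and `build_antiparallel_hairpin()` builds two extended strands
(phi = -139, psi = 135) and places the second by the antiparallel sheet's
local two-fold axis (180 degrees about the sheet normal) followed by a
deterministic grid search plus Nelder-Mead refinement of the in-sheet
translation and a small tilt, maximizing inter-strand Kabsch-Sander bonds
while pulling paired N...O separations toward 0.29 nm and the H-N...O
angles toward collinearity. The two-residue turn joining the strands is
deliberately coil-like.

## Numerical choices and degenerate inputs

- Internal units are nm everywhere; PDB I/O converts Angstrom at the
  boundary, and a read/write round trip is exact to the 1e-4 nm implied
  by the fixed three-decimal PDB coordinate field. Coordinates that do
  not fit the fixed-width field are an error.
- Residue numbering is taken verbatim from the input (author numbering,
  inclusive ranges); nothing is ever renumbered. Alternate locations
  other than blank/'A' are dropped; insertion codes are rejected.
- Kabsch fits require at least three non-collinear points (rank check on
  the second singular value); superposition weights default to uniform,
  which is reproducible without element masses.
- The Kabsch-Sander energy has a 0.05 nm clash guard below which an error
  is raised; bridge patterns require a sequence separation of at least
  three residues, and a 0.9 nm CA-CA prefilter keeps the bond scan fast.
- Empty atom selections, selections missing a requested atom name,
  overlapping hydrogen-bond regions, fewer than two frames for
  fluctuations, constant regressors, and non-symmetric distance matrices
  are all explicit errors naming the offending residues or inputs.
- Landscape bins are `[min, max]` per axis with 50 bins by default
  (plotting-script parameters are rarely printed; 50 is a reasonable
  default that the configuration can override).

## Problem sizes used in the test suite

The suite validates each stage at sizes chosen so the whole run stays
comfortably interactive while the statistical checks retain power:
DCCM-versus-oracle equivalence on 20 ensembles of 8-12 residues and 40-100
frames at 1e-12; planted-correlation recovery at 5000 frames within 0.05
over rho in {-0.8, -0.4, 0, 0.4, 0.8}; the RMSF analytic limit at 10000
frames within 2 percent; null calibration of the slope test over 1000
replicates against 99 percent binomial bounds; and end-to-end asymmetry
detection over 100 scenario seeds at the scenario's native 1001 frames,
requiring a negative slope with p < 0.05 in at least 95 of 100 runs. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch with 25 seeds for the detection rate.

## Known limitations

- The pipeline analyses the protomers of a dimer as separate ensembles;
  inter-protomer correlations (one DCCM across both chains) are not
  computed.
- Secondary structure is the reduced four-letter alphabet; no solvent
  accessibility, no 8-state DSSP parity.
- Hydrogen placement covers the backbone amide only; structures lacking
  side-chain hydrogens simply contribute no side-chain donors.
- The distance-matrix RMSD is quadratic in selection size; for very large
  selections prefer the fitted variant or a Calpha-only selection.
- `means_correlation_report()` regresses across systems with ordinary
  least squares and is only as meaningful as the number of systems
  supplied (at least three are required).
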