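# dimerdyn

Post-simulation analysis of multi-frame protein coordinate ensembles, built
around a question that arises for homodimeric enzymes such as erythroid
5-aminolevulinate synthase (ALAS2): do the two chemically identical
protomers move identically, or does the dimer behave asymmetrically, with
the mobile active site loop of one protomer anti-correlated with its
intrinsically disordered C-terminal tail while the other protomer stays
quiet?

`dimerdyn` implements the full analysis chain needed to answer that
question from an ensemble of structures (e.g. frames of a molecular
dynamics trajectory stored as multi-model PDB), plus a synthetic-ensemble
generator that plants known statistical structure so every stage can be
validated against exact ground truth.

## What it computes

Given ensembles for the two protomers, superposed on their conserved
region, the package computes for each protomer the Calpha displacement
cross-correlation matrix (DCCM)

    C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>),   C_ij in [-1, 1],

where `dr_i(t)` is the displacement of Calpha `i` from its time-mean
position, and the per-residue root-mean-square fluctuation
`RMSF_i = sqrt(<|dr_i|^2>)`. For each C-terminal tail residue `j` the loop
block of the DCCM is collapsed to the mean over the 15 active-site-loop
residues, `Cbar_j = mean_i C_ij`. The homodimer-asymmetry statistic is the
ordinary least-squares regression

    delta C_j = alpha + beta * delta RMSF_j,

with `delta` meaning chain B minus chain A per tail residue, a two-sided t
test on `beta` (df = n - 2) and the adjusted R-squared. A significantly
negative slope means the protomer whose tail fluctuates more shows the
stronger loop-tail anti-correlation.

Around this core the package provides the standard supporting stages:

- multi-model PDB reading/writing (`read_multimodel_pdb()`,
  `write_multimodel_pdb()`; Angstrom on disk, nm in memory) and named
  residue-region selection in author numbering (`region_set()`,
  `select_atoms()`);
- Kabsch least-squares superposition with reflection correction
  (`kabsch_fit()`, `fit_ensemble()`), per-frame RMSD in both
  fitted-coordinate and fit-free distance-matrix variants
  (`rmsd_series()`), and 2D RMSD landscapes (`rmsd_landscape()`);
- per-residue backbone RMSF profiles (`backbone_rmsf()`);
- geometric hydrogen-bond counting between two regions, e.g. active site
  loop against the beta13 strand (`hbond_count_series()`; criteria 0.35 nm
  / 30 degrees, always echoed into outputs);
- Kabsch-Sander style secondary-structure assignment (H/E/B/C) and
  per-frame counts of beta-strand-forming loop residues
  (`assign_secondary_structure()`, `beta_count_series()`);
- single-linkage clustering of frames with representative structures
  (`pairwise_rmsd_matrix()`, `linkage_cluster()`, `representative()`);
- synthetic generators: correlated Calpha ensembles with planted DCCM
  blocks and amplitude profiles (`generate_correlated_ensemble()`),
  asymmetric two-protomer scenarios whose noise-free asymmetry profile
  lies exactly on a requested line (`dimer_scenario()`,
  `make_asymmetric_dimer()`), and ideal helix / antiparallel-hairpin
  geometries with amide hydrogens (`build_ideal_helix()`,
  `build_antiparallel_hairpin()`).

Results are tibbles (or matrices with `tidy()` methods); fitted regressions
have broom-style `tidy()`/`glance()` methods and every result type has an
`autoplot()`.

## Worked example

Generate a synthetic homodimer whose noise-free asymmetry relation is
planted on the line `delta C = -0.04 - 1.10 * delta RMSF` (1001 frames per
protomer, rigid-body contamination on), run the full pipeline, and read off
the recovered regression:

```r
library(dimerdyn)

report <- run_pipeline(run_config(dimer_scenario(seed = 42), seed = 42))
#> dimerdyn: analysing protomer A (1001 frames)
#> dimerdyn: analysing protomer B (1001 frames)

report$regression
#> <ols_fit asymmetry> y = -0.02676 + -1.169 x, p = 8.42e-16, adj R2 = 0.859, n = 35

glance(report$regression)
#> # A tibble: 1 x 6
#>   intercept slope  p_value r2_adjusted     n exact_fit
#>       <dbl> <dbl>    <dbl>       <dbl> <int> <lgl>
#> 1   -0.0268 -1.17 8.42e-16       0.859    35 FALSE

head(report$asymmetry, 3)
#> # A tibble: 3 x 3
#>   residue delta_cij delta_rmsf_nm
#>     <int>     <dbl>         <dbl>
#> 1     553   -0.0300        0.0154
#> 2     554   -0.0735        0.0120
#> 3     555   -0.0619        0.0320
```

The recovered intercept and slope sit within finite-sampling noise of the
planted line, and the slope is significantly negative: the pipeline detects
the planted protomer asymmetry. `report$protomers` holds the per-protomer
stage results (RMSD series, landscape, RMSF profile, DCCM, clustering);
`autoplot(report$protomers$A$dccm)` draws the correlation heat map and
`autoplot(report$asymmetry)` the regression scatter.

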