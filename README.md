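# girdlemorph

Ecomorphology of the anuran pectoral girdle, as a reusable and fully
simulation-validated R pipeline. Frogs and toads use strikingly different
locomotor modes — swimming, walking/hopping, jumping, backward and headfirst
burrowing, climbing — and the shoulder skeleton (scapula, coracoid,
cleithrum, clavicula) is expected to carry signatures of those behaviors.
`girdlemorph` implements the complete analysis chain used to test that idea
on micro-CT data:

1. **Segmentation** (`calibrate_window`, `segment_vote`): calibrated
   gray-window adjustment (window centered at `t = 1.019·m − 462.812`, `m`
   the mean gray of bone plus surrounding soft tissue), slicewise local
   thresholding along three orthogonal reslicings, and a 2-of-3 per-voxel
   vote with mask-based cleanup.
2. **Geometric morphometrics** (`gpa`, `species_means`,
   `subset_landmarks`, `estimate_missing`): Generalized Procrustes Analysis
   with sliding semilandmarks that minimize thin-plate-spline bending
   energy, TPS estimation of missing landmarks (e.g. clavicula-less
   microhylids), a two-level species-mean procedure, and the five landmark
   datasets (i: fixed landmarks; ii–v: per-bone landmarks + semilandmarks).
3. **Phylogenetic comparative statistics** (`kmult`, `pgls_manova`,
   `pairwise_groups`, `pca_broken_stick`, `modularity_cr`): multivariate
   phylogenetic signal *K*<sub>mult</sub> (1 under Brownian motion),
   phylogenetic MANOVA `shape ~ logCS + group + logCS:group` fitted by a
   GLS whitening transform with type-II sums of squares and residual
   randomization (RRPP), size-corrected pairwise group tests, broken-stick
   PCA, and the covariance-ratio (CR) modularity test across the four
   bones.
4. **Biomechanics** (`build_frame`, `build_default_muscles`,
   `sweep_moment_arms`, `fea_solve`, `mwam`): an anatomical shoulder frame
   and two-axis joint, five hypothetical shoulder muscles whose moment
   arms are computed by the tendon-excursion relation *r* = −dL/dθ
   (verified against the cross-product formula to 10⁻⁶ mm), and
   linear-elastic tetrahedral FEA of the coracoid under five loading
   scenarios (E = 10 GPa, ν = 0.35), summarized by the mesh-weighted
   arithmetic mean (mwam) von Mises stress Σσᵥₘ·V / ΣV.
5. **Synthetic data** (`sim_tree`, `girdle_template`,
   `sim_species_shapes`, `make_tet_beam`, `make_coracoid_mesh`,
   `make_ct_phantom`): every input the pipeline needs — pure-birth trees,
   a stylized girdle template with 19 fixed landmarks and nine curves of
   sliding semilandmarks, species shapes evolving by Brownian motion with
   implanted locomotor-group and allometric effects, structured tet meshes
   with analytic stress solutions, and two-tissue CT phantoms — with
   seeded, bit-reproducible generation and ground truth returned for
   recovery tests.

The statistical model in brief: species mean shapes **Y** (Procrustes
coordinates) are analyzed under a Brownian-motion phylogenetic covariance
**C**; with **P** such that **PCP**ᵀ = **I**, the MANOVA fits
**PY** = **PX**β + ε, sums squared residuals over all coordinates, and
draws p-values by permuting reduced-model residuals (observed statistic
included; the smallest attainable p is 1/n_perm).

## Worked example

```r
library(girdlemorph)

cfg <- pipeline_config(
  synth = synth_config(n_species = 24, specimens_per_species = 3,
                       n_clav_absent = 3, seed = 1),
  subsets = c("fixed_only", "coracoid"), n_perm = 500, seed = 42)
report <- run_pipeline(cfg)
report
#> run_report: 24 species / 72 specimens, 2 landmark datasets
#>   dataset i   (fixed_only): K = 0.496 (p=0.002), group R2 = 0.344 (p=0.002), 4 sig. PCs
#>   dataset iii (coracoid): K = 0.499 (p=0.002), group R2 = 0.294 (p=0.002), 4 sig. PCs
#>   modularity CR = 0.8759 (p = 0.002)
#>   FEA mwam (Pa): I=2.45e+05, II=4.84e+05, III=3.48e+05, IV=8.07e+05, V=8.07e+05

print(report$stats$fixed_only$pmanova)
#> phylogenetic MANOVA (GLS transform, type-II SS, RRPP)
#>             Df        SS        MS     Rsq      F     p
#> logCS        1 0.0014643 0.0014643 0.02622 1.1068 0.334
#> group        5 0.0192220 0.0038444 0.34425 2.9058 0.002
#> logCS:group  5 0.0100520 0.0020104 0.18002 1.5195 0.018
#> Residuals   12 0.0158760 0.0013230 0.28433     NA    NA
#> Total       23 0.0558380        NA      NA     NA    NA
```

Reading the output: the generator implanted locomotor-group effects, so the
group term captures a large shape fraction (R² = 0.34) at the permutation
floor p = 1/500; *K* < 1 because group structure is assigned independently
of the phylogeny; CR < 1 with p at the floor indicates the four bones
covary more within than between (the generator evolves all landmarks
jointly, but alignment-induced structure and the bone partition make the
test's direction informative); and the coracoid model is stressed least
when loaded along its long axis (scenario I) and most under the
posteromedial tension/push cases (IV/V, identical by linearity).

`run_pipeline(cfg, out_dir = "out/")` additionally writes the ANOVA,
pairwise, PCA, moment-arm and mwam tables as CSV plus an md5 manifest;
reruns from the same config are bit-identical.

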