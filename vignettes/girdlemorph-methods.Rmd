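---
title: "Methods: models, parameters, and design choices in girdlemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in girdlemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`girdlemorph` reimplements a micro-CT-based ecomorphological workflow for
the anuran pectoral girdle as a closed, simulation-validated pipeline. This
vignette is the package's account of the science: the models it fits, the
parameters that matter, what the synthetic data do and do not emulate, and
the decisions taken where the design was genuinely open. Every numeric
statement here is computed by the test suite or by
`scripts/acceptance.R`; the vignette itself makes no additional empirical
claims.

## 1. Landmark scheme and superimposition

A configuration carries 19 fixed landmarks and nine curves of sliding
semilandmarks (25 per curve by default; any count in 21–29 is accepted)
distributed over scapula, coracoid, cleithrum and clavicula. Curve
endpoints are fixed landmarks; every landmark belongs to exactly one bone
and at most one curve.

**Generalized Procrustes Analysis.** Partial Procrustes: each
configuration is centered, scaled to unit centroid size
(CS = √Σ‖xᵢ − x̄‖², mm), and rotated onto the iteratively updated
consensus by the SVD orthogonal-Procrustes solution with reflections
disallowed (determinant forced +1) — sides are standardized by mirroring
beforehand, so reflections would only mask digitizing errors. Convergence
is declared when the root-mean-square change of the consensus falls below
`tol = 1e-6` (unit-CS shape units) with `max_iter = 20`; non-convergence is
flagged on the result, never thrown.

**Sliding semilandmarks.** One sliding pass per GPA iteration. Semis slide
along tangent lines estimated by central differences of their curve
neighbors (one-sided at points adjacent to endpoints); the tangent
amplitudes minimize the thin-plate-spline bending energy against the
current consensus (a quadratic solve), after which points are re-projected
onto the pre-slide piecewise-linear curve. The 3D TPS kernel is U(r) = r;
with that kernel the upper-left block of the inverse TPS system matrix is
negative semidefinite, so the package stores its negation and all bending
energies are ≥ 0, exactly 0 for affine deformations. A safeguard halves
(and ultimately abandons) any sliding step whose projection would increase
the bending energy, which makes the per-pass energy trace provably
non-increasing — a property the acceptance suite asserts.

**Missing landmarks.** Configurations lacking a clavicula (mirroring the
clavicula-less microhylid species of the study system) are completed by a
TPS warp fit on the shared landmarks of a complete reference; affine
(e.g. rigid) differences are recovered exactly. The reference is the most
complete specimen of the sample; this is an open point in the original
description and is recorded as a package choice.

**Two-level species means.** Specimens of one species are superimposed
(with sliding), rescaled to their own original centroid size, and averaged
coordinate-wise; species means are then superimposed again across species.
Sliding at level 1 relaxes against the per-species consensus, at level 2
against the across-species consensus — the alternative (a single global
reference at both levels) is defensible but was not chosen; the package
documents rather than hides this ambiguity.

**Datasets i–v.** Dataset i keeps the 19 fixed landmarks (no curves);
ii–v keep all landmarks of one bone and are re-superimposed with sliding.
Species flagged clavicula-less are excluded from the clavicula dataset.

## 2. Phylogenetic comparative statistics

All tests operate on species mean shapes with the Brownian-motion
phylogenetic covariance **C** (shared root-to-MRCA branch lengths) and its
whitening transform **P** = Λ^(−1/2)Uᵀ, so **PCP**ᵀ = **I**.

* ***K*<sub>mult</sub>** — the multivariate phylogenetic-signal ratio,
  scaled so its expectation is 1 under Brownian motion on the given tree;
  on a star phylogeny it equals 1 identically. For a single trait it
  reduces to Blomberg's K, which the tests cross-check against
  `picante::Kcalc`. Significance: random permutation of species across
  tips.
* **Phylogenetic MANOVA** — `shape ~ logCS + group + logCS:group` on
  transformed data, with type-II sums of squares (each main effect against
  the model holding the other main effect; the interaction against both)
  summed over all shape coordinates, and p-values by RRPP: rows of the
  reduced-model residuals are permuted, added back to the reduced-model
  fit, and the term's F recomputed. Note that type-II term SS do **not**
  add to the total SS in non-orthogonal designs; the table's accounting
  identities are the df decomposition and R² = SS/SS(total).
* **Pairwise group tests** — least-squares group means of the model
  `shape ~ logCS + group` evaluated at the grand-mean log centroid size
  with equal group weighting (the standard LS-means convention; the
  original description leaves this open). The statistic is the Euclidean
  distance between LS means; the RRPP null permutes the residuals of
  `shape ~ logCS`. Whether a variance-scaled distance was meant instead is
  unknowable from the source description and is documented here.
* **PCA + broken stick** — components are interpreted while their
  observed variance proportion exceeds the broken-stick expectation
  bⱼ = (1/p̃)Σ_{k≥j}1/k over the p̃ nonzero components.
* **Modularity (CR)** — on phylogenetically transformed residuals
  **P**(**Y** − **1â**), the covariance ratio compares between-module to
  within-module covariation with within-module diagonals zeroed; the four
  bones are the modules (the natural partition of the full landmark set).
  The null reassigns whole landmarks (xyz triples) to modules of the same
  sizes; the phylogenetic transform stays fixed during permutation. Low CR
  indicates modularity, so p is the fraction of permuted CR at or below
  the observed.

**Permutation convention.** Everywhere: the observed statistic counts as
one member of the permutation distribution, p = (1 + #{permuted ≥
observed})/n_perm, ties counted against the null, default n_perm = 1000,
seeded and bit-reproducible.

## 3. Muscle moment arms

The anatomical frame puts the origin at the glenoid center, x lateral
(toward the left limb), y dorsal, z anterior. Its construction needs two
midline witness points (the episternum anterior tip and sternum posterior
tip): one witness point alone cannot pin down the sagittal plane, whose
normal becomes the x axis. The remaining roll about the midline is fixed by
requiring the line from the anteromedial clavicula tip to the
posteromedial coracoid tip to be parallel to the x–z plane; constraint
residuals are reported on the frame object.

The two-axis shoulder joint applies protraction/retraction about y first,
then adduction/abduction about z (the source is silent on the order; this
one is fixed and documented — note that the pr axis is therefore carried
along by the aa rotation). Sign conventions: positive moment arm =
retraction (pr) and adduction (aa); published curves with the opposite
convention will appear sign-flipped. The reference pose is the humerus
along +x; the simplified humerus is a straight segment with the common
insertion at 40% of its 5 mm default length.

Muscles: `anterior` (anteromedial clavicula tip), `perpendicular` (origin
on the ventral midline at the insertion's anteroposterior level, so the
line is perpendicular to the long axis at reference), `posterior`
(posteromedial coracoid tip), plus `sternal`/`episternal` when those
elements are present. Wrap/warping surfaces are replaced by girdle-fixed
via points, which preserve the final-segment geometry that determines the
moment arm; path–bone intersections are detected and reported
(`check_path_intersections`), not resolved.

The moment arm is computed two ways that must agree to 10⁻⁶ mm:
geometrically, r = ((p − c) × f̂)·â with f̂ the unit vector from the
insertion toward the last girdle-fixed point; and by tendon excursion,
r = −dL/dθ with a central difference (h = 10⁻⁴ rad). Sweeps default to
−75°…+75° in 5° steps (the published plots do not state their range);
action ranges and zero crossings are derived from the grid with linear
interpolation, exact grid zeros counted as crossings.

## 4. Coracoid finite elements

Linear (constant-strain) 4-node tetrahedra; isotropic elasticity with
E = 10 GPa, ν = 0.35 (within reported ranges for vertebrate bone); sparse
symmetric assembly and a permuted Cholesky solve; Dirichlet constraints by
elimination with nonzero prescribed values supported. Units are (N, mm)
internally; stresses are reported in Pa. The relative residual
‖Ku − f‖/‖f‖ is reported (typically < 10⁻⁸), and reactions at fixed DOFs
balance the load to 10⁻⁸ relative.

The five loading scenarios: I and II fix the medial surface and load part
of the glenoidal surface (I compressively along the coracoid long axis —
the line from the mean of the two medial tips to the joint center — II
along −x); III–V fix the glenoid patch and load the posteromedial patch
(III along the posterior muscle's reference trajectory, IV along +z, V
along −z). Tractions are distributed per face in proportion to area and
split equally among the three face nodes (lumped loading; differs from
consistent loading at O(h)), so nodal forces sum to F_total·direction
exactly. F_total defaults to 1 N — linearity makes the magnitude a pure
scale, which the tests verify to 10⁻¹⁰. Because the model is linear,
reversing a load flips the stress sign but not the von Mises magnitude:
scenarios IV and V are provably identical here, unlike in a nonlinear
solver. Coracoids are modeled as solid; the patch extents (posteromedial
patch = posterior faces over the medial 20% of the beam length by default)
are parameters reported with results.

Quality and verification: a mesh containing any tet with aspect ratio
(longest edge / shortest altitude) above 50 is rejected; the element is
exact for linear displacement fields (patch test, 10⁻⁸); an axially loaded
bar with axial-only end constraints (a documented test recipe, not a
loading scenario) reproduces σ = F/A exactly; a 10×1×1 mm cantilever at
120×12×12 divisions reaches the Euler–Bernoulli tip deflection within 5%
(constant-strain tets converge slowly in bending — the deliberately coarse
scenario meshes are for comparative, not absolute, stress levels); the
mesh-weighted arithmetic mean, mwam = Σσᵥₘ·V/ΣV, makes means comparable
across refinements.

## 5. CT segmentation

`calibrate_window` implements the published gray-window calibration
verbatim: center t = 1.019·m − 462.812 with m the mean gray over bone plus
surrounding soft tissue, and half-width h = t − q with q the 0.1% quantile
of bone grays — the largest symmetric window whose lower limit clips at
most 0.1% of bone voxels to black. The formula's constants live in native
CT gray units and presume the gray structure of real scans, in which
partial-volume voxels give bone a low-gray tail below t; hard-edged
phantoms violate that (q > t) and correctly fail calibration, which is why
the phantom generator offers `partial_volume = TRUE` and why the
segmentation-quality tests run on the windowless path.

`segment_vote` thresholds each 2D slice along the three orthogonal axes
with a Niblack-family rule — foreground iff gray ≥ local mean + k·SD
(radius 15 px, k = 0.2, via integral images with border-clipped windows)
**and** ≥ a global floor, by default the midpoint of the two global Otsu
class means. The floor is the package's robustification: the plain local
rule marks roughly half of every object-free window as foreground. The
named Fiji plugin family does not say which of its methods the original
analysis used, so results carry the method and parameters rather than a
compatibility claim. A voxel is bone when ≥ 2 of the 3 axis-wise stacks
agree; the vote is intersected with the rough mask when given, and a
morphological closing (radius 1) stands in, documented as a deviation, for
the original manual foramen filling and artifact correction. Dice against
ground truth is the quality metric (two empty masks count as identical).

## 6. What the synthetic data emulate — and what they do not

`sim_species_shapes` evolves species mean shapes by isotropic, coordinate-
independent Brownian motion (rate `bm_rate`, mm² per unit branch length on
a height-1 pure-birth tree), adds a fixed random unit-direction
displacement per locomotor group (magnitude `group_effect`, mm), an
allometric displacement proportional to centered log size along a second
fixed direction (`allometry_slope`, mm per log-unit), scales species by
lognormal size factors (`size_sd = 0.3`), and adds iid Gaussian landmark
noise per specimen (`noise_sd`). Defaults: 64 species, six groups,
one specimen per species (most species in the motivating study had one),
`bm_rate = 0.01`, `group_effect = 0.5`, `allometry_slope = 0.5`,
`noise_sd = 0.05` — Brownian per-coordinate displacements of ~0.1 mm on a
~10 mm girdle, twice the digitizing noise, which a morphometrician would
call a realistic signal-to-noise regime. Directions are drawn once per
dataset from the seed; the group–allometry direction cosines are reported,
not constrained. Optionally three species are flagged clavicula-absent to
exercise the missing-landmark path.

The generator deliberately does **not** emulate: anatomically accurate
girdle geometry (the template is a stylized caricature with the right
landmark counts and named points), within-species covariance structure,
digitizing error correlated along curves, CT beam hardening or ring
artifacts, or non-Brownian evolutionary models. Passing tests therefore
demonstrate the correctness and calibration of the machinery under its
stated model, not the biological conclusions of any particular dataset.

One consequence worth flagging: the GLS tests assume the species means are
exactly Brownian. Adding iid within-species noise on top of Brownian
motion breaks that — the whitening transform amplifies the non-phylogenetic
component across short terminal branches and inflates RRPP rejection rates
(the measurement-error problem of phylogenetic comparative methods). The
calibration studies therefore simulate at the species-mean level
(`noise_sd = 0`), which is also the level at which the tests are applied;
the inflation under specimen noise is a property of the method class, not
of this implementation, and users with few specimens per species should
interpret borderline p-values accordingly.

## 7. Study conditions used by the automated checks

Chosen once as the package's reference conditions: Procrustes properties
on 4 transformed copies of the 244-landmark template; *K* calibration on a
32-tip tree with 200 Brownian replicates (20 traits); type-I error of the
group term over 200 null datasets of 24 species at 500 permutations, and
power over the implanted-effect grid (0, 0.25, 0.5, 1 mm; 50 replicates
per level at 200 permutations); the end-to-end pipeline at 24 species × 3
specimens with 500 permutations, run twice to verify bit-identical report
checksums; FEA benchmarks as in section 4; segmentation on 64³ phantoms
(bone 200, soft 100 gray, noise SD 5–45). The master seed spawns per-stage
seeds via a seeded integer draw, so any stage can be rerun independently
yet reproducibly.

## 8. Known limitations

* Surface (patch) semilandmarks, bilateral-symmetry decomposition, and
  digitizing-error models are out of scope; all semilandmarks are curve
  points.
* The frame construction requires two midline witnesses; specimens without
  ossified sternal elements need substitute midline points.
* Constant-strain tetrahedra are stiff in bending; comparative mwam values
  at the default mesh resolution are meaningful, absolute stresses near
  load application points are not (St. Venant effects, lumped tractions).
* The linear FE model cannot distinguish tension from compression
  reversals (scenarios IV vs V).
* The segmentation defaults assume bright bone on darker tissue with
  structures thinner than the local-threshold window; very thick compact
  bone interiors rely on the global floor and the closing step.
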