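---
title: "pahgeom: methods, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pahgeom: methods, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahgeom)
```

## The model

`pahgeom` estimates the isomerization energy of a polycyclic aromatic
hydrocarbon, ΔE_iso = E − E_min (energy relative to the most stable isomer
of the same formula, kcal/mol), as a linear combination of geometric
descriptors computed from Cartesian coordinates:

ΔE_iso ≈ a₀ + a₁·Σ_Dihedral + a₂·HOMA + …

The coefficients are chosen to minimize the *mean absolute deviation*
(MAD) of the residuals, not their squares. This is a deliberate modeling
assumption: isomer-energy distributions are right-skewed with heavy tails
(a few strongly destabilized outliers), and an L1 objective keeps those
outliers from dominating the fit while making the reported training MAD
the quantity actually optimized.

The underlying physical picture is that destabilization in fused-hexagon
PAHs is dominated by (i) *nonplanarity* — steric clashes force parts of the
π-system out of plane, which torsional descriptors integrate — and (ii)
loss of *bond-length uniformity* (aromatic delocalization), which the HOMA
family measures. The model is descriptive, not mechanistic: it assumes the
training and application structures come from the same geometry source
(method and basis), since bond lengths and near-planar torsions shift
systematically between optimizers.

## Descriptors and their parameters

All descriptors operate on the carbon skeleton; hydrogens are ignored
except where noted. Parameters, defaults, and the reason for each:

* **Bond perception** (`perceive_bonds`): distance windows, C–C bonds in
  (0.9, 1.75] Å, C–H in (0.7, 1.30] Å. Covalent-radius tables would add
  machinery without benefit for a two-element, sp²-only chemistry; the
  windows comfortably bracket aromatic C–C (≈1.35–1.45 Å) and C–H (≈1.09 Å)
  while excluding nonbonded contacts (≥ 2.4 Å across a ring). Both cutoffs
  are arguments. A carbon with < 1 or > 4 bonds aborts with a
  geometry-sanity error naming the atom (disable with
  `sanity_check = FALSE` to inspect pathological inputs).
* **Ring perception** (`perceive_rings`): a smallest-set-of-smallest-rings
  basis; size equals the cycle rank of the skeleton. For each edge the
  shortest cycle through it is found by BFS; candidates are ordered by
  size, then lexicographically by sorted member indices, and added greedily
  under GF(2) independence. The lexicographic tie-break makes ring order —
  and everything downstream — deterministic. For benzenoids every basis
  ring is a hexagon, so the choice of SSSR algorithm is immaterial in
  practice; the determinism is what matters for testing.
* **HOMA** (`homa`): HOMA = 1 − (α/n)·Σ(R_k − R_opt)², with R_opt = 1.388 Å
  and α = 257.7 (the standard aromatic C–C parameterization; α is chosen in
  the literature so a Kekulé-localized ring scores ≈ 0). The all-ring
  variant averages per-ring HOMA with equal ring weights (the simplest
  convention; a bond-count weighting would differ only when ring sizes
  differ, which benzenoids exclude). `homa_fused`/`homa_edge` evaluate the
  formula *once* over the pooled fused/perimeter bond set, because those
  bond classes do not partition into rings.
* **Σ_Dihedral** (`sum_dihedral`): every distinct simple bonded 4-carbon
  path contributes min(|φ|, 180° − |φ|), the unique continuous distance of
  the torsion to the nearest planar (cis/trans) configuration. All paths
  are enumerated — not just in-ring torsions — since exocyclic paths across
  ring fusions carry exactly the helical distortions the metric should see.
* **Bond-angle metrics** (`bond_angle_metrics`): all unordered C–C–C
  triples centered on each carbon; Σθ and θ_RMSD are deviations from the
  ideal sp² angle of 120°. BLA and BAA are defined here as the per-ring
  mean of cyclic consecutive absolute differences (of bond lengths /
  in-ring vertex angles), averaged over rings: the simplest alternation
  measure that is exactly zero in the uniform limit. Both sit behind one
  function each so an alternative convention is a one-line substitution.
* **Pyramidalization** (`pyramidalization_rmsd`): for each carbon with
  exactly three bonded neighbors, θ_pyr = arcsin(h / l_mean) where h is the
  carbon's distance from its neighbors' plane and l_mean its mean bond
  length; the package reports the RMSD over such carbons. The neighbor
  plane uses *all* bonded atoms including hydrogens — a rim carbon's sp²
  plane is defined by two carbons and one hydrogen — which is the one
  place hydrogens enter a descriptor. With a carbons-only convention the
  metric would be silently restricted to ring-junction atoms.
* **Δz** (`delta_z`): the structure is translated to the centroid of the
  selected atoms and rotated so their least-squares plane (smallest
  eigenvector of the coordinate covariance) is z = 0; Δz = max(z) − min(z).
  Carbons-only selection is the default: C–H bond tilt should not define
  the molecular plane. Whether hydrogens belonged in the plane fit was an
  open choice; `atom_selection = "all"` switches conventions. The rotation
  sign is fixed (normal → +z, first selected atom at z ≥ 0) so alignment is
  idempotent to 1e-9 Å.

## Fitting: least absolute deviations

`fit_lad` minimizes the weighted mean absolute residual. No linear-
programming backend is assumed; the solver is authored in the package:

1. iteratively reweighted least squares (weights 1/max(|r|, 1e-9), up to
   100 iterations or parameter change < 1e-12) brings the estimate near
   the L1 optimum;
2. *vertex polishing*: an LAD optimum interpolates p = k+1 observations,
   so all p-subsets of the ~p+9 smallest-|residual| points are solved
   exactly and the interpolant with the lowest objective replaces the
   iterate, repeated (≤ 12 rounds) to a fixed point.

The result is deterministic for fixed input; degenerate ties between
optimal vertices resolve to the first subset in enumeration order, and the
achieved MAD is always reported so non-uniqueness is observable. On
noiseless data the solver recovers coefficients to 1e-8; on ≤ 25-point
problems it matches (or beats) an exhaustive grid-search oracle. Weights
default to uniform — the "weighted" hook exists, but no specific weighting
scheme is baked in. Rank-deficient designs abort naming the collinear
columns.

Two conventions around the fit:

* ΔE_iso is computed *within each formula group* before any pooled fit
  (`fit_isomer_table`); a pooled fit therefore shares one intercept across
  groups whose zero points differ, which is visible in synthetic tests.
  The transferability protocol — train on one formula, apply to another —
  is the `train_formula` argument plus `predict`.
* `correct_xtb` fits the semiempirical-to-reference line with the LAD
  objective by default, for consistency with everything else; whether the
  original "line of best fit" was L1 or L2 is not knowable from the outside,
  so `objective = "ls"` is available. On low-noise synthetic data the two
  agree to the noise scale.
* The boundary Δz = 1.0 Å is classified *planar* in
  `planarity_partition` ("smaller or equal").

## The published predictor

`published_model()` carries the fixed equation
ΔE_iso = 0.0207·Σ_Dihedral − 339.00·HOMA + 16.44·θ_RMSD + 236.09, trained
on the C36H20 isomer subset, with provenance attached to every serialized
copy. The symmetric error bound reported with predictions defaults to
2.48 kcal/mol, the all-isomer training MAD of this descriptor combination
(which exact MAD a downstream tool should quote is not pinned down, so the
bound is a constructor argument). Negative estimates — e.g. a perfect
planar benzene scores 236.09 − 339.00 = −102.91 — are reported with a
warning, not clamped: they are a legible signal that the input lies below
the model's training manifold, and flooring them would hide it.

## The synthetic world

`make_benzenoid` builds exact-lattice benzenoids (all bonds equal, all
angles 120°, planar) from hexagon cells; `apply_distortion` superimposes
controlled twist (helicity), bend (rigid rotation about a fused bond —
which preserves every bond length, making it the clean probe for
"nonplanarity without bond strain"), seeded coordinate noise, and Kekulé
bond alternation. Alternation is exact (L ± a, angles 120°) only for a
single hexagon — on fused systems such a geometry cannot close — so
multi-ring alternation is approximated by contracting the bonds of a
perfect matching.

`synth_isomer_table` draws descriptor vectors spanning the ranges observed
in large PAH isomer sets (Σ_Dihedral up to 1912°, Δz up to 8.78 Å, a small
planar fraction so both planarity classes occur) and generates energies
*exactly linear* in the descriptors plus Laplace noise (default generating
law: the published equation; default noise 3 kcal/mol, the scale of
single-descriptor residuals). Laplace noise is chosen deliberately: the
LAD estimator is maximum-likelihood under it, so coefficient recovery has
clean asymptotics (and Gaussian noise would make least squares look better
for reasons unrelated to the package).

What the generator does *not* emulate: real isomer geometry–energy
coupling (descriptors here are drawn independently, whereas real
Σ_Dihedral and HOMA are correlated through the structure), conformer
effects, optimizer-dependent near-planar geometry noise, and
thermochemical-quality equilibrium structures. A green test suite
therefore establishes that the descriptors compute the stated geometry
exactly, and that the fitting machinery recovers a known linear law under
its stated noise model — it does not re-establish the empirical accuracy
of geometric descriptors on real DFT data, which requires the original
full-dataset descriptor/energy table. That table (tens of thousands of
rows) is not redistributable inside the package and is the one acceptance
criterion left unexercised; the column-mapped CSV ingestion it would use
(`read_isomer_table(mapping = ...)`) is implemented and tested on
synthetic tables with the same schema. For the same reason the R_opt
sensitivity scan (`ropt_scan`, grid restricted to (0, 5] Å) is validated
by construction — injecting a known optimal bond length and recovering it
— rather than against the published scan, and the default R_opt stays at
the literature value 1.388 Å rather than any dataset-optimal value.

## Degenerate inputs and tolerances

* XYZ parsing reports the offending line number for malformed counts,
  truncated frames and non-numeric coordinates; writing uses 6 decimals,
  so round trips are exact to 1e-6 Å.
* Collinear atom selections make the plane fit abort (degeneracy error);
  the planarity check uses a 1e-12-scaled eigenvalue threshold.
* Exactly planar input yields *exactly* zero Σ_Dihedral (the torsion's
  out-of-plane component vanishes identically), and Δz/θ_pyr below 1e-12.
* Descriptors undefined for a structure (HOMA_fused with no fused bond,
  pyramidalization with no 3-coordinate carbon) raise descriptor-undefined
  errors when called directly and become NA inside `compute_all`, which
  must stay total for batch CLI use.
* Heteroatoms are rejected at bond perception with a clear error: the
  descriptor definitions (120° ideal angles, aromatic C–C R_opt) are
  specific to C/H benzenoids.

## Known limitations

* Only C/H PAHs; no five-membered rings, heteroatoms, or sp³ centers.
* The LAD vertex polish enumerates subsets of the smallest-residual
  points; for k ≳ 6 descriptors it degrades to the IRLS optimum with
  local polishing (still deterministic, no longer provably exact).
* `bend` on peri-condensed systems where cutting a fused bond does not
  split the skeleton falls back to a half-space rotation, which can shear
  bonds crossing the cut plane.
* Ring perception assumes a connected carbon skeleton (single molecule
  per frame).
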