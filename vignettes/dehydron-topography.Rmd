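---
title: "Dehydrons, surface curvature and the water-tight seal: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dehydrons, surface curvature and the water-tight seal: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhtopo)
```

## The scientific question

Soluble proteins must keep their backbone amide-carbonyl hydrogen bonds
(BHBs) dry: a hydrated backbone destabilizes the fold.  Most bonds are
protected by burial or by "wrapping" — a shell of side-chain nonpolar
groups around the bond.  Some bonds, however, are genuinely exposed to
solvent yet persist.  dhtopo implements a geometric analysis of how such
exposed bonds (EBHBs, also called *dehydrons*) stay dry: the surface
around them is rugged at the sub-nanometer scale, forming concave cavities
too tight for a water molecule to enter *together with its hydrogen-bonded
coordination shell*.  Because losing hydrogen-bond partners is
thermodynamically costly, water stays out of cavities whose concave
curvature radius is below the penetration threshold, and the exposed bond
remains water-tight.

The package computes, for any protein structure, the three quantities this
mechanism connects:

1. **Wrapping** `rho`: the number of side-chain carbonaceous nonpolar
   groups (CH~n~, n = 0..3) inside the bond's desolvation domain — the
   union of two spheres of radius 6 Å centered on the paired
   alpha-carbons.  Bonds with `rho <= 19` (one standard deviation below
   the literature database mean of 26.6) are classified EBHBs.
2. **Local curvature** `theta`: signed osculating-sphere radii of the
   solvent-accessible envelope, sampled near each bond (positive concave,
   negative convex; sub-nanoscale means `0 < theta < 10` Å).
3. **Hydration order parameters** `d_min` and `g_min`: from
   explicit-solvent coordinate frames, the frame-averaged minimum distance
   from the bond's carbonyl oxygen to a water oxygen, and the
   hydrogen-bond coordination of the water realizing that minimum.

## Geometric definitions and defaults

All defaults live in `run_config()` and are the printed conventions of the
dehydron literature:

| parameter | default | meaning |
|---|---|---|
| `max_no_distance` | 3.2 Å | N–O cutoff for a backbone hydrogen bond |
| `angle_range` | 120–180° | angle between the N–H and O=C bond vectors |
| `min_seq_sep` | 2 | minimum residue-number separation of the pair |
| `desolvation_radius` | 6 Å | wrapping two-sphere radius (~three water layers) |
| `ebhb_threshold` | 19 | wrappers at or below → exposed bond |
| `probe_radius` | 1.4 Å | water probe for the accessible envelope |
| `point_spacing` | 0.5 Å | envelope dot spacing |
| `patch_radius` | 2.5 Å | osculating-sphere fitting patch |
| `vicinity_radius` | 3 Å | baricenter-to-atom vicinity of a bond |
| `binwidth` | 0.25 Å | histogram coarse-graining |
| `theta_max` | 10 Å | sub-nanoscale upper bound |
| `flat_cutoff` | 20 Å | \|theta\| beyond which a patch is flat |
| `coordination_radius` | 2.5 Å | ball radius of the coordination field g(**r**) |

A water–water hydrogen bond requires O–O distance < 3.2 Å and an O–H–O
angle (at the hydrogen, over any of the four donor arrangements) within
120–180°.  A molecule's coordination `g` is its degree in that graph.  The
coordination action

$$A[g] \;=\; \sum_{j \in W}\; \sum_{n(j) \in M(j)} \big(g(\mathbf r_j) - g(\mathbf r_{n(j)})\big)^2$$

sums squared coordination differences over ordered hydrogen-bonded
neighbor pairs (each edge contributes twice; the normalization constant is
configurable and defaults to 1).  It is nonnegative and vanishes exactly
when `g` is constant on every connected component, which formalizes the
observation that interfacial water resists spatial changes in its
coordination.  The squared-difference form is the package's declared
choice: it is the minimal functional with the properties the mechanism
requires — penalizing any coordination change between hydrogen-bonded
neighbors, minimized by uniform coordination — and both the form and the
normalization are pluggable.

### Choices the definitions leave open

Several operational details are not pinned down by the published
definitions; dhtopo resolves them as follows, and each is either
configurable or isolated behind one function.

* **Amide hydrogens.**  Crystal structures rarely include them, while the
  angle criterion needs them.  `place_amide_hydrogens()` puts H at 1.0 Å
  from N, in the C(prev)–N–CA plane, opposite the bisector of the two
  bonds — the ideal trans-amide direction.  Experimentally present
  hydrogens are never moved; prolines and chain N-termini get none.
* **Which carbons count as wrappers.**  `classify_nonpolar_groups()` takes
  the strictest consistent reading of "side-chain carbonaceous nonpolar
  groups": side-chain carbons not covalently bonded to N, O or S, from a
  bundled connectivity table (robust to coordinate noise).  The C-beta of
  Ser/Thr/Cys is excluded by default and can be included with
  `include_polar_cb = TRUE`.  Note this strict count runs lower than the
  published database mean (on hen lysozyme it averages ~19 per bond rather
  than ~27), so the fixed threshold 19 flags a larger fraction of bonds
  than the ~26% the dehydron literature reports for native folds;
  `classify_ebhb(mode = "population")`
  recomputes the threshold as `floor(mean - sd)` of the supplied
  population when relative calling is preferred.
* **Sequence separation.**  The geometric definition alone would accept
  i→i±1 amide–carbonyl contacts that are artifacts of covalent geometry;
  we require a residue-number separation of at least 2 (configurable).
  Bifurcated donors are kept: each qualifying pair is one bond.
* **One theta per bond.**  The literature reports a single curvature
  radius per exposed bond without defining the reduction.
  `bhb_vicinity_spectrum()` uses the median of the concave sub-nanoscale
  values among envelope dots whose generating atom lies within 3 Å of the
  bond baricenter (midpoint of amide N and carbonyl O), falling back to
  the median of all vicinal values when no concave dot exists.  Medians
  resist the convex contamination that any vicinity definition admits.
* **Protein–water hydrogen bonds** do not contribute to `g`: coordination
  is defined as water–water throughout.

## The envelope and the curvature estimator

`build_envelope()` samples the solvent-accessible surface the standard
way: every heavy atom is inflated by its van der Waals radius plus the
1.4 Å probe, quasi-uniform dots (Fibonacci spirals) are placed on each
sphere at the requested spacing, and dots strictly inside any other
inflated sphere are discarded.  Dot directions are generated in a frame
derived from the principal axes of the atom cloud, which makes every
downstream curvature value exactly rigid-body covariant (verified to
1e-6 relative tolerance in the test suite); for clouds with a degenerate
inertia spectrum the frame falls back to the laboratory axes.

`estimate_theta()` fits an algebraic least-squares sphere (the Coope
formulation, solved by Gaussian elimination with partial pivoting on the
patch centered at each dot) to the dots within `patch_radius`, and signs
the radius by which side of the surface the fitted center falls on:
positive when it lies along the outward normal (solvent side, concave
surface), negative otherwise.  Three safeguards matter in practice:

* **Degeneracy**: patches with fewer than 6 dots, or whose normal
  equations are ill-conditioned beyond a pivot-ratio of 1e8, are flagged
  flat.
* **Planarity**: the algebraic fit can lock onto the residual lattice
  ripple of a sampled flat surface and report a spurious finite radius, so
  every patch is also fit by a plane in its local tangent frame; if the
  plane's RMS residual is below `plane_tol` (0.05 Å — far above the
  sampling ripple of an inflated-sphere envelope, far below any genuine
  sub-nanoscale feature) the dot is flat regardless of the sphere fit.
* **Adaptive refinement**: an osculating sphere is only meaningful while
  the patch does not out-span the feature, so dots whose first-pass
  \|theta\| is smaller than the patch radius are refit once with the patch
  shrunk to 1.2 × \|theta\| (floored at 1 Å).  Without this pass,
  cavities tighter than the 2.5 Å patch are biased wide by 10–30%.

On synthetic spherical pits the estimator recovers curvature radii across
the full 1–10 Å sub-nanoscale range with a median error under 2% and a
worst case under 10% (at theta* = 1 Å, where the feature holds only a few
dozen dots); halving the dot spacing moves per-bond summaries by less
than 5%.

## What the synthetic generators emulate

Survey-scale versions of this analysis rest on thousands of crystal
structures plus long explicit-solvent molecular dynamics.  Neither input
is reproducible at desk scale, so the package ships deterministic generators
that encode each stage's ground truth; all tests and the acceptance
script run from them (plus one real crystal structure bundled with bio3d)
with no downloads.

* `make_helix(n)`: ideal polyalanine alpha-helix (phi = −57°, psi = −47°,
  textbook bond lengths and angles), whose candidate bond set is exactly
  i→i+4.
* `make_wrapped_bond(w)`: one ideal glycine–glycine bond plus exactly `w`
  pseudo-CH3 carbons rejection-sampled inside the desolvation domain, at
  least 1 Å apart — the wrapping ground truth is `rho = w`.
* `make_cavity_surface(theta_star)`: a dense carbon slab whose envelope
  carries a spherical pit of curvature radius exactly `theta_star`
  (shell atoms on the sphere of radius theta* + 3.1 Å around the pit
  center).  With `with_bond = TRUE` an ideal bond is buried behind the
  continuous pit floor, backed by a lattice below so that every exposed
  dot vicinal to the bond is a pit-floor dot.
* `make_water_lattice(g_star, n)`: oxygens on a compact diamond-cubic
  (ice-like) block with 2.8 Å neighbors; the edge set is pruned to
  maximum degree `g_star`, oriented with at most two donations per
  molecule (greedy with path-reversal repair), donated hydrogens placed on
  the O–O axis and spare hydrogens pointed where they satisfy the angle
  criterion with no neighbor.  The recovered graph equals the intended one
  exactly.
* `make_solvated_bond(d_star, g_star, theta_star)`: a bond fixture plus a
  probe water with `g_star` tetrahedral partners, placed by a
  **water-exclusion rule**: the probe descends toward the carbonyl only
  while its entire coordination shell keeps a 3.0 Å clearance (the
  water-oxygen/heavy-atom contact distance) from every protein atom, and
  never closer than `d_star`.  Frames jitter each molecule rigidly with
  isotropic Gaussian noise (sigma = 0.1 Å, truncated at 1.7 sigma so the
  intended hydrogen-bond topology survives every frame — the jitter
  models libration, not bond breaking).

The exclusion rule makes the central mechanism emerge from geometry
rather than being painted on: with the hydrogen-bond length 2.8 Å and the
tetrahedral tripod half-angle 70.53°, a coordination shell fits through a
concave opening only for curvature radii upwards of roughly 4.5 Å.  In
the generated fixtures a bond beneath a theta* = 2.25 Å pit keeps its
nearest water at ~5.7 Å while an identical bond beneath a theta* = 5 Å
opening is approached to ~3.2 Å — the two hydration regimes that
crystal-structure surveys separate at the same curvature threshold.  What the generators do **not** emulate:
real side-chain packing statistics, water dynamics and exchange,
protein–water hydrogen bonding, long-range order of the hydration shell.
Passing the generator suite therefore validates the measurement machinery
and the geometric mechanism, not any claim about a particular protein
family.

## Numerical choices

* Alternate locations resolve to the highest occupancy, ties toward
  altloc "A"; multi-model files use the first model unless asked
  otherwise.  Waters (HOH/WAT/TIP/TIP3/SOL) are routed to the solvent
  slot; other heteroatoms are dropped.
* Argmin ties in the closest-water search break toward the lowest
  molecule index (determinism).
* Histograms use quarter-angstrom bins with the left-edge convention;
  densities are unit-mass within the reported range.
* Frames without explicit hydrogens are refused by default
  (`strict_hb = TRUE`); the `strict = FALSE` fallback counts O–O distance
  only and flags the graph `distance_only`.
* Frames are assumed unwrapped; there is no periodic-boundary handling in
  this version.
* Problem sizes in the tests and acceptance script (a 19-point curvature
  grid, wrapping knobs to 30, lattices to 500 waters, a 50-bond batch at
  3 frames) were chosen as the smallest sets that exercise every regime
  of the method — both sides of the 19-wrapper threshold, curvature on
  both sides of the ~4.5 Å penetration limit, coordination 1 through 4.

## Known limitations

* The osculating-sphere field is estimated per dot from a sampled
  envelope, not from the minimal covering by water-confining spheres; the
  two agree pointwise on the curvature radius but we never construct the
  covering itself.
* The strict CHn classification shifts the absolute wrapping scale
  relative to counts that include hetero-bonded side-chain carbons; use
  population-mode thresholding when comparing across conventions.
* Inter-chain bonds are excluded by default (the reference statistics are
  for monomeric proteins); enable `include_interchain` for complexes.
* mmCIF input, side-chain protonation and periodic solvent boxes are out
  of scope for this version.
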