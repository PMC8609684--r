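---
title: "Methods: synthetic vascular networks and stereological estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic vascular networks and stereological estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereovasc)
```

This vignette is the package's own account of its models and numerical
choices: what the synthetic data emulate, how each estimator is defined,
which decisions were genuinely open, and what passing the test suite does
and does not demonstrate about real tissue.

## 1. The reference volume

The hippocampus is idealised as five axis-aligned slab compartments —
dentate gyrus granule layer (DG), CA1 and CA2/3 pyramidal layers (jointly
the principal cell layers, PCL), molecular layer (ML), and white matter
(WM). Compartment volume fractions follow published non-transgenic rat
hippocampal morphometry: DG 4.43%, CA1 3.36%, CA2/3 4.37% (PCL 12.16%).
The ML/WM split of the remaining 87.84% is not printed in the literature we
calibrate against; we fix ML at 55% and WM at 32.84% of total as a
realistic split. Analytic box volumes are exact, so the Cavalieri estimator
has a closed-form truth.

Two geometric choices deserve comment:

- **Slabs are stacked perpendicular to the sectioning axis.** Sections are
  cut along z; compartments are stacked along x. In horizontal histological
  sections all hippocampal laminae appear side by side in every section,
  and per-compartment estimation under every-30th-section sampling is only
  possible if every sampled section crosses every compartment. Stacking the
  slabs along the sectioning axis instead would leave a 4%-thick
  compartment visible in well under one sampled section on average.
- **Flat slabs, not curved laminae.** Design-based estimators are unbiased
  for any shape; flat boxes keep point-in-region tests and truth volumes
  exact. Curvature would change nothing about estimator validity.

The default region spans 350 sections of 18 µm (z = 6300 µm) with a lateral
extent of 1000 × 250 µm — a virtual tissue block of ~1.6 mm³, about 3% of a
real hippocampus. The sectioning design (t = 18 µm, every 30th section,
1-µm guard zones, ~11–12 sampled sections) is the study design the
simulator reproduces; the lateral extent is the package's own compute/
precision trade-off, chosen so that a simulated cohort runs in seconds
while the smallest compartment (DG) still accumulates enough probe counts
for stable per-animal estimates (see §6).

## 2. The synthetic capillary network

No generative model for hippocampal microvasculature is given in the
literature we target, so the package defines one with exactly computable
ground truth: an isotropic persistent random walk with subcritical
branching.

- Chains grow in steps of 20 µm with isotropic direction jitter
  (sd 0.35 per step), reflecting at compartment walls; a capillary
  *segment* is the polyline between two topological nodes.
- Segment length is exponential with mean 62 µm (the published mean
  capillary length), truncated to [5, 248] µm.
- At each segment end the chain branches with probability 0.4 (creating a
  degree-3 "saddle point" node and two daughter chains) or terminates
  (a degree-1 endpoint). Trees therefore die out (mean offspring 0.8,
  mean 5 segments per tree).
- Tree roots are stratified along z (one root per stratum, jittered, in
  random order). Free Poisson placement of whole ~300-µm trees produced
  unrealistic clumping of fiber mass along z — capillary beds are
  space-filling at tissue scale — which inflated between-section sampling
  variance well beyond what count statistics explain.
- Per-compartment length targets are `Lv × volume` with Lv calibrated to
  published values: DG 1.70, CA1 1.90, CA2/3 1.87, ML 1.65, WM 1.55
  m/mm³ (volume-weighted total ≈ 1.65 m/mm³). Whole trees are kept in
  spawn order while they fit the budget; the residue is added as
  unbranched filler chains grown with exact specular reflection so each
  compartment's truth length equals its target almost exactly (well within
  the 1% contract).

Truth tables (length, branch nodes, endpoints, segments per compartment)
are recomputed from the emitted polylines, never tracked incrementally —
`network_truth()` is the single source of truth and `validate_network()`
enforces the degree/kind invariants.

The **transgenic phenotype** imposes two effects. First, whole DG segments
are pruned at random from the tree leaves until DG truth length reaches
`dg_length_multiplier` (default 0.51) times its original value, within the
±2% contract; a former branch node left with degree 2 is healed by merging
its two incident segments, so node-kind bookkeeping stays exact and no
segment is ever split mid-length. Second, plaque centres are placed as a
uniform Poisson process (density 450/mm³, radius 25 µm — about 3% volume
coverage, matching reported plaque load at 12–17 months; the literature
notes the real distribution is non-uniform, and no fidelity is claimed),
and 80% of capillaries passing within a plaque radius are re-radiused to
1.5 µm ("thin hair-like capillaries"). Radii are carried as geometry
metadata; no estimator in the chain reads them, so the hair-like transform
is phenotypic dressing with zero effect on counts — which is itself the
correct property for centerline-based probes.

Leaf pruning removes proportionally more nodes than length (short terminal
twigs die first): the default transform leaves DG with ~51% of its length
but ~20–25% of its branch nodes. The simulator pins only the length
effect; number-density effects are emergent, and are larger than the
moderate Nv reductions real Tg cohorts show.

## 3. Probes

All probes operate on geometry directly; there is no image rendering.

**Sections** are half-open z-intervals `[z_i, z_i + t)`, 0-based, so every
point belongs to exactly one section. Systematic selection takes every
k-th section after a uniform random start. Shrinkage correction is not
modelled; `t` is taken as configured.

**Point grid.** A rectangular lattice with a uniform random 2D offset per
section is intersected with the section mid-plane; `ΣP` per compartment
uses half-open box membership, so boundary points are counted exactly once.

**Optical disector.** Branch nodes with z inside the guarded core
`[z_i + g, z_i + t − g)` are counted behind counting frames on a lattice
with random offset. The frame interval is half-open in both axes:
left/bottom edges include, right/top edges exclude — the unbiased-counting-
frame rule — and with frames tiling the plane (the default, asf = 1) every
node in the guarded core is counted exactly once, which the test suite
verifies exhaustively.

**Sphere probes.** Spheres of radius 7 µm are centred at the section
mid-depth on a per-compartment lattice with random offset. Intersections
are counted analytically per polyline edge as the real roots of
`|p(s) − c|² = r²` on the half-open edge parameter `(0, 1]`; a positive
discriminant guarantees a transversal crossing, tangency counts zero, and
the half-open convention prevents double counting at shared vertices.
With the default radius the sphere fits entirely inside the guarded core
(`r ≤ (t − 2g)/2`); optionally larger spheres may be truncated at the
guard planes, removing `2πr·h` of cap area per side from the exposed
surface.

Two design details keep the length estimator unbiased at compartment
boundaries:

- sphere centres are laid on the compartment *dilated* by r in x and y, so
  capillaries near a wall are probed from both sides;
- the exposed surface `S_exposed` is accounted analytically as (compartment
  sectional area / lattice cell area) × sphere surface per section, i.e.
  the expected surface within the reference area. Both `ΣI` and
  `S_exposed` then have exact expectations under the lattice argument, and
  `Lv = 2ΣI/S_exposed` is a ratio of unbiased quantities. Realized
  sphere-by-sphere surface bookkeeping inside the box would need
  two-plane corner wedge areas that have no simple closed form, for no
  gain in bias.

Each probe draws its own independent random offset per section, all
derived from the animal's seed through named streams.

## 4. Estimators and their aggregation

The estimator formulas are in the README. Numerical conventions:

- Sampling fractions compose as in the optical fractionator
  (`ssf·asf·hsf`); the Euler `+1` for endpoints is applied once per
  reference space after scaling, treating each region's network as one
  connected structure — applying it per disector would add +1 per frame.
- `PCL` and `total` aggregates sum the member compartments' *estimated
  totals* (V, nodes, L) before deriving densities. Pooling raw sphere
  counts across compartments would weight each compartment by its sphere-
  lattice density rather than its volume and bias Lv whenever lattices
  differ (we measured +6% on total length before fixing this).
- The diffusion distance uses `r_diff = (4π·Lv)^(−1/2)` — the Krogh-
  cylinder closed form in which each unit of capillary length supplies a
  tissue cylinder; the proportionality constant (default
  `(4π)^(−1/2) = 0.2821`) is configurable. This is the closed form most
  consistent with the published Lv / diffusion-distance pairs; the precise
  post-processing formula used by the original instrument software is not
  public, so the constant is documented rather than claimed.
- Gundersen CE uses smoothness class 1 for point-count (area) series and
  class 0 for object-count series, shape coefficient 5, nugget noise
  `0.0724·b/√a·√(n·ΣP)` for point counts and 0 for object counts; the
  systematic variance term is clamped at 0. At least 3 sampled sections
  are required; all-zero series raise an error rather than returning 0.
- Division-by-zero cases are flagged as missing (`mean_length` with zero
  capillaries), never silently zeroed.

## 5. Group statistics

Between-group tests are exact Mann-Whitney U by full enumeration of group
labelings over mid-ranks — exact under ties, unlike the standard
normal-approximation fallback — with the two-sided p defined through the
symmetry of the null U distribution: `p = P(min(U, nm−U) ≤ observed min)`.
Within-group comparisons run a Friedman rank ANOVA across DG/CA1/CA2-3 and,
only when the omnibus passes α = 0.05, all pairwise exact Wilcoxon
signed-rank tests (zeros dropped, mid-ranks on |d|, 2^m sign enumeration).
Post-hoc p-values are uncorrected by default, matching the protocol of the
studies this mirrors (their reported post-hoc values are consistent with
uncorrected tests); a Holm option exists. Tests are two-sided throughout;
sidedness and tie handling are not stated in the source protocols, so the
conservative convention is used. Percent changes are computed from group
means of per-animal values (the convention of published summary tables),
not from pooled totals. Spearman correlations wrap `stats::cor.test`
(exact for small tie-free samples). The Friedman omnibus and Spearman use
the standard library implementations; the exact U and signed-rank tests
are package code because enumeration under ties is the protocol's
substance, and the library versions serve as independent oracles in the
tests.

## 6. Problem sizes, precision, and what the tests show

Default problem sizes: each simulated animal carries ~45,000 capillary
segments (~2.6 m of capillary in 1.58 mm³); a cohort is 11 animals; the
validation suite uses 200 sampling replicates on a fixed network for
estimator bias, 100 freshly simulated cohorts for effect recovery, and
small purpose-built regions for exactness checks. These sizes were chosen
so the estimates' sampling error, not compute, dominates: with the default
design the whole-region estimates carry CE(V) ≈ 0.01 and CE(L) ≈ 0.06–0.08
per animal, comparable to the stringency real studies report (CE ≈ 0.03
and 0.13), and per-animal DG length estimates have ~15% CV.

Probe-lattice defaults (point grid 15 µm; spheres on 15-µm lattices in the
PCL compartments and 80 µm in ML/WM; 60×60 µm frames tiling the plane) are
instrument settings, not estimator constants; they are the package's
calibration to that stringency and are freely configurable.

What passing the suite demonstrates: the estimator chain is unbiased under
its own sampling design (mean V̂/V, L̂/L, N̂/N within 2% over replicates);
exhaustive sampling is exact for counting; the exact tests match
enumeration; and a 49% imposed DG effect is recovered with correct
magnitude and significance in ≥80% of simulated cohorts. What it does not
demonstrate: robustness to anything the simulator does not model — tissue
shrinkage and deformation, staining artifacts, lost or folded sections,
observer error in recognising saddle points, curved laminar geometry,
non-uniform plaque clustering, or between-animal biological variance
(synthetic animals share identical target densities, so real cohorts'
larger between-animal spread would lower power relative to the simulated
estimate).

## 7. Reproducibility

Every random draw descends from one master seed through named streams
(`animal:<id>`, `probe:<id>`, per-probe per-section labels), so an
animal's network is invariant to cohort size and order, reruns are
byte-identical, and stages can be re-executed independently. Network files
round-trip through JSON with full double precision.
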