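---
title: "Methods: region-wise pathogenicity gradients along protein tunnels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-wise pathogenicity gradients along protein tunnels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`tunnelgrad` quantifies how predicted missense pathogenicity varies across
three nested structural contexts of a cofactor-bearing enzyme: the whole
protein, the residues lining its tunnels, and the immediate cofactor
microenvironment. The analysis takes three inputs per protein — a structure,
tunnel centerlines, and a table of per-substitution pathogenicity scores —
and is deliberately modular, so each stage can be validated in isolation.

## Residue sets

Both geometric rules are *atom-count* rules, deliberately so:

* **Tunnel-lining set.** Each tunnel centerline is resampled at regular
  arc-length intervals (default 0.5 Å, linear interpolation between profile
  nodes; the first and last node are always included; a spacing of 0 uses
  the native nodes). At each sample point the 5 closest protein heavy atoms
  are found and mapped to their parent residues. Because 5 atoms can belong
  to anywhere from 1 to 5 residues, each point contributes between 1 and 5
  residues; the set is the deduplicated union over all points of all
  tunnels of the protein.
* **Cofactor-proximal set.** The same nearest-5-atoms rule applied at each
  cofactor atom, unioned over the cofactor atoms.

Distance ties are broken by atom serial number, which makes both sets
independent of atom storage order. Hydrogens are excluded everywhere: the
model structures this analysis is aimed at are heavy-atom only, and
including hydrogens where they happen to exist would make the "five closest
atoms" rule inconsistent across file provenances. The whole-protein region
is *all* residues, not the complement of the other two sets (a complement
mode exists on `protein_set()` but is off by default): the tunnel and
cofactor sets are small, so the protein region serves as the cohort
baseline.

## Score aggregation

Score tables arrive in three dialects (long variant tables, SIFT-like
position × substitution matrices, transcript variant tables) and are
normalised to one entry per (position, reference, alternate). A residue's
mean pathogenicity is the arithmetic mean over *all available*
non-synonymous substitutions at its position — at most 19. Positions with
no entries are carried as explicitly missing and excluded from region
means, never imputed. The substitution count is exposed on every per-residue
row so the averaging convention is auditable. Mismatches between the
table's reference amino acid and the structure's residue are reported but
do not drop the residue: position numbering, not sequence identity, is the
join key, and the mismatch report is the user's signal to investigate.

Scale orientation (`pathogenic_high` for AlphaMissense-like tools,
`pathogenic_low` for SIFT-like inverse scales) is pure metadata. No score is
ever transformed; only the direction logic of the adherence computation and
the interpretation of region means consume it. This guarantees the
inversion symmetry that the test suite asserts exactly: replacing every
score s by 1 − s and flipping the declared orientation leaves adherence
counts and significance tiers unchanged.

## Region statistics

Per protein, each region is summarised by the mean of its residues'
mean scores, with missing-score residues counted and excluded. Cohort-level
outputs are amino-acid frequency profiles (percentages over the 20 standard
residues, summing to 100), per-amino-acid × region group means (absent
combinations reported as missing — a residue type can genuinely never occur
near a cofactor), and score-frequency histogram counts over equal-width
bins on [0, 1] with a right-closed final bin.

**Adherence** counts the units showing the strict monotone pattern
mean(protein) < mean(tunnel) < mean(cofactor), inequalities reversed for
inverse scales. The unit is the protein by default; a per-amino-acid mode
uses the group-mean matrix instead. Strictness is exact (tolerance 0): the
underlying data are averages of many substitution scores, so exact ties are
measure-zero, and any epsilon would be an arbitrary threshold.

**Paired t-tests** compare per-protein region means for protein-vs-tunnel
and tunnel-vs-cofactor: t = mean(d)/(sd(d)/√n) on the n paired differences,
two-sided p from the t distribution with n − 1 degrees of freedom. The
implementation is the closed form above, cross-checked in the tests against
`stats::t.test(paired = TRUE)` to 1e-10. When every difference is zero the
test is degenerate; it is reported with p = 1, no stars, and a flag rather
than NaN. Significance tiers are `**` p < .05, `***` p < .005, `****`
p < .0005 — an unconventional star convention, reproduced deliberately
because it is the one this analysis's figures use. No multiple-testing
correction is applied; with two planned comparisons per tool the raw
p-values are the honest report.

# The built-in tunnel finder

When no external tunnel computation is available, `find_tunnels()` provides
a simplified grid-based stand-in. It is *not* a reimplementation of a
Voronoi-based tunnel algorithm; it exists so the pipeline runs offline, and
its radii are **center clearances** (distance to the nearest atom center,
no van der Waals radii), documented as such.

The algorithm: voxelise the padded bounding box (default 0.6 Å spacing);
compute each voxel's clearance to the nearest protein heavy atom; mark
voxels open at `interior_threshold` (1.1 Å); classify **bulk solvent** as
the probe-open region (clearance ≥ `probe_radius`, 5 Å) connected to the
box boundary, and **exterior** as its probe-radius dilation; run a
widest-bottleneck (max-min clearance) Dijkstra search from the open
interior voxel nearest the cofactor centroid (which must lie within
`origin_radius`, 5 Å) until it touches the exterior. Paths are smoothed
with a short moving average, radii re-read from the clearance field, and
tunnels narrower than `bottleneck_radius` (1.2 Å) discarded. Up to k
tunnels are returned, widest first; after each accepted tunnel the exterior
shell within `surface_cover_radius` (10 Å) of its exit is closed and the
search repeats, so distinct tunnels surface more than 10 Å apart.

Two design points deserve emphasis:

* The interior/exterior classification is what makes the finder honest: a
  search allowed to wander through the sub-probe solvent shell would leave
  through one mouth, crawl along the surface, and report a second
  "tunnel" 10 Å away. Restricting traversal to the protein interior ends
  every path at the molecular surface, which is also where a tunnel
  physically ends.
* Determinism: priority ties in the search break on voxel index, and the
  neighbour expansion order is a seed-derived permutation, so identical
  inputs and seed give byte-identical output.

The default parameter values (probe 5 Å, interior threshold 1.1 Å, origin
radius 5 Å, bottleneck 1.2 Å, surface cover 10 Å) are the standard
tunnel-detection settings for heme proteins; `grid_spacing` (0.6 Å) is the
finder's own resolution knob, and recovered bottlenecks are accurate to
about one grid spacing. Tunnel-merging heuristics of full tunnel software
(profile similarity, bottleneck tolerance) are out of scope and not
emulated. When tunnel JSON is supplied it always takes precedence over the
finder.

# The synthetic cohort generator

The generator exists to make every pipeline claim testable without external
data. Its defaults define the package's reference study conditions: 30
proteins, 240 residues each, gradient amplitude g = 0.2, decay length
λ = 8 Å, residue noise σ = 0.05, direct orientation.

## Structures

Each structure is an idealised α-helix bundle (1.5 Å rise and 100° turn per
residue, Cα plus two dummy side-chain atoms per residue) arranged in
concentric rings around a central cavity, with a flat pseudo-heme ring at
the center. Three geometric choices emulate the structural facts the
analysis relies on in real globular enzymes:

* **Ball-like mass profile.** Outer rings hold more and longer helices
  (shell mass growing roughly with radius squared), so most residues sit
  far from the buried cofactor — as in a real ~60 Å enzyme, where the
  protein-wide average is dominated by distant residues.
* **Tunnels end at the surface.** Planted channels are carved by omitting
  every residue with an atom within `channel_radius` of the channel axis,
  and their exported centerlines stop where the axis clearance reaches
  bulk-solvent size (5 Å). Outer rings leave a thin-wall corridor around
  each channel direction, so the tunnel meets the surface shortly after
  the core — substrate channels take the short way out.
* **Two channels per protein.** Heme enzymes typically carry several
  tunnels, and the lining rule unions across all of them. With a single
  channel the toy lining set has only ~7 members, and at the reference
  noise level σ = 0.05 the region-mean noise σ/√7 swamps the planted
  protein–tunnel contrast, making gradient recovery a coin flip rather
  than a property of the method. Two channels (default) double the set and
  restore the contrast-to-noise margin; the choice was made from the
  noiseless planted means at design time.

Residue identities are drawn from a configurable composition (default: an
average globular composition), so frequency-profile tests have exact ground
truth. Everything is a pure function of (seed, index): the same pair gives
a byte-identical PDB. Geometry does not vary with the seed — only residue
identities and score noise do — which the seed-sweep tests exploit by
generating structures once.

## Scores

The planted model is per-residue: s̄ᵢ = clip(b + g·exp(−dᵢ/λ) + εᵢ),
εᵢ ~ N(0, σ²), dᵢ the residue's minimum atom distance to the cofactor
centroid, b = 0.35. The 19 substitution entries at each position jitter
around s̄ᵢ with an *exactly* mean-zero perturbation (rescaled near the
[0, 1] boundary rather than clipped), so the per-residue mean recovered by
the aggregation stage equals the planted value to machine precision — the
generator is the oracle for the aggregation code, not merely a noise
source. λ = 8 Å is the second-shell interaction scale: the cofactor's first
shell (~7 Å in the toy cavity) gets nearly the full amplitude, tunnel walls
an intermediate value, the distant bulk essentially the baseline. For
inverse-scale cohorts every emitted score is 1 − s.

## What passing tests do and do not show

The generator emulates the *statistical* structure of the real analysis —
distances, nested residue sets, monotone planted signal, independent
residue noise, inverse scales — not real protein geometry or real score
distributions. The toy helices have no true side chains, the channel walls
are cleaner than real tunnel linings, scores are Gaussian around the
planted mean rather than bimodal, and residue noise is independent whereas
real predictors are spatially correlated. Passing the recovery tests
therefore shows the pipeline's machinery is correct and unbiased under
known conditions; it does not certify effect sizes or significance levels
on real proteins.

A consequence of the nested design worth knowing: under a null cohort
(g = 0) the chance rate of the strict double inequality is about 1/4, not
1/6, because the cofactor set is contained in the tunnel set (the
tunnel-vs-cofactor comparison reduces to cofactor members against the
remaining lining members, giving probability 1/2 nearly independent of the
protein-vs-tunnel coin flip). The 1/6 rate applies to exchangeable region
means, and the test suite asserts each statement in its own regime. The
paired t-test's size is exact either way, which the suite verifies on 1000
gradient-free cohorts.

# Numerical and edge-case policy

* Distance ties: (distance, atom serial); search ties: (clearance, voxel
  index) plus a seed-permuted neighbour order.
* Duplicate substitution rows: last wins, with a warning. Synonymous rows:
  dropped, with a message. Malformed variants or out-of-range scores: hard
  errors naming the row.
* Regions with no scored residues yield missing means and are excluded
  from adherence denominators (and reported); proteins without tunnels stay
  in the run but contribute no tunnel/cofactor statistics.
* A failing protein is skipped with a logged message; an empty surviving
  cohort is an error.
* All simulation-based tests use fixed seeds. Problem sizes were chosen to
  make the suite's statistical assertions sharp at desk scale: 50 random
  structures for the exhaustive nearest-atom oracles, 10³-voxel grids for
  widest-path optimality, 100 seeds of the 30-protein reference cohort for
  gradient recovery, and 1000 gradient-free cohorts (30 proteins of 40
  residues) for the type-I check.

# Limitations

* The grid finder reports center clearance, not probe-accessible radius,
  and uses 6-connected voxel paths; its bottlenecks are grid-resolution
  accurate and not comparable to Voronoi-based radii beyond ~one spacing.
* Multi-chain structures are joined to score tables by author residue
  number only; tables for hetero-oligomers should be split per chain.
* mmCIF input, score computation itself, transcript mapping, and
  secondary-structure visualisation are out of scope.
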