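# tunnelgrad

Missense pathogenicity predictors (AlphaMissense-like, SIFT-like,
PrimateAI-3D-like) assign every possible amino-acid substitution a score in
[0, 1]. For enzymes with a buried cofactor — the motivating system is the
heme-containing cytochrome P450 family — an informative structural question
is whether predicted pathogenicity *increases* from the protein at large,
through the residues lining its substrate tunnels, to the immediate cofactor
microenvironment. `tunnelgrad` is an R package for running that analysis
end-to-end on local files, and for validating every step of it on fully
synthetic cohorts with a known, planted gradient.

## What it computes

For each protein structure (PDB with one HET cofactor group, default `HEM`)
and each tunnel centerline (parsed from MOLE-style JSON exports, or computed
by a built-in grid-based widest-path finder seeded at the cofactor), the
package builds three residue sets:

* **protein** — every residue;
* **tunnel** — sample each tunnel centerline at regular arc-length points
  (default 0.5 Å), take the 5 protein heavy atoms closest to each point, map
  them to their parent residues (between 1 and 5 residues per point), and
  union over all points of all tunnels;
* **cofactor** — for each cofactor atom, the 5 closest protein heavy atoms,
  mapped to residues and unioned.

Substitution-level scores are aggregated per residue as the arithmetic mean
over all available non-synonymous substitutions at that position
(score s̄ᵢ = (1/nᵢ) Σⱼ sᵢⱼ, nᵢ ≤ 19). Region means are averages of s̄ᵢ over
each set. Cohort-level outputs are:

* amino-acid frequency profiles per region;
* per-amino-acid × region mean-score matrices and score-frequency
  histogram counts (heatmap data);
* the **adherence rate**: the percentage of units (proteins, or amino-acid
  types) whose means satisfy the strict monotone pattern
  mean(protein) < mean(tunnel) < mean(cofactor) — with both inequalities
  reversed for inverse-scaled (SIFT-like, `pathogenic_low`) tools;
* two-sided **paired t-tests** across proteins for protein-vs-tunnel and
  tunnel-vs-cofactor, t = mean(d)/(sd(d)/√n) with n − 1 degrees of freedom,
  annotated `**` (p < .05), `***` (p < .005), `****` (p < .0005).

Scale orientation is declared metadata: scores are never transformed, and
direction handling lives entirely in the adherence and reporting logic.

## Worked example

A self-contained synthetic cohort — helix-bundle structures with a buried
pseudo-heme, planted exit channels, and score tables carrying a planted
gradient toward the cofactor (amplitude 0.2, decay length 8 Å, residue noise
SD 0.05):

```r
library(tunnelgrad)

spec <- cohort_spec(n_proteins = 8, seed = 42)
dir  <- tempfile()
cfg  <- make_cohort(spec, dir)      # writes PDB + tunnel JSON + score TSVs
report <- run_pipeline(cfg)
print(report)
#> <tg_report> 8 proteins (0 without tunnels, 0 skipped)
#>   adherence (per_protein): 100.0% (8/8)
#>   protein vs tunnel    t = 10.224, p = 1.85e-05 ****
#>   tunnel vs cofactor   t = 8.742, p = 5.15e-05 ****

head(tidy(report), 3)               # per-protein region means
#>   protein_id region   mean_score n_residues n_missing
#> 1 SYN001     protein       0.362        240         0
#> 2 SYN001     tunnel        0.398         14         0
#> 3 SYN001     cofactor      0.412          6         0
```

All 8 proteins adhere to the planted protein < tunnel < cofactor pattern,
and both paired comparisons are significant at the `****` tier — the
generator's gradient is recovered. `autoplot(report)` draws the three-bar
region comparison with 95% confidence intervals;
`plot_aa_frequencies()` and `plot_score_heatmap()` mirror the frequency and
heatmap summaries. Real data run the same way: point the `run_config()`
manifest at your PDB files, MOLE JSON exports (or `tunnels: compute`), and
score tables (`variant`, `matrix`, or `transcript` dialect, with the tool's
scale orientation).

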