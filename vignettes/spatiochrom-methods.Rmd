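---
title: "Methods: chromosome reconstruction and spatiosynteny statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome reconstruction and spatiosynteny statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spatiochrom)
```

## The physical model and its assumptions

A chromosome is coarse-grained to one bead per Hi-C bin (150 kb by
default) and evolved as a damped Newtonian system,
`m a_i = -γ v_i + F_rep + F_ten + F_HiC`, under three linear-elastic
force terms: volume exclusion between overlapping beads, backbone tension
between consecutive beads, and restraint springs between bin pairs whose
interaction frequency (IF) exceeds a cutoff. The assumptions this
encodes:

* a *population-average* single conformation is a meaningful summary —
  the input matrix aggregates many cells (and often tissues), so the
  model is a consensus topology, not a single-cell structure;
* only **cis** contacts are informative enough to use; each chromosome is
  simulated alone, with no nuclear envelope, lamina, or trans contacts;
* every above-cutoff contact is restrained with the *same* rest length
  `d_HiC0` — IF magnitude beyond the cutoff does not change the target
  distance, only whether a spring exists. This keeps the model robust to
  IF scale and normalisation differences between datasets.

Integration is position-Verlet with the drag-term velocity estimated from
successive positions, `v = (x_t − x_{t−dt}) / dt`. This estimator makes
the steady state of a constant applied force exactly the terminal
velocity `F/γ` (the tests assert this within 1%), and is stable for the
overdamped spring systems used here. Initial conformations are
self-avoiding random walks (fixed step, minimum non-consecutive pair
distance), so replicates explore independent basins; a run is a fixed
10,000 steps with convergence *monitored* (pseudo-energy and
RMSD-to-final) but never used as a stopping rule, keeping runs exactly
reproducible per seed.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `r_bead` | nm | 25 | physical radius of a 150 kb bead; puts model pair distances in the 100–300 nm regime reported for chromosome-scale separations. A modeling convention, not a measurement. |
| `d_rep0` | nm | `2 r_bead` = 50 | beads touch at twice the radius; enforced at construction. |
| `c2`, `d_hic0` | nm | 50 | backbone and restraint rest lengths; both default to bead contact distance. |
| `m`, `gamma` | — | 1, 0.5 | drag-dominated dynamics; the momentum relaxation time is `m/γ` = 2 time units ≪ a run. |
| `k_rep`, `k_ten`, `k_hic` | force/length | 1, 1, 0.3 | stability parametrization: restraints softer than the backbone so Hi-C springs deform but never fold the chain through itself violently. The source parametrization for the published models is not printed; these defaults are validated by property tests (terminal velocity, spring equilibration, energy decay, structure recovery), not by matching constants. |
| `dt`, `n_steps` | — | 0.01, 10,000 | `dt` well under the fastest spring period; 10,000 steps ≈ 50 momentum relaxation times. |
| IF cutoff | — | mean IF | mean of the chromosome's nonzero cis IF values; median and arbitrary percentiles available, plus an explicit mode that consumes pre-filtered (e.g. FitHiC significant) pair lists verbatim. Strict inequality: ties at the cutoff are excluded. |
| IntSph radius | nm | 0.5–1.0 × fitted inflection | see below. |

## Interaction spheres

Contact density of bead *i* at radius *r* is the exact count of beads in
the closed ball of radius *r* around it (self excluded, genomic
neighbours included — small radii are legitimately dominated by local
genomic contacts; an `exclude_adjacent` flag exists for sensitivity
analyses). The implementation is distance-matrix based and is tested for
bit-identity against a naive double-loop recount.

To pick a working radius, mean density is scanned over a radius range and
fitted with a four-parameter logistic; the recommended radius is
0.5–1.0 × the fitted inflection `x0` (fractions outside that band are
rejected). The fit is least-squares from a deterministic grid of
quartile-based starts (BFGS, then an `nls` polish when it improves). A
fit is flagged `poor_fit` when the inflection leaves the scanned range,
the asymptotes overshoot the data by more than half its span, or
residuals exceed 5% of the data variance — strictly linear scans (no
plateau reached) are caught by the asymptote rule, since a logistic can
mimic a line arbitrarily well with runaway asymptotes. One ambiguity in
the source description — whether the "sigmoidal fit" applies to the
mean-density-vs-radius curve or to the per-bead density distribution —
is resolved here as mean-vs-radius; per-bead distributions remain
available for inspection.

## Synteny dialect

Genes map to the bead containing their midpoint (one gene, one bead — no
double counting). A bin is **ALG** if it holds at least one
ancestral-linkage-group gene, **nonALG** if it holds orthologous but no
ALG genes, unannotated otherwise.

Microsyntenic blocks are *order-free and strand-free*: a block is a
maximal set of shared orthogroups such that, in both species, consecutive
member genes (sorted by position) are separated by at most 5 intervening
non-member genes, with at least 3 orthogroups per block. Intervening
genes are counted over *all* annotated genes, orthologous or not. The
published chaining method this emulates is not reprinted in the source;
order-freedom was chosen because conservation is reported to survive
within-block scrambling, and the dialect is enforced by an independent
gap-rule verifier in the tests. Detection runs a split-to-fixed-point
refinement per chromosome pair: start from all shared orthogroups, split
by the gap rule in species A, then B, and repeat until stable.

Chromosome homology uses, per chromosome pair, the one-sided
hypergeometric (Fisher exact) enrichment of shared one-to-one orthologs
against the gene-permutation null, BH-corrected across all pairs, calling
homology at q < 0.05. One-sidedness is a package choice (homology =
excess sharing); the source does not state sidedness.

## The Fasano–Franceschini test

The 2D two-sample statistic uses every pooled data point as a quadrant
origin; the discrepancy at an origin is the largest absolute difference
in the two samples' quadrant fractions, and D averages the maximal
discrepancy over sample-A origins with that over sample-B origins. Each
point counts itself in its own closed lower-left quadrant — this tie
convention makes D exactly 0 for identical samples. P-values come from
label permutations (default 999) rather than the asymptotic
approximation: pair samples here can be small, and permutation is exact
in distribution at any n. D is invariant under axis-wise monotone
transforms (quadrant memberships cannot change), which the tests assert.
Type-I calibration at α = 0.05 over 500 null repetitions is part of the
acceptance suite.

Wilcoxon comparisons (microsynteny density tests) use exact enumeration
for tie-free samples up to n = 12 and the tie-corrected normal
approximation otherwise, with an exact permutation oracle in the tests;
an all-tied degenerate input returns p = 1.

## What the synthetic data emulates — and what it does not

`write_fixture_bundle()` is the package's stated world:

* **structures**: known 3D conformations (SARW by default; helix and
  rosette with closed forms) at 50 beads per chromosome;
* **contacts**: `IF = scale (d/d_ref)^(−α)` with α = 1 — a generic
  polymer-like decay chosen for internal consistency, not biophysical
  realism — optionally Poisson-sampled;
* **genomes**: two pseudo-species, 8 chromosomes × 100 genes each, with a
  one-to-one homologous chromosome map, an ALG fraction of 0.4 among
  single orthologs (the ALG/nonALG balance of chromosome-scale animal
  comparisons, where nonALG orthologs outnumber ALG ~9k to ~5.5k), 3
  planted microsyntenic blocks of 4 orthogroups, and ortholog spacing
  engineered so that *only* the planted blocks satisfy the gap rule.
  Eight chromosomes is a deliberate downscaling of real animal karyotypes
  (~19): with very few chromosomes a 0.4 diagonal fraction is barely
  above the permutation null and the homology test has no power, which
  would be an artifact of miniaturisation, not of the method.

A green test on these fixtures establishes that the algorithms recover
planted truth under their own generative assumptions. It does *not*
establish biological accuracy on real Hi-C: the fixtures have no
distance-dependent noise structure, no unmappable regions, no
normalisation artifacts, and their contact decay is exactly the model's
inverse power law. Published real-data quantities (observed vs random
microsynteny densities 7.68/6.0 vs 6.74/5.0, their Wilcoxon p-values, 14
conserved SuperHox-adjacent orthologs, per-chromosome ALG pair counts)
require the original SRA accessions; the recipe is: HiC-Pro matrices at
150 kb → `read_hicpro`/`extract_cis` → mean-IF `reconstruct` (3
replicates) → `contact_density` at the sigmoid-recommended radius →
`alg_contact_counts` / `microsynteny_density_test` /
`shared_spatial_neighbors` at r = 50 nm. They are documented, not
asserted.

## Numerical choices and degenerate inputs

* Coincident beads (undefined unit vector): separated by a seeded random
  1e-6·`r_bead` jitter, logged.
* Non-finite coordinates mid-run abort the replicate with a dt hint;
  other replicates continue, and at least one must survive.
* Percentiles are linear-interpolation order statistics (type 7); the
  35th-percentile retention (~65%) depends weakly on this convention and
  it is therefore fixed and documented.
* PDB output divides nm by a recorded scale to fit the fixed 8.3
  columns; round trips are exact to 1e-3·scale. Residues beyond 9999
  roll into a second chain, recorded in the header remarks.
* All stochastic operations take explicit seeds; replicate and
  permutation seeds derive deterministically from one run seed and stay
  within 32-bit integer range.

## Known limitations

Single-chromosome models only (no trans contacts, no nuclear context);
one consensus structure per replicate rather than an ensemble
deconvolution; restraints ignore IF magnitude above the cutoff; the
microsynteny dialect is an order-free approximation of the published
chaining method; matrix balancing is assumed done upstream; and model
quality is bounded by Hi-C quality — the motivation for the IntSph
partitioning is precisely to keep cross-species comparisons meaningful
when long-range contact information is thin.
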